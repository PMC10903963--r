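# Worked per-locus parameterisations used throughout the examples, tests,
# and experiment sweeps.

#' Example fitness schemes
#'
#' Canonical per-locus parameterisations for the three regimes the toolkit
#' explores, with adult coefficients equal in the two sex roles and `H = 2`:
#'
#' * `scheme_deleterious()`: a partially recessive deleterious allele
#'   (`s_AA = 0`, `s_Aa = -0.01`, `s_aa = -0.05`) also disfavoured in
#'   gametes - the mutation-selection-balance workhorse.
#' * `scheme_antagonistic()`: ploidally antagonistic selection - the a
#'   allele favoured in adults (`s_AA = -0.075`, `s_Aa = -0.01`,
#'   `s_aa = 0`) while A wins gamete competition; maintains a balanced
#'   polymorphism when gametic selection is strong enough.
#' * `scheme_antagonistic_mild()`: the gentler variant
#'   (`s_AA = -0.05`, `s_Aa = -0.01`, `s_aa = 0`).
#' * `scheme_overdominant()`: heterozygote advantage in adults
#'   (`s_AA = -0.075`, `s_Aa = 0`, `s_aa = -0.05`) with weak gametic
#'   selection.
#'
#' @param sigma Strength of gametic selection against a.
#' @param d Gametic expression pattern (0 haploid, 1 diploid).
#' @return A [fitness_scheme()].
#' @name example_schemes
NULL

#' @rdname example_schemes
#' @export
scheme_deleterious <- function(sigma = 0.12, d = 0) {
  fitness_scheme(c(AA = 0, Aa = -0.01, aa = -0.05), sigma = sigma, d = d)
}

#' @rdname example_schemes
#' @export
scheme_antagonistic <- function(sigma = 0.12, d = 0) {
  fitness_scheme(c(AA = -0.075, Aa = -0.01, aa = 0), sigma = sigma, d = d)
}

#' @rdname example_schemes
#' @export
scheme_antagonistic_mild <- function(sigma = 0.05, d = 0) {
  fitness_scheme(c(AA = -0.05, Aa = -0.01, aa = 0), sigma = sigma, d = d)
}

#' @rdname example_schemes
#' @export
scheme_overdominant <- function(sigma = 0.025, d = 0) {
  fitness_scheme(c(AA = -0.075, Aa = 0, aa = -0.05), sigma = sigma, d = d)
}
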