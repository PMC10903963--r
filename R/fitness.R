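#' Expression-masking function for gametic fitness
#'
#' Maps the proportion of a-allele expression in a male gamete to the factor
#' by which the full gametic selection coefficient `sigma` is felt,
#' `gamma(x) = 1 - (1 - x^H)^(1/H)`.  `H` is the gametic dominance of the
#' higher-fitness A allele: with `H = 1` masking is absent (gamma is the
#' identity), with `H > 1` partial expression of the a allele is masked.
#'
#' @param x Proportion of a-allele expression, in `[0, 1]`.  Vectorised.
#' @param H Gametic dominance of the A allele, `H > 0`.
#' @return Masking factor in `[0, 1]`, monotone non-decreasing in `x`, with
#'   `gamma(0) = 0` and `gamma(1) = 1`.
#' @examples
#' gamma_masking(0.5, H = 2) # 1 - sqrt(0.75)
#' gamma_masking(0.5, H = 1) # identity
#' @export
gamma_masking <- function(x, H = 2) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("`x` must be numeric in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(H) || length(H) != 1L || is.na(H) || H <= 0) {
    stop("`H` must be a single positive number", call. = FALSE)
  }
  1 - (1 - x^H)^(1 / H)
}

#' Per-locus fitness scheme for adults and male gametes
#'
#' Bundles the selection coefficients acting on one biallelic locus across
#' the life cycle: diploid adult fitness `1 + s` by genotype and sex role
#' (female fecundity vs male fecundity/siring), and the gametic selection
#' parameters.  Male gametes produced by `AA` males have relative fitness 1;
#' gametes from `Aa` males have fitness `1 - gamma(d/2) * sigma` (A-bearing)
#' and `1 - gamma(1 - d/2) * sigma` (a-bearing); `a` gametes from `aa` males
#' have fitness `1 - sigma`.
#'
#' The same scheme serves hermaphrodites and separate-sex interpretations:
#' the "female"/"male" maps are role-specific fitness effects.
#'
#' @param s_female Named numeric vector `c(AA=, Aa=, aa=)` of female-role
#'   selection coefficients (fitness `1 + s`).  An unnamed length-3 vector is
#'   taken in the order AA, Aa, aa.
#' @param s_male Same for the male role; defaults to `s_female`.
#' @param sigma Strength of gametic selection against the a allele,
#'   `0 <= sigma < 1`.
#' @param d Gametic expression pattern: `0` fully haploid (the gamete's own
#'   allele is expressed), `1` fully diploid (the father's genotype is
#'   expressed).
#' @param H Gametic dominance of the A allele in [gamma_masking()], `H > 0`.
#' @return An object of class `fitness_scheme`.
#' @examples
#' # partially recessive deleterious allele with gametic selection
#' fitness_scheme(c(AA = 0, Aa = -0.01, aa = -0.05), sigma = 0.12, d = 0)
#' @export
fitness_scheme <- function(s_female = c(AA = 0, Aa = 0, aa = 0),
                           s_male = s_female,
                           sigma = 0, d = 0, H = 2) {
  s_female <- check_s_map(s_female, "s_female")
  s_male <- check_s_map(s_male, "s_male")
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) ||
      sigma < 0 || sigma >= 1) {
    stop("`sigma` must be a single number in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d > 1) {
    stop("`d` must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(H) || length(H) != 1L || is.na(H) || H <= 0) {
    stop("`H` must be a single positive number", call. = FALSE)
  }
  structure(
    list(s_female = s_female, s_male = s_male, sigma = sigma, d = d, H = H),
    class = "fitness_scheme"
  )
}

check_s_map <- function(s, what) {
  if (!is.numeric(s) || length(s) != 3L || anyNA(s)) {
    stop("`", what, "` must be a numeric length-3 vector (AA, Aa, aa)",
         call. = FALSE)
  }
  if (is.null(names(s))) {
    names(s) <- c("AA", "Aa", "aa")
  } else if (!setequal(names(s), c("AA", "Aa", "aa"))) {
    stop("`", what, "` names must be AA, Aa, aa", call. = FALSE)
  }
  s <- s[c("AA", "Aa", "aa")]
  if (any(1 + s <= 0)) {
    stop("all adult fitnesses 1 + s must be positive", call. = FALSE)
  }
  s
}

#' @export
print.fitness_scheme <- function(x, ...) {
  cat("<fitness_scheme>\n")
  cat("  adult s (female):", sprintf("%g", x$s_female), "\n")
  cat("  adult s (male):  ", sprintf("%g", x$s_male), "\n")
  cat(sprintf("  gametic: sigma = %g, d = %g, H = %g\n", x$sigma, x$d, x$H))
  invisible(x)
}

# Internal: the four gamete relative fitnesses plus the Aa-male compound terms.
gamete_fitnesses <- function(scheme) {
  w_A_AA <- 1
  w_A_Aa <- 1 - gamma_masking(scheme$d / 2, scheme$H) * scheme$sigma
  w_a_Aa <- 1 - gamma_masking(1 - scheme$d / 2, scheme$H) * scheme$sigma
  w_a_aa <- 1 - scheme$sigma
  s_A_Aa <- w_A_Aa - 1
  s_a_Aa <- w_a_Aa - 1
  list(
    w_A_AA = w_A_AA, w_A_Aa = w_A_Aa, w_a_Aa = w_a_Aa, w_a_aa = w_a_aa,
    s_A_AA = 0, s_A_Aa = s_A_Aa, s_a_Aa = s_a_Aa, s_a_aa = w_a_aa - 1,
    s_delta_Aa = (s_A_Aa - s_a_Aa) / 2,
    s_bar_Aa = (s_A_Aa + s_a_Aa) / 2
  )
}

#' Gamete fitness table for a fitness scheme
#'
#' Evaluates the four combinations of gamete allele and paternal genotype.
#' Fitnesses are relative, normalised so that A gametes from AA males have
#' fitness 1.
#'
#' @param scheme A [fitness_scheme()].
#' @return A tibble with columns `father`, `gamete`, `fitness` (four rows).
#' @seealso [gamete_selection_summary()] for the compound Aa-male terms.
#' @export
gamete_fitness_table <- function(scheme) {
  stopifnot(inherits(scheme, "fitness_scheme"))
  g <- gamete_fitnesses(scheme)
  tibble::tibble(
    father = c("AA", "Aa", "Aa", "aa"),
    gamete = c("A", "A", "a", "a"),
    fitness = c(g$w_A_AA, g$w_A_Aa, g$w_a_Aa, g$w_a_aa)
  )
}

#' Compound gametic selection terms for Aa males
#'
#' The fitness half-difference between gamete types produced by heterozygous
#' males, `s_delta_Aa = (s_A^Aa - s_a^Aa) / 2`, and their mean deviation
#' `s_bar_Aa = (s_A^Aa + s_a^Aa) / 2`.  `s_delta_Aa` is the raw material for
#' within-male gamete competition; it vanishes exactly when expression is
#' diploid (`d = 1`) or gametic selection is absent (`sigma = 0`).
#'
#' @param scheme A [fitness_scheme()].
#' @return A one-row tibble with columns `s_delta_Aa`, `s_bar_Aa`.
#' @export
gamete_selection_summary <- function(scheme) {
  stopifnot(inherits(scheme, "fitness_scheme"))
  g <- gamete_fitnesses(scheme)
  tibble::tibble(s_delta_Aa = g$s_delta_Aa, s_bar_Aa = g$s_bar_Aa)
}
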