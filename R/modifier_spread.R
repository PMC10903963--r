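#' Spread rate of a polyandry modifier with the selected locus at
#' mutation-selection balance
#'
#' Per-generation growth rate of a rare mating-system modifier allele that
#' changes the proportion of polyandry by `delta_pi = (Pi_Mm - Pi)/2`, when
#' deleterious alleles segregate at frequency `q_hat` at the selected locus:
#' `lambda = 1 + delta_pi * q_hat * (s_A^AA - s_bar^Aa) *
#' (-s_bar_female_a - s_bar_male_diploid_a + Pi (s_A^AA - s_bar^Aa))`.
#' For a deleterious allele all bracketed factors are positive, so polyandry
#' (`delta_pi > 0`) is favoured: it sharpens gametic selection and raises
#' offspring fitness.
#'
#' @param scheme A [fitness_scheme()] with the a allele deleterious.
#' @param level Resident proportion of polyandry Pi.
#' @param delta_pi Modifier effect `(Pi_Mm - Pi)/2`.
#' @param q_hat Equilibrium deleterious-allele frequency (see [q_hat_msb()]).
#' @return Spread rate `lambda` (numeric).
#' @export
lambda_polyandry_msb <- function(scheme, level, delta_pi, q_hat) {
  g <- gamete_fitnesses(scheme)
  terms <- selection_terms(scheme, "polyandry", level)
  a <- terms[terms$allele == "a", ]
  pre <- g$s_A_AA - g$s_bar_Aa
  bracket <- -a$s_bar_female - a$s_bar_male_diploid + level * pre
  1 + delta_pi * q_hat * pre * bracket
}

#' Spread rate of a polyandry modifier with the selected locus under
#' balancing selection
#'
#' `lambda = 1 - delta_pi * q_hat (1 - q_hat) * s_delta_Aa *
#' ((1 - q_hat)(s_A^AA - s_bar^Aa) + q_hat (s_bar^Aa - s_a^aa))`.
#' As long as gametic fitness increases monotonically with expression of the
#' higher-fitness allele, the product is positive and monandry
#' (`delta_pi < 0`) is favoured: gametic selection drags a balanced
#' polymorphism away from the adult optimum, and monandry blunts it.  With
#' diploid expression (`d = 1`) `s_delta_Aa = 0` and the modifier is neutral.
#'
#' @inheritParams lambda_polyandry_msb
#' @param q_hat Balancing-selection equilibrium frequency of a (see
#'   [q_hat_balancing()]).
#' @return Spread rate `lambda` (numeric).
#' @export
lambda_polyandry_balancing <- function(scheme, delta_pi, q_hat) {
  g <- gamete_fitnesses(scheme)
  bracket <- (1 - q_hat) * (g$s_A_AA - g$s_bar_Aa) +
    q_hat * (g$s_bar_Aa - g$s_a_aa)
  1 - delta_pi * q_hat * (1 - q_hat) * g$s_delta_Aa * bracket
}

#' Leading-order spread rate of a selfing/outcrossing modifier: the
#' transmission advantage
#'
#' Independently of any selected locus, a modifier that increases outcrossing
#' by `delta_omega` changes frequency at rate
#' `lambda = 1 - delta_omega (1 - c) / (2 (1 - c (1 - Omega)))`.
#' Selfers contribute both gamete types to their own offspring while still
#' siring outcrossed offspring, an automatic advantage of up to 50% per
#' generation that pollen discounting `c` erodes; `c = 1` removes it.
#'
#' @param delta_omega Increase in outcrossing caused by the modifier,
#'   `Delta_Omega = (1 - F)(Omega_Mm - Omega) + F (Omega_mm - Omega)`.
#' @param c Pollen discounting in `[0, 1]`.
#' @param level Resident proportion of outcrossing Omega.
#' @return Spread rate `lambda` (numeric, vectorised).
#' @export
lambda_selfing_leading <- function(delta_omega, c, level) {
  if (any(c < 0) || any(c > 1)) stop("`c` must be in [0, 1]", call. = FALSE)
  1 - delta_omega * (1 - c) / (2 * (1 - c * (1 - level)))
}

#' Spread rate of an outcrossing modifier under full pollen discounting,
#' selected locus at mutation-selection balance
#'
#' With `c = 1` (no transmission advantage) and a small dominant modifier,
#' `lambda = 1 + delta_omega (1 + F) q_hat (I_A + I_a) / (2 Omega)`.
#' `I_A + I_a > 0` for (partially) recessive deleterious alleles, which
#' therefore favour outcrossing; dominant deleterious alleles reverse the
#' sign and favour selfing.
#'
#' @param scheme A [fitness_scheme()].
#' @param level Resident proportion of outcrossing Omega (must be > 0).
#' @param delta_omega Modifier effect on the rate of outcrossing (small,
#'   dominant: `Omega_mm = Omega_Mm`).
#' @param q_hat Mutation-selection-balance frequency of the deleterious
#'   allele in the `mode = "outcrossing"` context at `level`.
#' @return Spread rate `lambda` (numeric).
#' @export
lambda_selfing_msb <- function(scheme, level, delta_omega, q_hat) {
  if (level <= 0) {
    stop("`level` (Omega) must be positive: the spread rate is undefined ",
         "in a fully selfing population", call. = FALSE)
  }
  ic <- invasion_coefficients(scheme, "outcrossing", level)
  1 + delta_omega * (1 + ic$F) * q_hat * (ic$I_A + ic$I_a) / (2 * level)
}

#' Spread rate of an outcrossing modifier under full pollen discounting,
#' selected locus under balancing selection
#'
#' `lambda = 1 + delta_omega (1 + F) q_hat (1 - q_hat) (I_A + I_a) /
#' (2 Omega)`.  Balancing selection requires both alleles to be favoured
#' when rare (`I_A, I_a > 0`), so increased outcrossing is always favoured.
#'
#' @inheritParams lambda_selfing_msb
#' @param q_hat Balancing-selection equilibrium frequency of a.
#' @return Spread rate `lambda` (numeric).
#' @export
lambda_selfing_balancing <- function(scheme, level, delta_omega, q_hat) {
  if (level <= 0) {
    stop("`level` (Omega) must be positive: the spread rate is undefined ",
         "in a fully selfing population", call. = FALSE)
  }
  ic <- invasion_coefficients(scheme, "outcrossing", level)
  1 + delta_omega * (1 + ic$F) * q_hat * (1 - q_hat) *
    (ic$I_A + ic$I_a) / (2 * level)
}

#' Critical inbreeding depression for the stability of outcrossing
#'
#' Summing the transmission advantage of selfing with the genome-wide
#' inbreeding-depression cost gives net selection on a small outcrossing
#' modifier in an outcrossing population of `s_tot = delta_bar - (1 - c)/2`
#' per unit modifier effect.  Outcrossing is stable when genome-wide
#' inbreeding depression exceeds the returned threshold `(1 - c)/2`.
#'
#' @param c Pollen discounting in `[0, 1]`.
#' @return Critical genome-wide inbreeding depression (numeric, vectorised).
#' @examples
#' selfing_threshold(0)   # 0.5
#' selfing_threshold(0.5) # 0.25
#' @export
selfing_threshold <- function(c) {
  if (any(c < 0) || any(c > 1)) stop("`c` must be in [0, 1]", call. = FALSE)
  (1 - c) / 2
}
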