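#' Compound selection terms for a rare allele under a given mating system
#'
#' Collapses the per-stage fitness effects of a [fitness_scheme()] into the
#' three compound weak-selection terms that govern the spread of a rare
#' allele: selection through the female role, through the diploid male role,
#' and through male gametes.  Under the monandry-polyandry axis (`mode =
#' "polyandry"`, `level` = proportion polyandrous, Pi) mating is always
#' between individuals, so homozygous effects enter only via the common
#' genotype; under the selfing-outcrossing axis (`mode = "outcrossing"`,
#' `level` = proportion outcrossed, Omega) partial selfing generates excess
#' homozygosity `F = (1 - Omega)/(1 + Omega)`, which weights homozygous
#' fitnesses and tilts the female/male balance towards females.
#'
#' @param scheme A [fitness_scheme()].
#' @param mode `"polyandry"` (monandry-polyandry axis) or `"outcrossing"`
#'   (selfing-outcrossing axis).
#' @param level Proportion of polyandry (Pi) or outcrossing (Omega), in
#'   `[0, 1]`.
#' @return A tibble with one row per rare allele (`A`, `a`) and columns
#'   `s_bar_female`, `s_bar_male_diploid`, `s_bar_male_gametic`, plus the
#'   context (`mode`, `level`, `F`).
#' @examples
#' sch <- fitness_scheme(c(AA = 0, Aa = -0.01, aa = -0.05), sigma = 0.12, d = 0)
#' selection_terms(sch, "polyandry", level = 0)
#' @export
selection_terms <- function(scheme, mode = c("polyandry", "outcrossing"),
                            level) {
  stopifnot(inherits(scheme, "fitness_scheme"))
  mode <- match.arg(mode)
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level < 0 || level > 1) {
    stop("`level` must be a single number in [0, 1]", call. = FALSE)
  }
  sf <- scheme$s_female
  sm <- scheme$s_male
  g <- gamete_fitnesses(scheme)

  if (mode == "polyandry") {
    Pi <- level
    Fcoef <- 0
    out <- tibble::tibble(
      allele = c("A", "a"),
      s_bar_female = c(sf[["Aa"]] - sf[["aa"]], sf[["Aa"]] - sf[["AA"]]),
      s_bar_male_diploid = c(sm[["Aa"]] - sm[["aa"]], sm[["Aa"]] - sm[["AA"]]),
      s_bar_male_gametic = c(
        g$s_delta_Aa + Pi * (g$s_bar_Aa - g$s_a_aa),
        -g$s_delta_Aa + Pi * (g$s_bar_Aa - g$s_A_AA)
      )
    )
  } else {
    Om <- level
    Fcoef <- (1 - Om) / (1 + Om)
    out <- tibble::tibble(
      allele = c("A", "a"),
      s_bar_female = (2 - Om) * c(
        Fcoef * sf[["AA"]] + (1 - Fcoef) * sf[["Aa"]] - sf[["aa"]],
        Fcoef * sf[["aa"]] + (1 - Fcoef) * sf[["Aa"]] - sf[["AA"]]
      ),
      s_bar_male_diploid = Om * c(
        Fcoef * sm[["AA"]] + (1 - Fcoef) * sm[["Aa"]] - sm[["aa"]],
        Fcoef * sm[["aa"]] + (1 - Fcoef) * sm[["Aa"]] - sm[["AA"]]
      ),
      s_bar_male_gametic = Om * c(
        g$s_A_Aa - g$s_a_aa + Fcoef * (g$s_A_AA - g$s_a_Aa),
        g$s_a_Aa - g$s_A_AA + Fcoef * (g$s_a_aa - g$s_A_Aa)
      )
    )
  }
  out$mode <- mode
  out$level <- level
  out$F <- Fcoef
  out
}

#' Invasion coefficients for both alleles
#'
#' The per-generation weak-selection growth coefficient of a rare allele,
#' `I_alpha = s_bar_female/2 + (s_bar_male_diploid + s_bar_male_gametic)/2`.
#' A rare allele alpha spreads when `I_alpha > 0`; `I_A > 0` and `I_a > 0`
#' together indicate a protected polymorphism (balancing selection).
#'
#' @inheritParams selection_terms
#' @return A one-row tibble with columns `I_A`, `I_a`, `mode`, `level`, `F`.
#' @examples
#' sch <- fitness_scheme(c(AA = 0, Aa = -0.01, aa = -0.05), sigma = 0.12, d = 0)
#' invasion_coefficients(sch, "polyandry", level = 0) # I_a = -0.04
#' @export
invasion_coefficients <- function(scheme, mode = c("polyandry", "outcrossing"),
                                  level) {
  terms <- selection_terms(scheme, mode, level)
  I <- terms$s_bar_female / 2 +
    (terms$s_bar_male_diploid + terms$s_bar_male_gametic) / 2
  tibble::tibble(
    I_A = I[terms$allele == "A"],
    I_a = I[terms$allele == "a"],
    mode = terms$mode[1], level = terms$level[1], F = terms$F[1]
  )
}

#' Equilibrium frequency of a deleterious allele at mutation-selection balance
#'
#' `q_hat = mu / (-I_a)`: the balance between the mutational input of the
#' deleterious allele and its removal by selection when rare.  Valid for
#' `mu` much smaller than `|I_a|`.
#'
#' @param mu Per-locus mutation rate towards the deleterious allele.
#' @param I_a Invasion coefficient of the deleterious allele (must be
#'   negative; see [invasion_coefficients()]).
#' @return Equilibrium frequency (numeric, vectorised over `mu`).
#' @export
q_hat_msb <- function(mu, I_a) {
  if (any(mu < 0)) stop("`mu` must be non-negative", call. = FALSE)
  if (any(I_a >= 0)) {
    stop("`I_a` must be negative: the allele is not deleterious, ",
         "mutation-selection balance is undefined", call. = FALSE)
  }
  mu / (-I_a)
}

#' Equilibrium frequency of the a allele under balancing selection
#'
#' When both alleles invade when rare (`I_A > 0`, `I_a > 0`), the stable
#' polymorphic equilibrium frequency of a is `q_hat = I_a / (I_A + I_a)`,
#' balancing the rare-allele advantages.
#'
#' @param I_A,I_a Invasion coefficients of the two alleles (both positive).
#' @return Equilibrium frequency of the a allele.
#' @export
q_hat_balancing <- function(I_A, I_a) {
  if (any(I_A <= 0) || any(I_a <= 0)) {
    stop("both `I_A` and `I_a` must be positive: ",
         "no protected polymorphism", call. = FALSE)
  }
  I_a / (I_A + I_a)
}
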