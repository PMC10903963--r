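#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a two-locus equilibrium
#'
#' @param x A `two_locus_equilibrium` from [find_equilibrium()].
#' @param ... Unused.
#' @return The equilibrium genotype distribution as a tibble
#'   (`hap1`, `hap2`, `freq`).
#' @method tidy two_locus_equilibrium
#' @export
tidy.two_locus_equilibrium <- function(x, ...) {
  out <- tibble::as_tibble(x$state)
  attr(out, "G") <- NULL
  out
}

#' @rdname tidy.two_locus_equilibrium
#' @return `glance()`: a one-row tibble with `q_a`, `q_m`, `het_A`, `F_A`,
#'   `generations`, `converged`.
#' @method glance two_locus_equilibrium
#' @export
glance.two_locus_equilibrium <- function(x, ...) {
  dplyr::mutate(state_summary(x$state),
                generations = x$generations, converged = x$converged)
}

#' Tidy a numerical invasion fit
#'
#' @param x An `invasion_fit` from [numerical_invasion()] or
#'   [numerical_allele_growth()].
#' @param ... Unused.
#' @return The rare-allele frequency trajectory as a tibble.
#' @method tidy invasion_fit
#' @export
tidy.invasion_fit <- function(x, ...) x$trajectory

#' @rdname tidy.invasion_fit
#' @return `glance()`: a one-row tibble with `lambda`, `log_lambda`,
#'   `burn_in`, `window`.
#' @method glance invasion_fit
#' @export
glance.invasion_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, log_lambda = log(x$lambda),
                 burn_in = x$burn_in, window = x$window)
}

#' Tidy a multilocus simulation
#'
#' @param x A `gs_sim` from [simulate_population()].
#' @param ... Unused.
#' @return The per-measurement trajectory tibble (all replicates).
#' @method tidy gs_sim
#' @export
tidy.gs_sim <- function(x, ...) x$trajectory

#' @rdname tidy.gs_sim
#' @return `glance()`: replicate summaries averaged into a single row, with
#'   between/within-replicate CI half-widths.
#' @method glance gs_sim
#' @export
glance.gs_sim <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    load = mean(s$load), load_ci = mean(s$load_ci),
    delta = mean(s$delta), delta_ci = mean(s$delta_ci),
    q_msb_gam = mean(s$q_msb_gam), q_msb_nogam = mean(s$q_msb_nogam),
    q_bal = mean(s$q_bal), het = mean(s$het),
    replicates = nrow(s)
  )
}
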