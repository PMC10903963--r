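#' Plot a multilocus simulation trajectory
#'
#' Mutation load, inbreeding depression, and per-class allele frequencies
#' over time, one panel per statistic, coloured by replicate.
#'
#' @param object A `gs_sim` from [simulate_population()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gs_sim
#' @export
autoplot.gs_sim <- function(object, ...) {
  long <- object$trajectory |>
    tidyr::pivot_longer(
      cols = c("load", "delta", "q_msb_gam", "q_msb_nogam", "q_bal"),
      names_to = "statistic", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value,
                                     colour = factor(.data$replicate))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$statistic), scales = "free_y") +
    ggplot2::labs(colour = "replicate", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a numerical invasion trajectory
#'
#' Log modifier (or rare-allele) frequency against generation; the
#' asymptotic slope is the measured log growth rate.
#'
#' @param object An `invasion_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot invasion_fit
#' @export
autoplot.invasion_fit <- function(object, ...) {
  tr <- object$trajectory
  names(tr)[2] <- "freq"
  ggplot2::ggplot(tr, ggplot2::aes(.data$generation, log(.data$freq))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$burn_in, linetype = 3) +
    ggplot2::labs(y = "log rare-allele frequency") +
    ggplot2::theme_minimal()
}

#' @method autoplot gs_experiment
#' @export
autoplot.gs_experiment <- function(object, ...) {
  if (is.null(object$plot)) {
    stop("experiment `", object$id, "` has no associated plot", call. = FALSE)
  }
  object$plot
}
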