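# Reproducible experiment sweeps tying the analytic machinery, the exact
# two-locus engine, and the multilocus simulator together.

EXPERIMENT_IDS <- c("load_sweep", "polyandry_surface", "depression_sweep",
                    "balancing_sweep", "modifier_sweep",
                    "depression_sigma_sweep", "invasion_check", "simulate")

#' Run a named experiment sweep
#'
#' Each experiment evaluates the analytic pipeline over a parameter grid
#' (optionally adding individual-based simulation points) and returns a tidy
#' table plus a ggplot:
#'
#' * `load_sweep`: genome-wide mutation load against the mating-system level
#'   (Pi or Omega per `mode`) for several strengths of gametic selection.
#' * `polyandry_surface`: net selection `s_tot` on a full-effect polyandry
#'   modifier over a grid of genome-wide mutation rate `U` and number of
#'   balancing-selection loci `l_B`.
#' * `depression_sweep`: genome-wide inbreeding depression against the
#'   fraction `k` of loci under gametic selection.
#' * `balancing_sweep`: equilibrium frequency of the gamete-beneficial A
#'   allele under ploidally antagonistic balancing selection across mating
#'   systems.
#' * `modifier_sweep`: per-locus modifier selection `lambda - 1` against the
#'   gametic expression pattern `d`, for both axes and both maintenance
#'   regimes (full pollen discounting).
#' * `depression_sigma_sweep`: inbreeding depression against `sigma` for
#'   several `U`, with the outcrossing-stability thresholds.
#' * `invasion_check`: the six-scenario direction-of-evolution matrix,
#'   via the analytic spread rates and (optionally) the numerical invasion
#'   oracle.
#' * `simulate`: a single simulator run from the supplied `sim_config`.
#'
#' @param id Experiment name (see above).
#' @param mode Mating-system axis for experiments that sweep it.
#' @param simulate Add individual-based simulation points (slow).
#' @param numerical For `invasion_check`: verify signs with the exact
#'   two-locus engine as well.
#' @param config A [sim_config()] (for `id = "simulate"`).
#' @param U,sigma_values,k_values,level_values,l_B_values,d_values Grid
#'   axes; defaults mirror the package's worked examples.
#' @param scale `"desk"` (N = 500, L = 50, 5000 generations, 2 replicates)
#'   or `"paper"` (N = 5000, L = 100, 50000 generations, 3 replicates) for
#'   simulation points.
#' @param seed Integer seed for any stochastic component.
#' @param out_dir Optional directory: results are written as TSV plus a
#'   JSON sidecar recording the experiment id, seed, and a config hash.
#' @return A list of class `gs_experiment` with elements `id`, `result`
#'   (tibble), `plot` (ggplot or NULL), `seed`, `hash`.
#' @export
run_experiment <- function(id, mode = c("polyandry", "outcrossing"),
                           simulate = FALSE, numerical = FALSE,
                           config = NULL, U = 0.5,
                           sigma_values = c(0, 0.04, 0.08, 0.12),
                           k_values = seq(0, 1, by = 0.1),
                           level_values = seq(0, 1, by = 0.1),
                           l_B_values = 0:20,
                           d_values = seq(0, 1, by = 0.1),
                           scale = c("desk", "paper"),
                           seed = 1, out_dir = NULL) {
  id <- match.arg(id, EXPERIMENT_IDS)
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  sc <- if (scale == "desk") {
    list(N = 500, L = 50, generations = 5000, replicates = 2)
  } else {
    list(N = 5000, L = 100, generations = 50000, replicates = 3)
  }
  res <- switch(
    id,
    load_sweep = exp_load_sweep(mode, U, sigma_values, level_values,
                                simulate, sc, seed),
    polyandry_surface = exp_polyandry_surface(l_B_values),
    depression_sweep = exp_depression_sweep(U, sigma_values, k_values,
                                            simulate, sc, seed),
    balancing_sweep = exp_balancing_sweep(mode, sigma_values, level_values),
    modifier_sweep = exp_modifier_sweep(d_values),
    depression_sigma_sweep = exp_depression_sigma_sweep(),
    invasion_check = invasion_direction_check(numerical = numerical),
    simulate = {
      if (is.null(config)) stop("`config` is required", call. = FALSE)
      sim <- simulate_population(config)
      list(result = tidy(sim), plot = autoplot(sim))
    }
  )
  out <- structure(
    list(id = id, result = res$result, plot = res$plot, seed = seed,
         hash = rlang::hash(list(id, mode, U, sigma_values, k_values,
                                 level_values, l_B_values, d_values, seed))),
    class = "gs_experiment"
  )
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' @export
print.gs_experiment <- function(x, ...) {
  cat("<gs_experiment>", x$id, "(seed", paste0(x$seed, ","),
      "hash", paste0(x$hash, ")\n"))
  print(x$result)
  invisible(x)
}

write_experiment <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x$result, file.path(out_dir, paste0(x$id, ".tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(id = x$id, seed = x$seed, hash = x$hash,
         package_version = as.character(utils::packageVersion("gameticsel"))),
    file.path(out_dir, paste0(x$id, "_meta.json")), auto_unbox = TRUE)
  if (!is.null(x$plot)) {
    ggplot2::ggsave(file.path(out_dir, paste0(x$id, ".png")), x$plot,
                    width = 7, height = 5, dpi = 150)
  }
  invisible(x)
}

exp_load_sweep <- function(mode, U, sigma_values, level_values,
                           simulate, sc, seed) {
  grid <- tidyr::expand_grid(sigma = sigma_values, level = level_values)
  grid$load <- purrr::pmap_dbl(grid, function(sigma, level) {
    gs <- genome_spec(scheme_deleterious(sigma = sigma), mode, level, U = U)
    genome_summary(gs)$load
  })
  grid$source <- "analytic"
  if (simulate) {
    sim_grid <- tidyr::expand_grid(sigma = range(sigma_values),
                                   level = c(0, 0.5, 1))
    sims <- purrr::pmap(sim_grid, function(sigma, level) {
      cfg <- sim_config(N = sc$N, L = sc$L,
                        msb_scheme = scheme_deleterious(sigma = sigma),
                        mode = mode, level = level, U = U,
                        generations = sc$generations,
                        replicates = sc$replicates, seed = seed)
      glance(simulate_population(cfg))
    })
    sim_grid$load <- purrr::map_dbl(sims, "load")
    sim_grid$load_ci <- purrr::map_dbl(sims, "load_ci")
    sim_grid$source <- "simulation"
    grid <- dplyr::bind_rows(grid, sim_grid)
  }
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$level, .data$load,
                                          colour = factor(.data$sigma))) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$source == "analytic")) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$source == "simulation")) +
    ggplot2::labs(
      x = if (mode == "polyandry") "proportion polyandrous" else
        "proportion outcrossed",
      y = "mutation load", colour = "sigma") +
    ggplot2::theme_minimal()
  list(result = grid, plot = p)
}

exp_polyandry_surface <- function(l_B_values,
                                  U_values = seq(0, 1, by = 0.05)) {
  grid <- tidyr::expand_grid(U = U_values, l_B = l_B_values)
  grid$s_tot <- purrr::pmap_dbl(grid, function(U, l_B) {
    gs <- genome_spec(scheme_deleterious(), "polyandry", level = 0,
                      U = U, k = 1, l_B = l_B,
                      balancing_scheme = scheme_antagonistic())
    genome_summary(gs, delta_mod = 0.5)$s_tot
  })
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$U, .data$l_B,
                                          fill = .data$s_tot)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "purple4", mid = "white",
                                  high = "darkgreen", midpoint = 0) +
    ggplot2::labs(x = "genome-wide deleterious mutation rate U",
                  y = "balancing-selection loci",
                  fill = "s_tot") +
    ggplot2::theme_minimal()
  list(result = grid, plot = p)
}

exp_depression_sweep <- function(U, sigma_values, k_values,
                                 simulate, sc, seed) {
  grid <- tidyr::expand_grid(sigma = setdiff(sigma_values, 0), k = k_values)
  grid$delta_bar <- purrr::pmap_dbl(grid, function(sigma, k) {
    gs <- genome_spec(scheme_deleterious(sigma = sigma), "outcrossing",
                      level = 1, U = U, k = k)
    genome_summary(gs)$delta_bar
  })
  baseline <- genome_summary(
    genome_spec(scheme_deleterious(sigma = 0), "outcrossing", 1, U = U))
  grid$source <- "analytic"
  if (simulate) {
    sim_grid <- tidyr::expand_grid(sigma = max(sigma_values), k = c(0, 0.5, 1))
    sims <- purrr::pmap(sim_grid, function(sigma, k) {
      cfg <- sim_config(N = sc$N, L = sc$L,
                        msb_scheme = scheme_deleterious(sigma = sigma),
                        mode = "outcrossing", level = 1, k = k, U = U,
                        generations = sc$generations,
                        replicates = sc$replicates, seed = seed)
      glance(simulate_population(cfg))
    })
    sim_grid$delta_bar <- purrr::map_dbl(sims, "delta")
    sim_grid$delta_ci <- purrr::map_dbl(sims, "delta_ci")
    sim_grid$source <- "simulation"
    grid <- dplyr::bind_rows(grid, sim_grid)
  }
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$k, .data$delta_bar,
                                          colour = factor(.data$sigma))) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$source == "analytic")) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$source == "simulation")) +
    ggplot2::geom_hline(yintercept = baseline$delta_bar, linetype = 2) +
    ggplot2::geom_hline(yintercept = selfing_threshold(0), colour = "grey40") +
    ggplot2::labs(x = "fraction of loci under gametic selection (k)",
                  y = "inbreeding depression", colour = "sigma") +
    ggplot2::theme_minimal()
  list(result = grid, plot = p, baseline = baseline$delta_bar)
}

exp_balancing_sweep <- function(mode, sigma_values, level_values) {
  grid <- tidyr::expand_grid(sigma = sigma_values, level = level_values)
  grid$p_A <- purrr::pmap_dbl(grid, function(sigma, level) {
    sch <- scheme_antagonistic_mild(sigma = sigma)
    ic <- invasion_coefficients(sch, mode, level)
    if (ic$I_A <= 0) return(0) # a fixes
    if (ic$I_a <= 0) return(1) # A fixes
    1 - q_hat_balancing(ic$I_A, ic$I_a)
  })
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$level, .data$p_A,
                                          colour = factor(.data$sigma))) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (mode == "polyandry") "proportion polyandrous" else
        "proportion outcrossed",
      y = "equilibrium frequency of gamete-beneficial allele",
      colour = "sigma") +
    ggplot2::theme_minimal()
  list(result = grid, plot = p)
}

exp_modifier_sweep <- function(d_values, level = 0.5, mu = 1e-5) {
  grid <- tidyr::expand_grid(
    d = d_values,
    axis = c("polyandry", "outcrossing"),
    regime = c("mutation-selection balance", "balancing selection")
  )
  grid$lambda_minus_1 <- purrr::pmap_dbl(grid, function(d, axis, regime) {
    if (regime == "mutation-selection balance") {
      sch <- scheme_deleterious(d = d)
      ic <- invasion_coefficients(sch, axis, level)
      q <- q_hat_msb(mu, ic$I_a)
      if (axis == "polyandry") {
        lambda_polyandry_msb(sch, level, delta_pi = 0.05, q_hat = q) - 1
      } else {
        lambda_selfing_msb(sch, level, delta_omega = 0.05, q_hat = q) - 1
      }
    } else {
      sch <- scheme_antagonistic(d = d)
      ic <- invasion_coefficients(sch, axis, level)
      if (ic$I_A <= 0 || ic$I_a <= 0) return(NA_real_)
      q <- q_hat_balancing(ic$I_A, ic$I_a)
      if (axis == "polyandry") {
        lambda_polyandry_balancing(sch, delta_pi = 0.05, q_hat = q) - 1
      } else {
        lambda_selfing_balancing(sch, level, delta_omega = 0.05,
                                 q_hat = q) - 1
      }
    }
  })
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$d, .data$lambda_minus_1,
                                          colour = .data$regime)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$axis), scales = "free_y") +
    ggplot2::labs(x = "gametic expression pattern d",
                  y = "modifier selection (lambda - 1)") +
    ggplot2::theme_minimal()
  list(result = grid, plot = p)
}

exp_depression_sigma_sweep <- function(U_values = c(0.25, 0.5, 1),
                                       sigma_values = seq(0, 0.1, 0.01)) {
  grid <- tidyr::expand_grid(U = U_values, sigma = sigma_values)
  grid$delta_bar <- purrr::pmap_dbl(grid, function(U, sigma) {
    gs <- genome_spec(scheme_deleterious(sigma = sigma), "outcrossing",
                      level = 1, U = U, k = 1)
    genome_summary(gs)$delta_bar
  })
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$sigma, .data$delta_bar,
                                          colour = factor(.data$U))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = selfing_threshold(0), colour = "grey60") +
    ggplot2::geom_hline(yintercept = selfing_threshold(0.5),
                        colour = "grey30") +
    ggplot2::labs(x = "strength of gametic selection (sigma)",
                  y = "inbreeding depression", colour = "U") +
    ggplot2::theme_minimal()
  list(result = grid, plot = p)
}

#' Direction-of-evolution check across maintenance regimes
#'
#' Evaluates the six canonical scenarios - modifier axis x how variation is
#' maintained - and reports the predicted direction of mating-system
#' evolution from the analytic spread rates, optionally confirmed by the
#' exact two-locus numerical invasion oracle.
#'
#' @param numerical Also run the engine oracle (slower).
#' @param mu Mutation rate for the mutation-selection-balance rows.
#' @return A list with `result`: a tibble with one row per scenario and
#'   columns `axis`, `regime`, `lambda_analytic` (for a modifier increasing
#'   polyandry/outcrossing), `direction`, and (with `numerical`)
#'   `lambda_numerical`.
#' @export
invasion_direction_check <- function(numerical = FALSE, mu = 1e-4) {
  rows <- list(
    list(axis = "polyandry", regime = "mutation-selection balance",
         scheme = scheme_deleterious(), level = 0.5),
    list(axis = "polyandry", regime = "balancing selection",
         scheme = scheme_antagonistic(), level = 0.5),
    list(axis = "polyandry", regime = "balancing selection (diploid expression)",
         scheme = scheme_antagonistic(d = 1), level = 0.5),
    list(axis = "outcrossing", regime = "mutation-selection balance (recessive)",
         scheme = scheme_deleterious(), level = 0.8),
    list(axis = "outcrossing", regime = "mutation-selection balance (dominant)",
         scheme = fitness_scheme(c(AA = 0, Aa = -0.045, aa = -0.05),
                                 sigma = 0.12, d = 0), level = 0.8),
    list(axis = "outcrossing", regime = "balancing selection",
         scheme = scheme_overdominant(), level = 0.8)
  )
  eff <- 0.1 # modifier increases the level by this much (dominant)
  out <- purrr::map(rows, function(r) {
    msb <- grepl("mutation-selection", r$regime)
    bal_diploid <- grepl("diploid", r$regime)
    ic <- invasion_coefficients(r$scheme, r$axis, r$level)
    lam <- if (r$axis == "polyandry") {
      dp <- eff / 2
      if (msb) {
        lambda_polyandry_msb(r$scheme, r$level, dp, q_hat_msb(mu, ic$I_a))
      } else {
        lambda_polyandry_balancing(r$scheme, dp,
                                   q_hat_balancing(ic$I_A, ic$I_a))
      }
    } else {
      q <- if (msb) q_hat_msb(mu, ic$I_a) else
        q_hat_balancing(ic$I_A, ic$I_a)
      if (msb) {
        lambda_selfing_msb(r$scheme, r$level, eff, q)
      } else {
        lambda_selfing_balancing(r$scheme, r$level, eff, q)
      }
    }
    lam_num <- NA_real_
    if (numerical) {
      mod <- modifier_scheme(r$axis, level_MM = r$level,
                             level_Mm = r$level + eff, c = 1)
      fit <- numerical_invasion(r$scheme, mod, mu = if (msb) mu else 0,
                                q_init = 1e-10, burn_in = 4000,
                                window = 2000)
      lam_num <- fit$lambda
    }
    neutral_tol <- 1e-6
    dir_of <- function(l) {
      if (bal_diploid && abs(l - 1) < neutral_tol) return("neutral")
      if (r$axis == "polyandry") {
        if (l > 1) "polyandry favoured" else if (l < 1) "monandry favoured"
        else "neutral"
      } else {
        if (l > 1) "outcrossing favoured" else if (l < 1) "selfing favoured"
        else "neutral"
      }
    }
    tibble::tibble(
      axis = r$axis, regime = r$regime,
      lambda_analytic = lam, lambda_numerical = lam_num,
      direction = dir_of(if (numerical) lam_num else lam)
    )
  })
  list(result = dplyr::bind_rows(out), plot = NULL)
}

#' Validate the toolkit's headline predictions
#'
#' Recomputes the desk-checkable quantities from scratch - the net selection
#' coefficient on a full-effect polyandry modifier in a monandrous genome
#' (`U = 1`, gametic selection at every locus), the transmission advantage
#' of a dominant full-selfing modifier without pollen discounting, and the
#' critical inbreeding depression stabilising outcrossing - and reports them
#' against their expected values.
#'
#' @param seed Unused (the checks are deterministic); kept for interface
#'   symmetry with [run_experiment()].
#' @return A tibble with columns `check`, `value`, `expected`, `pass`.
#' @export
validate_predictions <- function(seed = 1) {
  gs <- genome_spec(scheme_deleterious(), "polyandry", level = 0, U = 1, k = 1)
  s_tot <- genome_summary(gs, delta_mod = 0.5)$s_tot
  adv <- abs(lambda_selfing_leading(delta_omega = -1, c = 0, level = 1) - 1)
  thr <- selfing_threshold(0)
  tibble::tibble(
    check = c("net selection on full polyandry modifier (U = 1, monandrous)",
              "selfing transmission advantage at c = 0 (%)",
              "critical inbreeding depression at c = 0"),
    value = c(s_tot, 100 * adv, thr),
    expected = c(0.015, 50, 0.5),
    pass = abs(value - expected) <=
      c(5e-4, 1e-9, 1e-12)
  )
}
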