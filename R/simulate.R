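# Individual-based Wright-Fisher forward simulator of N diploid
# hermaphrodites with L unlinked loci, multiplicative fitness across loci,
# and explicit competition among male gametes.  Mothers are sampled with
# replacement in proportion to female fitness (soft selection, constant N).
# Each fertilisation event draws a pool of `gamete_ratio` male gametes from
# the source dictated by the mating system (population-wide for
# polyandry/outcrossing, a single designated mate for monandry, the mother
# herself for selfing); the pool competes by multiplicative gametic fitness
# and one gamete fertilises the egg.  Mutation is one-way A -> a at rate mu
# per locus per gamete, applied after gamete competition.

#' Configuration for the multilocus simulator
#'
#' @param N Diploid population size.
#' @param L Number of unlinked loci.
#' @param msb_scheme [fitness_scheme()] for deleterious-mutation loci; its
#'   `sigma` applies to the gametic-selected fraction `k`.
#' @param mode,level Mating system, as in [selection_terms()] (`level` is
#'   Pi or Omega).
#' @param k Fraction of mutation-selection-balance loci under gametic
#'   selection.
#' @param l_B Number of balancing-selection loci.
#' @param balancing_scheme [fitness_scheme()] for balancing loci (required
#'   when `l_B > 0`); they receive no recurrent mutation and start at their
#'   analytic equilibrium frequency.
#' @param U Haploid genome-wide deleterious mutation rate; the per-locus
#'   rate is `U / (L - l_B)` unless `mu` is given directly.
#' @param mu Per-locus mutation rate (overrides `U`).
#' @param gamete_ratio Male gametes competing per fertilisation event.
#' @param generations Generations to simulate.
#' @param stat_window Final generations over which summary statistics are
#'   averaged.
#' @param measure_every Interval (generations) between statistics records.
#' @param replicates Independent replicates.
#' @param seed Integer seed; replicate `i` uses `seed + i - 1` and locus
#'   class placement uses `seed` itself.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(N = 500, L = 50, msb_scheme,
                       mode = c("polyandry", "outcrossing"), level = 1,
                       k = 1, l_B = 0, balancing_scheme = NULL,
                       U = 0.5, mu = NULL, gamete_ratio = 10,
                       generations = 5000, stat_window = 1000,
                       measure_every = 20, replicates = 1, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(msb_scheme, "fitness_scheme"),
            N > 0, L > 0, l_B >= 0, l_B < L, k >= 0, k <= 1,
            gamete_ratio >= 1, generations > 0,
            stat_window <= generations)
  if (l_B > 0 && !inherits(balancing_scheme, "fitness_scheme")) {
    stop("`balancing_scheme` is required when `l_B` > 0", call. = FALSE)
  }
  if (is.null(mu)) mu <- U / (L - l_B)
  structure(
    list(N = as.integer(N), L = as.integer(L), msb_scheme = msb_scheme,
         mode = mode, level = level, k = k, l_B = as.integer(l_B),
         balancing_scheme = balancing_scheme, mu = mu,
         gamete_ratio = as.integer(gamete_ratio),
         generations = as.integer(generations),
         stat_window = as.integer(stat_window),
         measure_every = as.integer(measure_every),
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# locus bookkeeping: class 1 = MSB with gametic selection, 2 = MSB without,
# 3 = balancing.  Placement along the genome is uniform at random (no
# dynamical effect with free recombination; retained for protocol fidelity).
assign_locus_classes <- function(config) {
  set.seed(config$seed)
  L <- config$L
  n_msb <- L - config$l_B
  n_gam <- round(config$k * n_msb)
  classes <- integer(L)
  pos <- sample.int(L)
  classes[pos[seq_len(config$l_B)]] <- 3L
  msb_pos <- pos[config$l_B + seq_len(n_msb)]
  classes[msb_pos[seq_len(n_gam)]] <- 1L
  classes[classes == 0L] <- 2L
  classes
}

# per-locus lookup tables (log scale) for adult and gametic fitness
build_locus_tables <- function(config, classes) {
  schemes <- list(config$msb_scheme, strip_gametic(config$msb_scheme),
                  config$balancing_scheme)
  L <- config$L
  lwf <- matrix(0, 3, L) # rows: genotype a-count 0,1,2
  lwm <- matrix(0, 3, L)
  lg <- matrix(0, 6, L)  # rows: father geno * 2 + gamete allele (0-indexed)
  for (l in seq_len(L)) {
    sch <- schemes[[classes[l]]]
    lwf[, l] <- log(1 + sch$s_female)
    lwm[, l] <- log(1 + sch$s_male)
    g <- gamete_fitnesses(sch)
    # combos: (0,A) (0,a) (1,A) (1,a) (2,A) (2,a); mutants arise post-choice
    lg[, l] <- log(c(g$w_A_AA, g$w_A_AA, g$w_A_Aa, g$w_a_Aa,
                     g$w_a_aa, g$w_a_aa))
  }
  list(lwf = lwf, lwm = lwm, lg = lg,
       mu_loc = ifelse(classes == 3L, 0, config$mu))
}

row_log_lookup <- function(tab, idx_mat) {
  # tab: k x L; idx_mat: n x L of 0-based row indices
  n <- nrow(idx_mat)
  L <- ncol(idx_mat)
  k <- nrow(tab)
  v <- tab[c(idx_mat) + 1L + k * rep(0:(L - 1L), each = n)]
  rowSums(matrix(v, n, L))
}

draw_gametes <- function(h1, h2, rows) {
  n <- length(rows)
  L <- ncol(h1)
  g <- h1[rows, , drop = FALSE]
  alt <- h2[rows, , drop = FALSE]
  coin <- matrix(stats::runif(n * L) < 0.5, n, L)
  g[coin] <- alt[coin]
  g
}

mutate_gametes <- function(g, mu_loc) {
  n <- nrow(g)
  hit <- matrix(stats::runif(n * ncol(g)) <
                  rep(mu_loc, each = n), n, ncol(g))
  g[hit & g == 0L] <- 1L
  g
}

# draw one fitness-weighted sperm per offspring from pools of size K whose
# fathers are given by the n x K matrix `fathers`
competitive_sperm <- function(h1, h2, fathers, tabs) {
  n <- nrow(fathers)
  K <- ncol(fathers)
  fa <- c(fathers)
  sp <- draw_gametes(h1, h2, fa)
  fgeno <- h1[fa, , drop = FALSE] + h2[fa, , drop = FALSE]
  lgw <- row_log_lookup(tabs$lg, fgeno * 2L + sp)
  W <- matrix(exp(lgw), n, K)
  cum <- W %*% upper.tri(diag(K), diag = TRUE)
  u <- stats::runif(n) * cum[, K]
  pick <- K + 1L - rowSums(cum >= u)
  sp[(pick - 1L) * n + seq_len(n), , drop = FALSE]
}

sim_replicate <- function(config, tabs, classes, rep_seed) {
  set.seed(rep_seed)
  N <- config$N
  L <- config$L
  K <- config$gamete_ratio
  mode <- config$mode
  level <- config$level

  # founders: MSB loci mutation-free, balancing loci at the analytic
  # equilibrium (Hardy-Weinberg draw)
  q0 <- numeric(L)
  if (config$l_B > 0) {
    ic <- invasion_coefficients(config$balancing_scheme, mode, level)
    q0[classes == 3L] <- q_hat_balancing(ic$I_A, ic$I_a)
  }
  h1 <- matrix(stats::rbinom(N * L, 1L, rep(q0, each = N)), N, L)
  h2 <- matrix(stats::rbinom(N * L, 1L, rep(q0, each = N)), N, L)

  stats_rows <- list()
  for (gen in seq_len(config$generations)) {
    geno <- h1 + h2
    wf <- exp(row_log_lookup(tabs$lwf, geno))
    wm <- exp(row_log_lookup(tabs$lwm, geno))

    mothers <- sample.int(N, N, replace = TRUE, prob = wf)
    egg <- draw_gametes(h1, h2, mothers)

    fathers <- matrix(sample.int(N, N * K, replace = TRUE, prob = wm), N, K)
    if (mode == "polyandry") {
      mono <- stats::runif(N) < (1 - level) # per successful mother
      mate <- sample.int(N, N, replace = TRUE, prob = wm)
      is_mono <- mono[mothers]
      fathers[is_mono, ] <- mate[mothers[is_mono]]
    } else {
      is_self <- stats::runif(N) < (1 - level) # per female gamete
      fathers[is_self, ] <- mothers[is_self]
    }
    sperm <- competitive_sperm(h1, h2, fathers, tabs)

    egg <- mutate_gametes(egg, tabs$mu_loc)
    sperm <- mutate_gametes(sperm, tabs$mu_loc)

    measure <- gen %% config$measure_every == 0L || gen == config$generations
    if (measure) {
      off_geno <- egg + sperm
      w_off <- (exp(row_log_lookup(tabs$lwf, off_geno)) +
                  exp(row_log_lookup(tabs$lwm, off_geno))) / 2
      # parallel selfed cohort from the same mothers, within-self competition
      egg_s <- draw_gametes(h1, h2, mothers)
      sperm_s <- competitive_sperm(h1, h2,
                                   matrix(mothers, N, K), tabs)
      self_geno <- mutate_gametes(egg_s, tabs$mu_loc) +
        mutate_gametes(sperm_s, tabs$mu_loc)
      w_self <- (exp(row_log_lookup(tabs$lwf, self_geno)) +
                   exp(row_log_lookup(tabs$lwm, self_geno))) / 2
      q_class <- vapply(1:3, function(cl) {
        sel <- classes == cl
        if (!any(sel)) return(NA_real_)
        mean(off_geno[, sel]) / 2
      }, numeric(1))
      het <- mean(off_geno == 1L)
      stats_rows[[length(stats_rows) + 1L]] <- tibble::tibble(
        generation = gen,
        mean_fitness = mean(w_off),
        load = 1 - mean(w_off),
        delta = 1 - mean(w_self) / mean(w_off),
        q_msb_gam = q_class[1], q_msb_nogam = q_class[2], q_bal = q_class[3],
        het = het
      )
    }
    h1 <- egg
    h2 <- sperm
  }
  traj <- dplyr::bind_rows(stats_rows)
  list(trajectory = traj, h1 = h1, h2 = h2)
}

#' Run the multilocus simulator
#'
#' @param config A [sim_config()].
#' @return An object of class `gs_sim`: a list with `trajectory` (tibble of
#'   per-measurement statistics for every replicate), `summary` (one row per
#'   replicate, time-averaged over the final `stat_window` generations, with
#'   normal-theory 95% CI half-widths), `config`, and the final haplotype
#'   matrices of the last replicate (`h1`, `h2`).  Supports
#'   [generics::tidy()], [generics::glance()], and [ggplot2::autoplot()].
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  classes <- assign_locus_classes(config)
  tabs <- build_locus_tables(config, classes)
  reps <- purrr::map(seq_len(config$replicates), function(i) {
    sim_replicate(config, tabs, classes, rep_seed = config$seed + i - 1L)
  })
  trajectory <- purrr::imap(reps, function(r, i) {
    dplyr::mutate(r$trajectory, replicate = i)
  })
  trajectory <- dplyr::bind_rows(trajectory)
  cut <- config$generations - config$stat_window
  summarise_rep <- function(df) {
    win <- df[df$generation > cut, ]
    n <- nrow(win)
    ci <- function(x) 1.96 * stats::sd(x) / sqrt(max(n, 2))
    tibble::tibble(
      load = mean(win$load), load_ci = ci(win$load),
      delta = mean(win$delta), delta_ci = ci(win$delta),
      q_msb_gam = mean(win$q_msb_gam), q_msb_nogam = mean(win$q_msb_nogam),
      q_bal = mean(win$q_bal), het = mean(win$het), n_measurements = n
    )
  }
  summary <- trajectory |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(~summarise_rep(.x)) |>
    dplyr::ungroup()
  structure(
    list(trajectory = trajectory, summary = summary, config = config,
         classes = classes, h1 = reps[[length(reps)]]$h1,
         h2 = reps[[length(reps)]]$h2),
    class = "gs_sim"
  )
}

#' Measure inbreeding depression from a simulated population
#'
#' Re-applies the measurement protocol to the final stored population of a
#' simulation: mothers are sampled by female fitness; a normally mated
#' cohort and a selfed cohort (within-individual gamete competition) are
#' produced, and `delta = 1 - mean(w_selfed) / mean(w_mated)`.
#'
#' @param sim A `gs_sim` from [simulate_population()].
#' @param seed Integer seed for the measurement draws.
#' @return Inbreeding depression estimate (numeric scalar).
#' @export
measure_inbreeding_depression <- function(sim, seed = 1) {
  stopifnot(inherits(sim, "gs_sim"))
  config <- sim$config
  tabs <- build_locus_tables(config, sim$classes)
  set.seed(seed)
  N <- config$N
  K <- config$gamete_ratio
  h1 <- sim$h1
  h2 <- sim$h2
  geno <- h1 + h2
  wf <- exp(row_log_lookup(tabs$lwf, geno))
  wm <- exp(row_log_lookup(tabs$lwm, geno))
  mothers <- sample.int(N, N, replace = TRUE, prob = wf)
  w_mean <- function(fathers) {
    egg <- draw_gametes(h1, h2, mothers)
    sperm <- competitive_sperm(h1, h2, fathers, tabs)
    off <- egg + sperm
    mean((exp(row_log_lookup(tabs$lwf, off)) +
            exp(row_log_lookup(tabs$lwm, off))) / 2)
  }
  out <- w_mean(matrix(sample.int(N, N * K, replace = TRUE, prob = wm), N, K))
  self <- w_mean(matrix(mothers, N, K))
  1 - self / out
}

#' @export
print.gs_sim <- function(x, ...) {
  cat("<gs_sim>", x$config$replicates, "replicate(s),",
      x$config$generations, "generations, N =", x$config$N,
      ", L =", x$config$L, "\n")
  print(x$summary)
  invisible(x)
}
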