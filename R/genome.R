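# Genome-wide extrapolation: mutation load, inbreeding depression, and net
# selection on mating-system modifiers, assuming loosely linked loci with
# multiplicative, non-epistatic fitness so per-locus equilibria compose.

# Zygote genotype frequencies at allele frequency q with excess homozygosity F.
genotype_freqs <- function(q, F = 0) {
  p <- 1 - q
  c(AA = p^2 + F * p * q, Aa = 2 * p * q * (1 - F), aa = q^2 + F * p * q)
}

# Mean adult fitness (sex-role average) relative to the AA genotype.
per_locus_mean_fitness <- function(scheme, q, F = 0) {
  f <- genotype_freqs(q, F)
  w <- 1 + (scheme$s_female + scheme$s_male) / 2
  sum(f * w) / w[["AA"]]
}

#' Per-locus inbreeding depression at equilibrium
#'
#' `delta = 1 - w_bar_s / w_bar_o`, comparing the mean adult fitness of
#' selfed versus outcrossed offspring of the same mothers.  Mothers are
#' drawn in proportion to female fitness from the zygote genotype
#' distribution at frequency `q_hat` (with excess homozygosity `F`).
#' Outcrossed sperm come from the population-wide male gamete pool (fathers
#' weighted by male fitness, gametes competing by gametic fitness); selfed
#' sperm compete only within the mother's own gamete pool, so gametic
#' selection is blunted for selfed offspring of heterozygotes whenever
#' expression is not fully haploid-symmetric.
#'
#' @param scheme A [fitness_scheme()].
#' @param q_hat Equilibrium frequency of the a allele.
#' @param F Excess homozygosity at the locus (0 under full outcrossing).
#' @return Inbreeding depression `delta` (numeric scalar).
#' @export
per_locus_inbreeding_depression <- function(scheme, q_hat, F = 0) {
  stopifnot(inherits(scheme, "fitness_scheme"))
  f <- genotype_freqs(q_hat, F)
  wf <- 1 + scheme$s_female
  wm <- 1 + scheme$s_male
  w_off <- (wf + wm) / 2
  if (sum(f * wf) <= 0) stop("degenerate female fitness", call. = FALSE)
  p_mother <- f * wf / sum(f * wf)

  # rows: mother/father genotype AA, Aa, aa; cols: gamete allele A, a
  egg <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))
  g <- gamete_fitnesses(scheme)
  sperm_out <- rbind(
    c(g$w_A_AA, 0),
    c(g$w_A_Aa / 2, g$w_a_Aa / 2),
    c(0, g$w_a_aa)
  )
  pool <- colSums(f * wm * sperm_out)
  pool <- pool / sum(pool)
  sperm_self <- sperm_out / rowSums(sperm_out)

  # offspring fitness by (egg allele, sperm allele)
  W <- matrix(w_off[c(1, 2, 2, 3)], 2, 2)
  w_o <- sum(p_mother * as.vector((egg %*% W) %*% pool))
  w_s <- sum(p_mother * rowSums((egg %*% W) * sperm_self))
  1 - w_s / w_o
}

#' Genome-scale composition for load, inbreeding depression, and net
#' modifier selection
#'
#' Describes a genome of unlinked, multiplicatively acting loci: deleterious
#' mutations arise at genome-wide (haploid) rate `U` across the
#' mutation-selection-balance loci, a fraction `k` of which experience
#' gametic selection (the remainder use the same adult coefficients with
#' `sigma = 0`), plus `l_B` loci maintained polymorphic by balancing
#' selection.  `mu` is the nominal per-locus mutation rate used to evaluate
#' per-locus equilibria; genome-wide results depend on it only through
#' higher-order terms because mutation-selection-balance contributions scale
#' with `U = mu * l_mu`.
#'
#' @param msb_scheme [fitness_scheme()] for loci at mutation-selection
#'   balance (its `sigma` applies to the gametic-selected fraction `k`).
#' @param mode,level Mating-system context as in [selection_terms()].
#' @param U Haploid genome-wide deleterious mutation rate.
#' @param k Fraction of mutation-selection-balance loci under gametic
#'   selection.
#' @param l_B Number of balancing-selection loci.
#' @param balancing_scheme [fitness_scheme()] for balancing-selection loci
#'   (required when `l_B > 0`).
#' @param c Pollen discounting (used for selfing-modifier summaries).
#' @param mu Nominal per-locus mutation rate.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(msb_scheme, mode = c("polyandry", "outcrossing"),
                        level, U, k = 1, l_B = 0, balancing_scheme = NULL,
                        c = 1, mu = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(msb_scheme, "fitness_scheme"), U >= 0,
            k >= 0, k <= 1, l_B >= 0, mu > 0, mu < 1)
  if (l_B > 0 && !inherits(balancing_scheme, "fitness_scheme")) {
    stop("`balancing_scheme` is required when `l_B` > 0", call. = FALSE)
  }
  structure(
    list(msb_scheme = msb_scheme, mode = mode, level = level, U = U, k = k,
         l_B = l_B, balancing_scheme = balancing_scheme, c = c, mu = mu),
    class = "genome_spec"
  )
}

# scheme with gametic selection switched off
strip_gametic <- function(scheme) {
  fitness_scheme(scheme$s_female, scheme$s_male, sigma = 0, d = scheme$d,
                 H = scheme$H)
}

#' Genome-wide summary: load, inbreeding depression, net modifier selection
#'
#' Composes per-locus equilibria multiplicatively across the genome:
#' mutation load `1 - prod(w_bar_l)` on sex-averaged adult fitness relative
#' to the deleterious-allele-free genotype, inbreeding depression
#' `1 - prod(1 - delta_l)`, and net selection on a mating-system modifier
#' `s_tot = sum(lambda_l - 1)` (plus, on the selfing axis, the direct
#' transmission term of [lambda_selfing_leading()]).
#'
#' @param spec A [genome_spec()].
#' @param delta_mod Modifier effect: `Delta_Pi` in `"polyandry"` mode or
#'   `Delta_Omega` in `"outcrossing"` mode.  `NULL` skips `s_tot`.
#' @param method `"leading_order"` evaluates per-locus equilibria with the
#'   weak-selection formulas at the nominal `mu` and scales by `U/mu`, which
#'   is the mu-independent extrapolation suitable for genome-wide rates.
#'   `"exact"` instead solves each locus class to its exact single-locus
#'   equilibrium with the deterministic recursions at the *actual* per-locus
#'   rate `mu` (so `U/mu` should equal the real locus count), including the
#'   realised excess homozygosity at the selected locus; only the
#'   cross-locus independence assumption remains.  Use `"exact"` when
#'   comparing against finite-genome simulations, where `mu = U/L` is not
#'   small.  `s_tot` is reported for `"leading_order"` only.
#' @return A one-row tibble with columns `load`, `delta_bar`, `s_tot`,
#'   per-class equilibrium frequencies (`q_msb_gam`, `q_msb_nogam`,
#'   `q_bal`), and the context (`mode`, `level`, `F`, `U`, `k`, `l_B`).
#' @examples
#' sch <- fitness_scheme(c(AA = 0, Aa = -0.01, aa = -0.05), sigma = 0.12, d = 0)
#' gs <- genome_spec(sch, "polyandry", level = 0, U = 1, k = 1)
#' genome_summary(gs, delta_mod = 0.5)$s_tot # 0.015
#' @export
genome_summary <- function(spec, delta_mod = NULL,
                           method = c("leading_order", "exact")) {
  stopifnot(inherits(spec, "genome_spec"))
  method <- match.arg(method)
  if (method == "exact") {
    return(genome_summary_exact(spec))
  }
  mu <- spec$mu
  Fcoef <- if (spec$mode == "outcrossing") {
    (1 - spec$level) / (1 + spec$level)
  } else {
    0
  }
  sch_gam <- spec$msb_scheme
  sch_nogam <- strip_gametic(sch_gam)

  log_load <- 0
  log_keep <- 0 # log prod (1 - delta_l)
  s_tot <- if (is.null(delta_mod)) NA_real_ else 0
  q_gam <- q_nogam <- q_bal <- NA_real_

  msb_class <- function(scheme, weight) {
    if (spec$U == 0 || weight == 0) return(NULL)
    I_a <- invasion_coefficients(scheme, spec$mode, spec$level)$I_a
    q <- q_hat_msb(mu, I_a)
    l_class <- weight * spec$U / mu
    list(q = q, l = l_class, scheme = scheme)
  }
  add_class <- function(cls, lam_fun) {
    if (is.null(cls)) return(invisible())
    log_load <<- log_load +
      cls$l * log(per_locus_mean_fitness(cls$scheme, cls$q, Fcoef))
    log_keep <<- log_keep +
      cls$l * log(1 - per_locus_inbreeding_depression(cls$scheme, cls$q, Fcoef))
    if (!is.null(delta_mod)) {
      s_tot <<- s_tot + cls$l * (lam_fun(cls$scheme, cls$q) - 1)
    }
    invisible()
  }

  lam_msb <- function(scheme, q) {
    if (spec$mode == "polyandry") {
      lambda_polyandry_msb(scheme, spec$level, delta_mod, q)
    } else if (spec$level > 0) {
      lambda_selfing_msb(scheme, spec$level, delta_mod, q)
    } else {
      NA_real_
    }
  }
  cls_gam <- msb_class(sch_gam, spec$k)
  cls_nogam <- msb_class(sch_nogam, 1 - spec$k)
  add_class(cls_gam, lam_msb)
  add_class(cls_nogam, lam_msb)
  if (!is.null(cls_gam)) q_gam <- cls_gam$q
  if (!is.null(cls_nogam)) q_nogam <- cls_nogam$q

  if (spec$l_B > 0) {
    ic <- invasion_coefficients(spec$balancing_scheme, spec$mode, spec$level)
    q_bal <- q_hat_balancing(ic$I_A, ic$I_a)
    log_load <- log_load +
      spec$l_B * log(per_locus_mean_fitness(spec$balancing_scheme, q_bal, Fcoef))
    log_keep <- log_keep + spec$l_B *
      log(1 - per_locus_inbreeding_depression(spec$balancing_scheme, q_bal, Fcoef))
    if (!is.null(delta_mod)) {
      lam_b <- if (spec$mode == "polyandry") {
        lambda_polyandry_balancing(spec$balancing_scheme, delta_mod, q_bal)
      } else if (spec$level > 0) {
        lambda_selfing_balancing(spec$balancing_scheme, spec$level, delta_mod,
                                 q_bal)
      } else {
        NA_real_
      }
      s_tot <- s_tot + spec$l_B * (lam_b - 1)
    }
  }

  if (!is.null(delta_mod) && spec$mode == "outcrossing") {
    s_tot <- s_tot +
      (lambda_selfing_leading(delta_mod, spec$c, spec$level) - 1)
  }

  tibble::tibble(
    load = 1 - exp(log_load),
    delta_bar = 1 - exp(log_keep),
    s_tot = s_tot,
    q_msb_gam = q_gam, q_msb_nogam = q_nogam, q_bal = q_bal,
    mode = spec$mode, level = spec$level, F = Fcoef,
    U = spec$U, k = spec$k, l_B = spec$l_B
  )
}

# Compose genome-wide load and inbreeding depression from exact
# deterministic single-locus equilibria at the actual per-locus mutation
# rate; cross-locus independence is the only remaining approximation.
genome_summary_exact <- function(spec) {
  mu <- spec$mu
  resident <- modifier_scheme(spec$mode, level_MM = spec$level)
  F0 <- if (spec$mode == "outcrossing") {
    (1 - spec$level) / (1 + spec$level)
  } else {
    0
  }
  solve_class <- function(scheme, mu_class, init_q) {
    eq <- find_equilibrium(recursion_params(scheme, resident, mu_class),
                           init = two_locus_state(init_q, 0, F0))
    s <- state_summary(eq$state)
    list(q = s$q_a, F = if (is.na(s$F_A)) F0 else s$F_A)
  }
  log_load <- 0
  log_keep <- 0
  q_gam <- q_nogam <- q_bal <- NA_real_
  add <- function(scheme, l_class, sol) {
    log_load <<- log_load +
      l_class * log(per_locus_mean_fitness(scheme, sol$q, sol$F))
    log_keep <<- log_keep +
      l_class * log(1 - per_locus_inbreeding_depression(scheme, sol$q, sol$F))
    invisible()
  }
  if (spec$U > 0 && spec$k > 0) {
    sol <- solve_class(spec$msb_scheme, mu, init_q = 0.05)
    q_gam <- sol$q
    add(spec$msb_scheme, spec$k * spec$U / mu, sol)
  }
  if (spec$U > 0 && spec$k < 1) {
    sch <- strip_gametic(spec$msb_scheme)
    sol <- solve_class(sch, mu, init_q = 0.05)
    q_nogam <- sol$q
    add(sch, (1 - spec$k) * spec$U / mu, sol)
  }
  if (spec$l_B > 0) {
    sol <- solve_class(spec$balancing_scheme, 0, init_q = 0.5)
    q_bal <- sol$q
    add(spec$balancing_scheme, spec$l_B, sol)
  }
  tibble::tibble(
    load = 1 - exp(log_load),
    delta_bar = 1 - exp(log_keep),
    s_tot = NA_real_,
    q_msb_gam = q_gam, q_msb_nogam = q_nogam, q_bal = q_bal,
    mode = spec$mode, level = spec$level, F = F0,
    U = spec$U, k = spec$k, l_B = spec$l_B
  )
}
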