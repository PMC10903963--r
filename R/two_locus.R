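# Exact deterministic recursions for a selected locus A linked (recombination
# r) to a mating-system modifier locus M, censused at the zygote stage.
# One generation: sex-specific fecundity selection on adults -> gametogenesis
# (recombination, gametic selection among male gametes, then mutation A->a)
# -> fertilisation according to the mating system set by the mother's M
# genotype -> zygotes.  The state is the full unordered diploid two-locus
# genotype distribution (10 classes; cis and trans double heterozygotes are
# dynamically distinct when r < 1/2), carried internally as a symmetric 4x4
# matrix over the haplotypes AM, Am, aM, am.

HAPLOTYPES <- c("AM", "Am", "aM", "am")
HAP_A <- c(0L, 0L, 1L, 1L) # a-allele count of each haplotype
HAP_M <- c(0L, 1L, 0L, 1L) # m-allele count

hap_index <- function(a, m) 1L + 2L * a + m

#' Mating-system modifier scheme
#'
#' Describes the modifier locus M: which mating-system axis it controls, the
#' allocation expressed by mothers of each M genotype (proportion of
#' polyandry Pi or of outcrossing Omega), pollen discounting `c`, and the
#' recombination rate `r` to the selected locus.
#'
#' @param mode `"polyandry"` or `"outcrossing"` (see [selection_terms()]).
#' @param level_MM,level_Mm,level_mm Allocation (Pi or Omega, in `[0, 1]`)
#'   expressed by mothers of each M genotype.  Defaults make the modifier
#'   dominant (`level_mm = level_Mm`).
#' @param c Pollen discounting in `[0, 1]` (outcrossing mode only): an
#'   individual's male-gamete contribution to the outcross pool is scaled by
#'   `1 - c (1 - Omega_i)`.
#' @param r Recombination rate between the A and M loci, in `[0, 1/2]`.
#' @return An object of class `modifier_scheme`.
#' @export
modifier_scheme <- function(mode = c("polyandry", "outcrossing"),
                            level_MM, level_Mm = level_MM,
                            level_mm = level_Mm, c = 1, r = 0.5) {
  mode <- match.arg(mode)
  lv <- c(level_MM, level_Mm, level_mm)
  if (!is.numeric(lv) || length(lv) != 3L || anyNA(lv) ||
      any(lv < 0) || any(lv > 1)) {
    stop("levels must be numbers in [0, 1]", call. = FALSE)
  }
  if (c < 0 || c > 1) stop("`c` must be in [0, 1]", call. = FALSE)
  if (r < 0 || r > 0.5) stop("`r` must be in [0, 1/2]", call. = FALSE)
  structure(
    list(mode = mode, level_MM = level_MM, level_Mm = level_Mm,
         level_mm = level_mm, c = c, r = r),
    class = "modifier_scheme"
  )
}

#' Modifier effect size
#'
#' The compound modifier effect entering the weak-selection spread rates:
#' `Delta_Pi = (Pi_Mm - Pi_MM)/2` on the monandry-polyandry axis, or
#' `Delta_Omega = (1 - F)(Omega_Mm - Omega) + F (Omega_mm - Omega)` with
#' `F = (1 - Omega)/(1 + Omega)` on the selfing-outcrossing axis.
#'
#' @param modifier A [modifier_scheme()].
#' @return Numeric modifier effect.
#' @export
modifier_delta <- function(modifier) {
  stopifnot(inherits(modifier, "modifier_scheme"))
  if (modifier$mode == "polyandry") {
    (modifier$level_Mm - modifier$level_MM) / 2
  } else {
    Fcoef <- (1 - modifier$level_MM) / (1 + modifier$level_MM)
    (1 - Fcoef) * (modifier$level_Mm - modifier$level_MM) +
      Fcoef * (modifier$level_mm - modifier$level_MM)
  }
}

#' Parameters for the two-locus recursion
#'
#' @param scheme A [fitness_scheme()] for the selected locus.
#' @param modifier A [modifier_scheme()] for the mating-system locus.
#' @param mu One-way A-to-a mutation rate per gamete, in `[0, 1)`.
#' @return An object of class `recursion_params`.
#' @export
recursion_params <- function(scheme, modifier, mu = 0) {
  stopifnot(inherits(scheme, "fitness_scheme"),
            inherits(modifier, "modifier_scheme"))
  if (mu < 0 || mu >= 1) stop("`mu` must be in [0, 1)", call. = FALSE)
  structure(list(scheme = scheme, modifier = modifier, mu = mu),
            class = "recursion_params")
}

# ---- state representation -------------------------------------------------

state_matrix <- function(state) {
  G <- attr(state, "G")
  if (is.null(G)) {
    G <- matrix(0, 4, 4, dimnames = list(HAPLOTYPES, HAPLOTYPES))
    for (k in seq_len(nrow(state))) {
      i <- match(state$hap1[k], HAPLOTYPES)
      j <- match(state$hap2[k], HAPLOTYPES)
      G[i, j] <- G[i, j] + state$freq[k] / (if (i == j) 1 else 2)
      if (i != j) G[j, i] <- G[j, i] + state$freq[k] / 2
    }
  }
  G
}

state_from_matrix <- function(G) {
  idx <- which(upper.tri(G, diag = TRUE), arr.ind = TRUE)
  freq <- ifelse(idx[, 1] == idx[, 2], G[idx], 2 * G[idx])
  out <- tibble::tibble(
    hap1 = HAPLOTYPES[idx[, 1]],
    hap2 = HAPLOTYPES[idx[, 2]],
    freq = freq
  )
  attr(out, "G") <- G
  class(out) <- c("two_locus_state", class(out))
  out
}

#' Construct a two-locus population state
#'
#' Builds the 10-genotype unordered diploid distribution from allele
#' frequencies, assuming linkage equilibrium between the loci and a common
#' excess homozygosity `F` (haplotype pairs are identical by descent with
#' probability `F`, as under partial selfing).
#'
#' @param q_a Frequency of the a allele at the selected locus.
#' @param q_m Frequency of the m allele at the modifier locus.
#' @param F Excess homozygosity in `[0, 1]`.
#' @return A `two_locus_state` tibble with columns `hap1`, `hap2`, `freq`.
#' @export
two_locus_state <- function(q_a, q_m = 0, F = 0) {
  stopifnot(q_a >= 0, q_a <= 1, q_m >= 0, q_m <= 1, F >= 0, F <= 1)
  h <- (1 - q_a)^(1 - HAP_A) * q_a^HAP_A *
    (1 - q_m)^(1 - HAP_M) * q_m^HAP_M
  G <- (1 - F) * outer(h, h) + F * diag(h)
  dimnames(G) <- list(HAPLOTYPES, HAPLOTYPES)
  state_from_matrix(G)
}

#' Allele frequencies and inbreeding summary of a state
#'
#' @param state A `two_locus_state`.
#' @return A one-row tibble: `q_a`, `q_m`, `het_A` (frequency of A-locus
#'   heterozygotes), and `F_A` (excess homozygosity at the A locus relative
#'   to Hardy-Weinberg; `NA` when the locus is monomorphic).
#' @export
state_summary <- function(state) {
  G <- state_matrix(state)
  q_a <- sum(G * outer(HAP_A, HAP_A, "+")) / 2
  q_m <- sum(G * outer(HAP_M, HAP_M, "+")) / 2
  het <- sum(G[outer(HAP_A, HAP_A, "!=")])
  F_A <- if (q_a %in% c(0, 1)) NA_real_ else 1 - het / (2 * q_a * (1 - q_a))
  tibble::tibble(q_a = q_a, q_m = q_m, het_A = het, F_A = F_A)
}

# ---- engine ---------------------------------------------------------------

# Precompute everything that depends on the parameters but not the state.
build_engine <- function(params) {
  sch <- params$scheme
  mod <- params$modifier
  mu <- params$mu
  r <- mod$r

  acnt <- outer(HAP_A, HAP_A, "+") # 0, 1, 2 copies of a
  wf <- matrix((1 + sch$s_female)[acnt + 1], 4, 4)
  wm <- matrix((1 + sch$s_male)[acnt + 1], 4, 4)
  mcnt <- outer(HAP_M, HAP_M, "+")
  lev <- matrix(c(mod$level_MM, mod$level_Mm, mod$level_mm)[mcnt + 1], 4, 4)
  disc <- if (mod$mode == "outcrossing") 1 - mod$c * (1 - lev) else
    matrix(1, 4, 4)

  # recombination: gamete haplotype distribution of each ordered genotype
  R <- array(0, c(4, 4, 4))
  for (i in 1:4) {
    for (j in 1:4) {
      rec1 <- hap_index(HAP_A[i], HAP_M[j])
      rec2 <- hap_index(HAP_A[j], HAP_M[i])
      R[i, j, i] <- R[i, j, i] + (1 - r) / 2
      R[i, j, j] <- R[i, j, j] + (1 - r) / 2
      R[i, j, rec1] <- R[i, j, rec1] + r / 2
      R[i, j, rec2] <- R[i, j, rec2] + r / 2
    }
  }

  # gametic fitness of haplotype h from a father with a-count acnt
  g <- gamete_fitnesses(sch)
  WG <- rbind(
    c(g$w_A_AA, g$w_A_AA), # AA father (a-gametes unreachable pre-mutation)
    c(g$w_A_Aa, g$w_a_Aa),
    c(g$w_a_aa, g$w_a_aa)
  )
  wg <- array(0, c(4, 4, 4))
  for (h in 1:4) wg[, , h] <- WG[cbind(c(acnt) + 1, HAP_A[h] + 1)]

  # mutation A -> a acting on gamete haplotypes (after selection)
  Mu <- diag(4)
  Mu[1, 1] <- 1 - mu; Mu[1, 3] <- mu
  Mu[2, 2] <- 1 - mu; Mu[2, 4] <- mu

  flat <- function(arr) matrix(arr, 16, 4) # ordered-genotype rows
  E16 <- flat(R) %*% Mu                    # egg distributions (no selection)
  U16 <- flat(R * wg) %*% Mu               # male gametes, selection-weighted
  S16 <- U16 / rowSums(U16)                # normalised within one father

  list(mode = mod$mode, E16 = E16, U16 = U16, S16 = S16,
       wf = as.vector(wf), wm = as.vector(wm),
       lev = as.vector(lev), disc = as.vector(disc))
}

step_engine <- function(Gv, eng) {
  pm <- Gv * eng$wf
  pm <- pm / sum(pm)
  if (eng$mode == "polyandry") {
    wpool <- Gv * eng$wm
    pool <- as.vector(crossprod(eng$U16, wpool))
    pool <- pool / sum(pool)
    smon <- as.vector(crossprod(eng$S16, wpool / sum(wpool)))
    eggs_poly <- colSums(eng$E16 * (pm * eng$lev))
    eggs_mono <- colSums(eng$E16 * (pm * (1 - eng$lev)))
    Gp <- outer(eggs_poly, pool) + outer(eggs_mono, smon)
  } else {
    wpool <- Gv * eng$wm * eng$disc
    pool <- as.vector(crossprod(eng$U16, wpool))
    # with full discounting in a fully selfing population nobody outcrosses;
    # the empty pool then multiplies a zero egg mass
    pool <- if (sum(pool) > 0) pool / sum(pool) else numeric(4)
    eggs_out <- colSums(eng$E16 * (pm * eng$lev))
    Gp <- outer(eggs_out, pool) +
      crossprod(eng$E16 * (pm * (1 - eng$lev)), eng$S16)
  }
  Gp <- (Gp + t(Gp)) / 2
  tot <- sum(Gp)
  if (abs(tot - 1) > 1e-9) {
    stop("normalisation drift in recursion step (sum = ", format(tot), ")",
         call. = FALSE)
  }
  as.vector(Gp / tot)
}

#' Advance the two-locus recursion
#'
#' @param state A `two_locus_state` (see [two_locus_state()]).
#' @param params A [recursion_params()].
#' @param generations Number of generations to iterate.
#' @return The next `two_locus_state`.
#' @export
step_two_locus <- function(state, params, generations = 1) {
  eng <- build_engine(params)
  Gv <- as.vector(state_matrix(state))
  for (i in seq_len(generations)) Gv <- step_engine(Gv, eng)
  state_from_matrix(matrix(Gv, 4, 4, dimnames = list(HAPLOTYPES, HAPLOTYPES)))
}

#' Deterministic equilibrium of the two-locus recursion
#'
#' Iterates the exact recursion to a fixed point.
#'
#' @param params A [recursion_params()].
#' @param init Initial `two_locus_state`; defaults to `q_a = 0.25`,
#'   modifier absent, neutral-expectation `F` for the resident mating
#'   system.
#' @param tol Convergence tolerance on the maximum per-genotype frequency
#'   change per generation.
#' @param max_gen Generation cap.
#' @return An object of class `two_locus_equilibrium`: a list with elements
#'   `state`, `generations`, `converged`, `params`.  Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
find_equilibrium <- function(params, init = NULL, tol = 1e-12,
                             max_gen = 5e5) {
  stopifnot(inherits(params, "recursion_params"), tol > 0)
  if (is.null(init)) {
    F0 <- if (params$modifier$mode == "outcrossing") {
      (1 - params$modifier$level_MM) / (1 + params$modifier$level_MM)
    } else {
      0
    }
    init <- two_locus_state(q_a = 0.25, q_m = 0, F = F0)
  }
  eng <- build_engine(params)
  Gv <- as.vector(state_matrix(init))
  gen <- 0L
  delta <- Inf
  last_check <- Inf
  while (gen < max_gen) {
    Gn <- step_engine(Gv, eng)
    delta <- max(abs(Gn - Gv))
    Gv <- Gn
    gen <- gen + 1L
    if (delta < tol) break
    if (gen %% 50000L == 0L) {
      if (delta > 0.5 * last_check) {
        stop("two-locus recursion is not converging (per-generation change ",
             format(delta), " after ", gen, " generations)", call. = FALSE)
      }
      last_check <- delta
    }
  }
  if (delta >= tol) {
    stop("no equilibrium within ", max_gen, " generations (last change ",
         format(delta), ")", call. = FALSE)
  }
  structure(
    list(
      state = state_from_matrix(
        matrix(Gv, 4, 4, dimnames = list(HAPLOTYPES, HAPLOTYPES))),
      generations = gen, converged = TRUE, params = params
    ),
    class = "two_locus_equilibrium"
  )
}

#' @export
print.two_locus_equilibrium <- function(x, ...) {
  s <- state_summary(x$state)
  cat("<two_locus_equilibrium> after", x$generations, "generations\n")
  cat(sprintf("  q_a = %.8g, q_m = %.8g, F_A = %.6g\n",
              s$q_a, s$q_m, s$F_A))
  invisible(x)
}

# ---- numerical invasion ---------------------------------------------------

# Replace each M haplotype by its m counterpart with probability q_init,
# independently for the two haplotypes of every genotype: the mutant enters
# in linkage equilibrium with A and in the resident diploid structure.
inject_modifier <- function(G, q_init) {
  T <- diag(4)
  T[1, 1] <- 1 - q_init; T[1, 2] <- q_init
  T[3, 3] <- 1 - q_init; T[3, 4] <- q_init
  crossprod(T, G) %*% T
}

#' Numerically measured invasion growth rate of a rare modifier allele
#'
#' Brings the selected locus to its single-locus equilibrium under the
#' resident mating system (modifier fixed for M), introduces the m allele at
#' frequency `q_init` in linkage equilibrium, iterates the exact recursion,
#' and estimates the asymptotic per-generation growth factor of the m
#' frequency from the log-frequency change over a window after burn-in.
#' The mutant frequency must stay below `q_cap` for the estimate to reflect
#' the linear (rare-modifier) regime.
#'
#' @param scheme A [fitness_scheme()].
#' @param modifier A [modifier_scheme()]; `level_MM` is the resident.
#' @param mu One-way A-to-a mutation rate.
#' @param q_init Initial modifier frequency (rare).
#' @param burn_in Generations discarded before the measurement window.
#' @param window Generations over which the log-linear growth is measured.
#' @param init Optional initial state for the resident equilibrium solve.
#' @param resident_tol Tolerance passed to [find_equilibrium()].
#' @param q_cap Upper bound on the mutant frequency during measurement.
#' @return An object of class `invasion_fit` with elements `lambda`
#'   (growth factor), `trajectory` (tibble of generation and `q_m`),
#'   `burn_in`, `window`, `resident` (the resident equilibrium summary).
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
numerical_invasion <- function(scheme, modifier, mu = 0, q_init = 1e-6,
                               burn_in = 3000, window = 2000, init = NULL,
                               resident_tol = 1e-13, q_cap = 1e-3) {
  resident <- modifier_scheme(modifier$mode, level_MM = modifier$level_MM,
                              level_Mm = modifier$level_MM,
                              level_mm = modifier$level_MM,
                              c = modifier$c, r = modifier$r)
  res_eq <- find_equilibrium(recursion_params(scheme, resident, mu),
                             init = init, tol = resident_tol)
  G <- inject_modifier(state_matrix(res_eq$state), q_init)
  eng <- build_engine(recursion_params(scheme, modifier, mu))
  total <- burn_in + window
  Gv <- as.vector(G)
  qm <- numeric(total + 1L)
  qm[1L] <- sum(Gv * outer(HAP_M, HAP_M, "+")) / 2
  mfac <- as.vector(outer(HAP_M, HAP_M, "+")) / 2
  for (t in seq_len(total)) {
    Gv <- step_engine(Gv, eng)
    qm[t + 1L] <- sum(Gv * mfac)
    if (qm[t + 1L] > q_cap) {
      stop("modifier frequency left the rare-allele regime before a stable ",
           "estimate; use a smaller `q_init`", call. = FALSE)
    }
  }
  lambda <- exp((log(qm[total + 1L]) - log(qm[burn_in + 1L])) / window)
  structure(
    list(
      lambda = lambda,
      trajectory = tibble::tibble(generation = 0:total, q_m = qm),
      burn_in = burn_in, window = window,
      resident = state_summary(res_eq$state)
    ),
    class = "invasion_fit"
  )
}

#' Numerically measured growth rate of a rare allele at the selected locus
#'
#' The brute-force counterpart of [invasion_coefficients()]: fixes the
#' modifier locus, makes the population (nearly) monomorphic for the common
#' allele, introduces the rare allele at `q_init` and measures its
#' asymptotic per-generation growth factor, which approximates
#' `1 + I_alpha` under weak selection.
#'
#' @inheritParams numerical_invasion
#' @param mode,level Resident mating system (see [selection_terms()]).
#' @param allele Which allele is rare, `"A"` or `"a"`.
#' @return An `invasion_fit` (growth of the rare-allele frequency).
#' @export
numerical_allele_growth <- function(scheme, mode = c("polyandry", "outcrossing"),
                                    level, allele = c("a", "A"),
                                    q_init = 1e-6, burn_in = 2000,
                                    window = 2000, q_cap = 1e-3) {
  mode <- match.arg(mode)
  allele <- match.arg(allele)
  resident <- modifier_scheme(mode, level_MM = level)
  eng <- build_engine(recursion_params(scheme, resident, mu = 0))
  F0 <- if (mode == "outcrossing") (1 - level) / (1 + level) else 0
  q0 <- if (allele == "a") q_init else 1 - q_init
  Gv <- as.vector(state_matrix(two_locus_state(q_a = q0, q_m = 0, F = F0)))
  afac <- as.vector(outer(HAP_A, HAP_A, "+")) / 2
  total <- burn_in + window
  qa <- numeric(total + 1L)
  qa[1L] <- sum(Gv * afac)
  for (t in seq_len(total)) {
    Gv <- step_engine(Gv, eng)
    qa[t + 1L] <- sum(Gv * afac)
    qr <- if (allele == "a") qa[t + 1L] else 1 - qa[t + 1L]
    if (qr > q_cap) {
      stop("rare-allele frequency left the linear regime; ",
           "use a smaller `q_init`", call. = FALSE)
    }
  }
  qrare <- if (allele == "a") qa else 1 - qa
  lambda <- exp((log(qrare[total + 1L]) - log(qrare[burn_in + 1L])) / window)
  structure(
    list(
      lambda = lambda,
      trajectory = tibble::tibble(generation = 0:total, q_rare = qrare),
      burn_in = burn_in, window = window, resident = NULL
    ),
    class = "invasion_fit"
  )
}

#' @export
print.invasion_fit <- function(x, ...) {
  cat("<invasion_fit>\n")
  cat(sprintf("  lambda = %.12g (burn-in %d, window %d)\n",
              x$lambda, x$burn_in, x$window))
  invisible(x)
}
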