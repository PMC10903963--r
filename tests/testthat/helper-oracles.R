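# Shared helpers for oracle-equivalence and property-style tests.

# Scale every selection coefficient (adult s, sigma) by a factor.
scale_scheme <- function(sch, f) {
  fitness_scheme(sch$s_female * f, sch$s_male * f, sigma = sch$sigma * f,
                 d = sch$d, H = sch$H)
}

# Measure the numerical-vs-analytic error of a modifier spread rate.
# `type` selects the analytic formula; the modifier effect `eff` (an
# increase of the resident level, dominant) is part of the weak-selection
# scaling and is scaled alongside the fitness coefficients by callers.
lambda_oracle_error <- function(sch, mode, level, eff, mu, type,
                                burn_in = 4000, window = 3000,
                                q_init = 1e-10) {
  mod <- modifier_scheme(mode, level_MM = level, level_Mm = level + eff,
                         c = 1)
  ic <- invasion_coefficients(sch, mode, level)
  delta <- modifier_delta(mod)
  lam_an <- switch(
    type,
    pmsb = lambda_polyandry_msb(sch, level, delta, q_hat_msb(mu, ic$I_a)),
    pbal = lambda_polyandry_balancing(sch, delta,
                                      q_hat_balancing(ic$I_A, ic$I_a)),
    smsb = lambda_selfing_msb(sch, level, delta, q_hat_msb(mu, ic$I_a)),
    sbal = lambda_selfing_balancing(sch, level, delta,
                                    q_hat_balancing(ic$I_A, ic$I_a))
  )
  init <- if (type %in% c("pbal", "sbal")) two_locus_state(0.5, 0, 0) else NULL
  fit <- numerical_invasion(sch, mod, mu = mu, q_init = q_init,
                            burn_in = burn_in, window = window, init = init)
  list(lambda_num = fit$lambda, lambda_an = lam_an,
       err = fit$lambda - lam_an)
}

# Independent brute-force inbreeding depression: plain loops over mother
# genotype, egg allele, and sperm allele (no shared code with the
# implementation's vectorised enumeration).
delta_bruteforce <- function(sch, q, F = 0) {
  p <- 1 - q
  f <- c(p^2 + F * p * q, 2 * p * q * (1 - F), q^2 + F * p * q)
  wf <- unname(1 + sch$s_female)
  wm <- unname(1 + sch$s_male)
  gam <- function(x) 1 - (1 - x^sch$H)^(1 / sch$H)
  # gamete fitness w[geno][allele]: allele 1 = A, 2 = a
  wg <- list(c(1, 0), # from AA males only A gametes exist
             c(1 - gam(sch$d / 2) * sch$sigma,
               1 - gam(1 - sch$d / 2) * sch$sigma),
             c(0, 1 - sch$sigma))
  egg_p <- list(c(1, 0), c(0.5, 0.5), c(0, 1))
  # outcross sperm pool
  pool <- c(0, 0)
  for (g in 1:3) {
    raw <- egg_p[[g]] * wg[[g]] # production share x gametic fitness
    pool <- pool + f[g] * wm[g] * raw
  }
  pool <- pool / sum(pool)
  num_o <- num_s <- den <- 0
  for (g in 1:3) {
    pmother <- f[g] * wf[g]
    selfpool <- egg_p[[g]] * wg[[g]]
    selfpool <- selfpool / sum(selfpool)
    for (ea in 1:2) {
      for (sa in 1:2) {
        off <- ea + sa - 1 # genotype index 1..3
        woff <- (wf[off] + wm[off]) / 2
        num_o <- num_o + pmother * egg_p[[g]][ea] * pool[sa] * woff
        num_s <- num_s + pmother * egg_p[[g]][ea] * selfpool[sa] * woff
      }
    }
    den <- den + pmother
  }
  1 - (num_s / den) / (num_o / den)
}
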