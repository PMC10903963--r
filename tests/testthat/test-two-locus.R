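test_that("neutral recursions conserve both allele frequencies exactly", {
  sch0 <- fitness_scheme()
  set.seed(4)
  for (md in c("polyandry", "outcrossing")) {
    for (i in 1:5) {
      # on the selfing axis a *differential* modifier is not neutral even in
      # a fitness-neutral genome (transmission advantage), so conservation
      # is asserted for an M locus with no effect there; monandry/polyandry
      # differences carry no transmission advantage and may differ freely
      lv <- runif(3)
      if (md == "outcrossing") lv[2:3] <- lv[1]
      mod <- modifier_scheme(md, level_MM = lv[1], level_Mm = lv[2],
                             level_mm = lv[3], c = runif(1),
                             r = runif(1, 0, 0.5))
      st <- two_locus_state(q_a = runif(1, 0.05, 0.95),
                            q_m = runif(1, 0.05, 0.95), F = runif(1, 0, 0.8))
      s0 <- state_summary(st)
      st2 <- step_two_locus(st, recursion_params(sch0, mod, mu = 0), 3)
      s2 <- state_summary(st2)
      expect_equal(s2$q_a, s0$q_a, tolerance = 1e-13)
      expect_equal(s2$q_m, s0$q_m, tolerance = 1e-13)
      expect_true(all(st2$freq >= -1e-15))
      expect_equal(sum(st2$freq), 1, tolerance = 1e-12)
    }
  }
})

test_that("partial selfing builds the classic excess homozygosity", {
  # neutral locus, Omega = 0.5: F converges to (1-Omega)/(1+Omega) = 1/3
  eq <- find_equilibrium(
    recursion_params(fitness_scheme(),
                     modifier_scheme("outcrossing", level_MM = 0.5), mu = 0),
    init = two_locus_state(0.3, 0, 0), tol = 1e-14)
  expect_equal(glance(eq)$F_A, 1 / 3, tolerance = 1e-10)
  expect_equal(glance(eq)$q_a, 0.3, tolerance = 1e-12)
})

test_that("monandry with diploid expression exactly mirrors no gametic selection", {
  modP <- modifier_scheme("polyandry", level_MM = 0)
  q_d1 <- glance(find_equilibrium(
    recursion_params(scheme_deleterious(sigma = 0.12, d = 1), modP, 1e-6),
    init = two_locus_state(0.01, 0, 0)))$q_a
  q_s0 <- glance(find_equilibrium(
    recursion_params(scheme_deleterious(sigma = 0), modP, 1e-6),
    init = two_locus_state(0.01, 0, 0)))$q_a
  expect_equal(q_d1, q_s0, tolerance = 1e-10)
})

test_that("deterministic equilibria agree with the weak-selection formulas", {
  # mutation-selection balance under full polyandry, haploid expression
  mu <- 1e-6
  eq <- find_equilibrium(
    recursion_params(scheme_deleterious(),
                     modifier_scheme("polyandry", level_MM = 0), mu),
    init = two_locus_state(0.01, 0, 0))
  q_an <- q_hat_msb(mu, invasion_coefficients(scheme_deleterious(),
                                              "polyandry", 0)$I_a)
  expect_equal(glance(eq)$q_a, q_an, tolerance = 0.1) # O(eps) relative
  # ploidally antagonistic balancing selection: interior equilibrium
  schb <- scheme_antagonistic_mild(sigma = 0.05)
  eqb <- find_equilibrium(
    recursion_params(schb, modifier_scheme("polyandry", level_MM = 1), 0),
    init = two_locus_state(0.5, 0, 0))
  ic <- invasion_coefficients(schb, "polyandry", 1)
  expect_equal(glance(eqb)$q_a, q_hat_balancing(ic$I_A, ic$I_a),
               tolerance = 0.05)
  # below the invasion boundary no variation is maintained
  eq_lost <- find_equilibrium(
    recursion_params(scheme_antagonistic_mild(sigma = 0.01),
                     modifier_scheme("polyandry", level_MM = 1), 0),
    init = two_locus_state(0.5, 0, 0))
  expect_true(glance(eq_lost)$q_a %in% c(0, 1) ||
                min(glance(eq_lost)$q_a, 1 - glance(eq_lost)$q_a) < 1e-6)
})

test_that("without mutation an absent allele stays absent", {
  eq <- find_equilibrium(
    recursion_params(scheme_deleterious(),
                     modifier_scheme("polyandry", level_MM = 0.5), mu = 0),
    init = two_locus_state(0, 0, 0))
  expect_equal(glance(eq)$q_a, 0)
  expect_equal(eq$generations, 1L)
})

test_that("recombination does not move single-locus equilibria", {
  mu <- 1e-6
  qs <- vapply(c(0.05, 0.5), function(r) {
    glance(find_equilibrium(
      recursion_params(scheme_deleterious(),
                       modifier_scheme("polyandry", level_MM = 0, r = r), mu),
      init = two_locus_state(0.01, 0, 0)))$q_a
  }, numeric(1))
  expect_equal(qs[1], qs[2], tolerance = 1e-12)
})

test_that("a do-nothing modifier and a discounted selfing modifier are neutral", {
  fit <- numerical_invasion(
    fitness_scheme(), modifier_scheme("outcrossing", 0.5, 0.5), mu = 0,
    burn_in = 500, window = 500)
  expect_equal(fit$lambda, 1, tolerance = 1e-9)
  # full pollen discounting kills the transmission advantage in a neutral genome
  fit_c1 <- numerical_invasion(
    fitness_scheme(), modifier_scheme("outcrossing", 0.8, 0.9, c = 1),
    mu = 0, burn_in = 1000, window = 1000)
  expect_equal(fit_c1$lambda, 1, tolerance = 1e-9)
})

test_that("rare-allele growth matches the invasion coefficient to O(eps^2)", {
  sch <- scheme_deleterious()
  g <- numerical_allele_growth(sch, "polyandry", 0, allele = "a")
  I_a <- invasion_coefficients(sch, "polyandry", 0)$I_a
  err_full <- abs(g$lambda - (1 + I_a))
  expect_lt(err_full, 0.12^2)
  g_half <- numerical_allele_growth(scale_scheme(sch, 0.5), "polyandry", 0,
                                    allele = "a", burn_in = 4000)
  I_half <- invasion_coefficients(scale_scheme(sch, 0.5), "polyandry", 0)$I_a
  expect_lt(abs(g_half$lambda - (1 + I_half)), err_full / 3)
})

test_that("equilibrium solver reports non-convergence instead of looping", {
  expect_error(
    find_equilibrium(
      recursion_params(scheme_deleterious(),
                       modifier_scheme("polyandry", level_MM = 0), 1e-6),
      init = two_locus_state(0.01, 0, 0), max_gen = 10),
    "no equilibrium")
})
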