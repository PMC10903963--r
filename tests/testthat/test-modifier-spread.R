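sch_del <- scheme_deleterious()

test_that("polyandry is favoured by deleterious variation, and only then", {
  ic <- invasion_coefficients(sch_del, "polyandry", 0)
  q <- q_hat_msb(1e-5, ic$I_a)
  expect_equal(lambda_polyandry_msb(sch_del, 0, delta_pi = 0, q_hat = q), 1)
  # sign follows the modifier direction for any deleterious scheme
  set.seed(2)
  for (i in 1:10) {
    s_het <- -runif(1, 0.001, 0.02)
    sch <- fitness_scheme(c(AA = 0, Aa = s_het, aa = s_het * 4),
                          sigma = runif(1, 0.02, 0.3), d = runif(1, 0, 0.9))
    lv <- runif(1)
    qq <- q_hat_msb(1e-5, invasion_coefficients(sch, "polyandry", lv)$I_a)
    for (dp in c(-0.2, 0.3)) {
      expect_equal(sign(lambda_polyandry_msb(sch, lv, dp, qq) - 1), sign(dp))
    }
  }
})

test_that("balancing selection favours monandry unless expression is diploid", {
  sch_b <- scheme_antagonistic()
  ic <- invasion_coefficients(sch_b, "polyandry", 0)
  q <- q_hat_balancing(ic$I_A, ic$I_a)
  expect_gt(lambda_polyandry_balancing(sch_b, delta_pi = -0.25, q_hat = q), 1)
  expect_lt(lambda_polyandry_balancing(sch_b, delta_pi = 0.25, q_hat = q), 1)
  # diploid expression: no within-male variation, no mating-system evolution
  expect_equal(
    lambda_polyandry_balancing(scheme_antagonistic(d = 1), 0.25, q), 1)
})

test_that("selfing transmission advantage is (1-c)/2 and dies at c = 1", {
  expect_equal(lambda_selfing_leading(0.3, c = 1, level = 0.5), 1)
  # dominant full-selfing modifier in an outcrossing population
  expect_equal(abs(lambda_selfing_leading(-1, c = 0, level = 1) - 1), 0.5)
  expect_lt(lambda_selfing_leading(0.2, c = 0.3, level = 0.7), 1)
})

test_that("outcrossing responds to dominance of deleterious alleles", {
  # additive scheme (adult and gametic) is exactly neutral: I_A + I_a = 0
  sch_add <- fitness_scheme(c(AA = 0, Aa = -0.025, aa = -0.05),
                            sigma = 0.1, d = 0.5, H = 1)
  ic <- invasion_coefficients(sch_add, "outcrossing", 0.7)
  expect_equal(ic$I_A + ic$I_a, 0)
  expect_equal(
    lambda_selfing_msb(sch_add, 0.7, 0.1, q_hat_msb(1e-5, ic$I_a)), 1)
  # recessive: outcrossing favoured
  icr <- invasion_coefficients(sch_del, "outcrossing", 0.8)
  expect_gt(
    lambda_selfing_msb(sch_del, 0.8, 0.1, q_hat_msb(1e-5, icr$I_a)), 1)
  # dominant deleterious allele: selfing favoured
  sch_dom <- fitness_scheme(c(AA = 0, Aa = -0.045, aa = -0.05),
                            sigma = 0.12, d = 0)
  icd <- invasion_coefficients(sch_dom, "outcrossing", 0.8)
  expect_lt(
    lambda_selfing_msb(sch_dom, 0.8, 0.1, q_hat_msb(1e-5, icd$I_a)), 1)
  expect_error(lambda_selfing_msb(sch_del, 0, 0.1, 1e-4), "positive")
})

test_that("balancing selection always favours outcrossing", {
  for (sch in list(scheme_overdominant(), scheme_antagonistic_mild(0.05))) {
    for (lv in c(0.4, 0.8)) {
      ic <- invasion_coefficients(sch, "outcrossing", lv)
      if (ic$I_A <= 0 || ic$I_a <= 0) next
      q <- q_hat_balancing(ic$I_A, ic$I_a)
      expect_gt(lambda_selfing_balancing(sch, lv, 0.1, q), 1)
      expect_equal(lambda_selfing_balancing(sch, lv, 0, q), 1)
    }
  }
})

test_that("outcrossing-stability threshold falls linearly with discounting", {
  expect_equal(selfing_threshold(0), 0.5)
  expect_equal(selfing_threshold(0.5), 0.25)
  expect_equal(selfing_threshold(1), 0)
})
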