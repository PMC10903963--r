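test_that("masking function hits its boundary and closed-form values", {
  expect_identical(gamma_masking(0, H = 2), 0)
  expect_identical(gamma_masking(1, H = 2), 1)
  expect_equal(gamma_masking(0.5, H = 1), 0.5)
  expect_equal(gamma_masking(0.5, H = 2), 1 - sqrt(0.75))
  expect_error(gamma_masking(-0.1, 2), "0, 1")
  expect_error(gamma_masking(0.5, H = 0), "positive")
})

test_that("masking is monotone in expression for any dominance", {
  x <- seq(0, 1, length.out = 101)
  for (H in c(0.3, 0.7, 1, 2, 5, 20)) {
    expect_true(all(diff(gamma_masking(x, H)) >= -1e-12), info = paste("H =", H))
  }
})

test_that("gamete fitness table matches the life-cycle parameterisation", {
  # haploid expression: gamete fitness depends on own allele only
  tab <- gamete_fitness_table(fitness_scheme(sigma = 0.1, d = 0, H = 2))
  expect_equal(tab$fitness, c(1, 1, 0.9, 0.9))
  expect_equal(
    gamete_selection_summary(fitness_scheme(sigma = 0.1, d = 0))$s_delta_Aa,
    0.05)
  # diploid expression: both gamete types from heterozygotes are equal
  tab1 <- gamete_fitness_table(fitness_scheme(sigma = 0.1, d = 1, H = 2))
  expect_equal(tab1$fitness[2], tab1$fitness[3])
  # no gametic selection
  expect_equal(
    gamete_fitness_table(fitness_scheme(sigma = 0, d = 0.3))$fitness,
    rep(1, 4))
})

test_that("gamete fitnesses are ordered and respond to expression pattern", {
  set.seed(1)
  for (i in 1:25) {
    sigma <- runif(1, 0, 0.9)
    d <- runif(1)
    H <- runif(1, 1, 6)
    tab <- gamete_fitness_table(fitness_scheme(sigma = sigma, d = d, H = H))
    w <- tab$fitness
    expect_true(all(w > 0 & w <= 1))
    # w_a_aa <= w_a_Aa <= w_A_Aa <= w_A_AA for sigma >= 0, H >= 1
    expect_true(w[4] <= w[3] + 1e-12 && w[3] <= w[2] + 1e-12 &&
                  w[2] <= w[1] + 1e-12)
    # more haploid-like expression exposes the a gamete and shields the A
    tab_lo <- gamete_fitness_table(
      fitness_scheme(sigma = sigma, d = d * 0.5, H = H))
    expect_lte(tab_lo$fitness[3], w[3] + 1e-12)
    expect_gte(tab_lo$fitness[2], w[2] - 1e-12)
  }
})

test_that("within-male fitness variation vanishes iff d = 1 or sigma = 0", {
  grid <- expand.grid(sigma = c(0, 0.05, 0.3), d = c(0, 0.4, 1))
  for (i in seq_len(nrow(grid))) {
    sdel <- gamete_selection_summary(
      fitness_scheme(sigma = grid$sigma[i], d = grid$d[i]))$s_delta_Aa
    if (grid$sigma[i] == 0 || grid$d[i] == 1) {
      expect_equal(sdel, 0)
    } else {
      expect_gt(sdel, 0)
    }
  }
})

test_that("scheme validation rejects impossible parameters", {
  expect_error(fitness_scheme(c(AA = 0, Aa = -1, aa = -2)), "positive")
  expect_error(fitness_scheme(sigma = 1), "sigma")
  expect_error(fitness_scheme(d = 2), "d")
  expect_error(fitness_scheme(c(a = 1, b = 2, c = 3)), "names")
  # unnamed vectors are taken in AA, Aa, aa order
  sch <- fitness_scheme(c(0, -0.01, -0.05))
  expect_equal(sch$s_female[["aa"]], -0.05)
})
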