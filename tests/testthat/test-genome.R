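sch_del <- scheme_deleterious()

test_that("per-locus inbreeding depression matches a brute-force enumeration", {
  cases <- list(
    list(sch = sch_del, q = 0.01, F = 0),
    list(sch = scheme_deleterious(sigma = 0), q = 0.05, F = 0.2),
    list(sch = scheme_overdominant(), q = 0.4, F = 0),
    list(sch = fitness_scheme(c(AA = 0, Aa = -0.03, aa = -0.05),
                              sigma = 0.2, d = 0.6), q = 0.02, F = 0.5)
  )
  for (cs in cases) {
    expect_equal(per_locus_inbreeding_depression(cs$sch, cs$q, cs$F),
                 delta_bruteforce(cs$sch, cs$q, cs$F), tolerance = 1e-9)
  }
})

test_that("inbreeding depression vanishes without variation or dominance", {
  expect_equal(per_locus_inbreeding_depression(sch_del, 0, 0), 0)
  # additive adult effects, no gametic selection: no O(q) term survives
  sch_add <- fitness_scheme(c(AA = 0, Aa = -0.025, aa = -0.05), sigma = 0)
  expect_lt(abs(per_locus_inbreeding_depression(sch_add, 1e-3, 0)), 1e-12)
  # recessive deleterious alleles do cause depression at O(q)
  expect_gt(per_locus_inbreeding_depression(
    scheme_deleterious(sigma = 0), 1e-3, 0), 1e-5)
})

test_that("empty genomes carry no load, depression, or modifier selection", {
  gs <- genome_spec(sch_del, "polyandry", level = 0, U = 0, k = 1, l_B = 0)
  out <- genome_summary(gs, delta_mod = 0.5)
  expect_equal(out$load, 0)
  expect_equal(out$delta_bar, 0)
  expect_equal(out$s_tot, 0)
})

test_that("genome summaries are invariant to the (mu, l_mu) split at fixed U", {
  for (mu in c(1e-7, 1e-6, 1e-5)) {
    gs <- genome_spec(sch_del, "polyandry", level = 0, U = 1, k = 1, mu = mu)
    out <- genome_summary(gs, delta_mod = 0.5)
    expect_equal(out$s_tot, 0.015, tolerance = 1e-6)
    ref <- genome_summary(
      genome_spec(sch_del, "polyandry", level = 0, U = 1, k = 1, mu = 1e-6))
    expect_equal(out$load, ref$load, tolerance = 1e-3)
    expect_equal(out$delta_bar, ref$delta_bar, tolerance = 1e-3)
  }
})

test_that("monandry raises deleterious-allele frequencies under haploid expression", {
  q <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(Pi) {
    genome_summary(genome_spec(sch_del, "polyandry", Pi, U = 0.5))$q_msb_gam
  }, numeric(1))
  expect_true(all(diff(q) < 0)) # q falls as polyandry rises
})

test_that("full selfing erases the imprint of gametic selection", {
  outs <- lapply(c(0, 0.06, 0.12), function(sg) {
    genome_summary(genome_spec(scheme_deleterious(sigma = sg),
                               "outcrossing", 0, U = 0.5))
  })
  loads <- vapply(outs, function(x) x$load, numeric(1))
  qs <- vapply(outs, function(x) x$q_msb_gam, numeric(1))
  expect_equal(max(loads) - min(loads), 0, tolerance = 1e-12)
  expect_equal(max(qs) - min(qs), 0, tolerance = 1e-15)
  # ... whereas under outcrossing sigma matters a lot
  loads1 <- vapply(c(0, 0.12), function(sg) {
    genome_summary(genome_spec(scheme_deleterious(sigma = sg),
                               "outcrossing", 1, U = 0.5))$load
  }, numeric(1))
  expect_gt(loads1[1] / loads1[2], 2)
})

test_that("gametic selection depresses inbreeding depression in k and sigma", {
  dk <- vapply(seq(0, 1, 0.25), function(k) {
    genome_summary(genome_spec(sch_del, "outcrossing", 1, U = 0.5,
                               k = k))$delta_bar
  }, numeric(1))
  expect_true(all(diff(dk) < 0))
  ds <- vapply(c(0.01, 0.05, 0.1), function(sg) {
    genome_summary(genome_spec(scheme_deleterious(sigma = sg),
                               "outcrossing", 1, U = 0.5))$delta_bar
  }, numeric(1))
  expect_true(all(diff(ds) < 0))
})

test_that("balancing loci punch above their weight in modifier selection", {
  # per-locus modifier selection at equal selection strengths
  gs_msb <- genome_spec(sch_del, "polyandry", 0, U = 1e-5, k = 1, mu = 1e-5)
  per_msb <- abs(genome_summary(gs_msb, delta_mod = 0.25)$s_tot)
  gs_bal <- genome_spec(sch_del, "polyandry", 0, U = 0, l_B = 1,
                        balancing_scheme = scheme_antagonistic())
  per_bal <- abs(genome_summary(gs_bal, delta_mod = 0.25)$s_tot)
  expect_gt(per_bal, per_msb)
})
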