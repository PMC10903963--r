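test_that("fitness-scheme configs round-trip through YAML", {
  sch <- fitness_scheme(c(AA = 0, Aa = -0.01, aa = -0.05),
                        c(AA = 0, Aa = -0.02, aa = -0.04),
                        sigma = 0.12, d = 0.3, H = 2)
  path <- withr::local_tempfile(fileext = ".yml")
  write_fitness_scheme(sch, path)
  back <- read_fitness_scheme(path)
  expect_equal(back, sch)
  # male role defaults to the female values
  sch2 <- read_fitness_scheme(list(s_AA_f = 0, s_Aa_f = -0.01,
                                   s_aa_f = -0.05, sigma = 0.1))
  expect_equal(sch2$s_male, sch2$s_female)
  expect_error(read_fitness_scheme(list(sigma = 0.1)), "must contain")
  # the shipped example config parses to the workhorse scheme
  shipped <- read_fitness_scheme(
    system.file("extdata", "deleterious_scheme.yml", package = "gameticsel"))
  expect_equal(shipped, scheme_deleterious())
})

test_that("the polyandry selection surface contains the headline corner", {
  ex <- run_experiment("polyandry_surface", l_B_values = c(0, 5, 10))
  corner <- ex$result[ex$result$U == 1 & ex$result$l_B == 0, ]
  expect_equal(corner$s_tot, 0.015, tolerance = 1e-3)
  # balancing loci pull the net selection towards monandry
  col <- ex$result[ex$result$U == 1, ]
  expect_true(all(diff(col$s_tot[order(col$l_B)]) < 0))
  expect_s3_class(ex$plot, "ggplot")
})

test_that("the depression sweep collapses to the no-gametic baseline at k = 0", {
  ex <- run_experiment("depression_sweep", k_values = c(0, 0.5, 1),
                       sigma_values = c(0, 0.05, 0.12))
  base <- genome_summary(genome_spec(scheme_deleterious(sigma = 0),
                                     "outcrossing", 1, U = 0.5))$delta_bar
  at_k0 <- ex$result[ex$result$k == 0, ]
  expect_equal(at_k0$delta_bar, rep(base, nrow(at_k0)), tolerance = 1e-12)
})

test_that("load sweeps produce tidy grids and sensible monotonicity", {
  ex <- run_experiment("load_sweep", mode = "outcrossing",
                       sigma_values = c(0, 0.12),
                       level_values = c(0, 0.5, 1))
  expect_setequal(names(ex$result), c("sigma", "level", "load", "source"))
  sig0 <- ex$result[ex$result$sigma == 0, ]
  # without gametic selection selfing purges: load rises with outcrossing
  expect_true(all(diff(sig0$load[order(sig0$level)]) > 0))
  expect_s3_class(autoplot(ex), "ggplot")
})

test_that("direction-of-evolution matrix matches the analytic expectations", {
  chk <- invasion_direction_check(numerical = FALSE)$result
  expect_equal(chk$direction, c(
    "polyandry favoured", "monandry favoured", "neutral",
    "outcrossing favoured", "selfing favoured", "outcrossing favoured"))
})

test_that("experiment outputs are written with provenance metadata", {
  dir <- withr::local_tempdir()
  ex <- run_experiment("balancing_sweep", sigma_values = c(0, 0.05),
                       level_values = c(0, 1), seed = 3, out_dir = dir)
  expect_true(file.exists(file.path(dir, "balancing_sweep.tsv")))
  meta <- jsonlite::read_json(file.path(dir, "balancing_sweep_meta.json"))
  expect_equal(meta$seed, 3)
  expect_equal(meta$hash, ex$hash)
  # the same spec and seed reproduce the same table
  ex2 <- run_experiment("balancing_sweep", sigma_values = c(0, 0.05),
                        level_values = c(0, 1), seed = 3)
  expect_identical(ex$result, ex2$result)
})

test_that("headline validation checks pass end to end", {
  v <- validate_predictions()
  expect_true(all(v$pass))
})
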