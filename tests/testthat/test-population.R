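# Log-normal population, quantile quadrature, dose-response, IC50.

test_that("log-normal parameters reproduce the median/SD by Monte Carlo", {
  expect_equal(unname(lognormal_from_median_sd(8.18, 0)), c(log(8.18), 0))
  ln <- lognormal_from_median_sd(8.18, 4.31)
  expect_equal(unname(ln["sigma"]), 0.45175, tolerance = 1e-4)
  set.seed(5)
  for (sd in c(0.1, 1, 3)) {
    lm <- lognormal_from_median_sd(1, sd)
    x <- rlnorm(2e5, lm["mu"], lm["sigma"])
    expect_equal(median(x), 1, tolerance = 0.01)
    expect_equal(sd(x), sd, tolerance = 0.02 * sd + 0.01)
  }
  expect_error(lognormal_from_median_sd(0, 1), "median")
  expect_error(lognormal_from_median_sd(1, -1), "sd")
})

test_that("quantile grid is increasing and degenerates at sd = 0", {
  q <- cycb_quantiles(population_spec(8.18, 4.31, 32))
  expect_false(is.unsorted(q, strictly = TRUE))
  expect_equal(median(q), 8.18, tolerance = 0.02)
  q0 <- cycb_quantiles(population_spec(8.18, 0, 16))
  expect_equal(q0, rep(8.18, 16))
})

test_that("IC50 interpolation handles crossings, grid hits and flat curves", {
  expect_equal(ic50(data.frame(dose_uM = c(0, 1),
                               fraction_mitotic = c(1, 0))), 0.5)
  expect_equal(ic50(data.frame(dose_uM = c(0, 0.2, 0.4),
                               fraction_mitotic = c(1, 0.5, 0))), 0.2)
  expect_error(ic50(data.frame(dose_uM = c(0, 1),
                               fraction_mitotic = c(0.8, 0.8))), "never crosses")
})

test_that("binary-search grid classification equals exhaustive per-dose simulation", {
  p <- mito_params()
  g <- c(0, 0.05, 0.15, 0.4, 1)
  for (prot in c("entry", "exit")) {
    fast <- population_dose_response(p, "control", prot, small_pop, g)
    full <- population_dose_response(p, "control", prot, small_pop, g,
                                     exhaustive = TRUE)
    expect_identical(fast$fraction_mitotic, full$fraction_mitotic)
  }
})

test_that("a homogeneous population yields a step curve at the single-cell threshold", {
  p <- mito_params()
  spec0 <- population_spec(8.1808, 0, 16)
  g_entry <- seq(0.08, 0.16, by = 0.02)
  cu <- population_dose_response(p, "control", "entry", spec0, g_entry)
  expect_true(all(cu$fraction_mitotic %in% c(0, 1)))
  expect_false(is.unsorted(rev(cu$fraction_mitotic)))
  # the step sits within one grid cell of the entry fold
  f <- cached("folds_control", fold_points(p, "control"))
  step_at <- max(cu$dose_uM[cu$fraction_mitotic == 1])
  expect_lt(abs(step_at - f$fold_entry_uM), 0.021)
  g_exit <- seq(0.52, 0.64, by = 0.02)
  cx <- population_dose_response(p, "control", "exit", spec0, g_exit)
  step_x <- max(cx$dose_uM[cx$fraction_mitotic == 1])
  expect_lt(abs(step_x - f$fold_exit_uM), 0.021)
})

test_that("entry curves are non-increasing in dose and saturate correctly", {
  p <- mito_params()
  cu <- cached("curve_small_entry",
               population_dose_response(p, "control", "entry", small_pop,
                                        c(0, 0.05, 0.1, 0.2, 0.5, 2)))
  expect_false(is.unsorted(rev(cu$fraction_mitotic)))
  expect_gt(cu$fraction_mitotic[1], 0.9)    # nearly all enter without inhibitor
  expect_equal(cu$fraction_mitotic[nrow(cu)], 0)
})

test_that("stochastic sampling brackets the deterministic curve", {
  p <- mito_params()
  det <- cached("curve_small_entry",
                population_dose_response(p, "control", "entry", small_pop,
                                         c(0, 0.05, 0.1, 0.2, 0.5, 2)))
  det64 <- population_dose_response(p, "control", "entry",
                                    population_spec(n_quantiles = 64),
                                    c(0.05, 0.1, 0.2))
  for (s in 1:2) {
    samp <- population_dose_response(p, "control", "entry", small_pop,
                                     c(0.05, 0.1, 0.2), mode = "sample",
                                     n_cells = 200, seed = s)
    pr <- det64$fraction_mitotic
    band <- 2.6 * sqrt(pr * (1 - pr) / 200) + 1e-3
    expect_true(all(abs(samp$fraction_mitotic - pr) <= band + 0.03))
  }
})

test_that("hysteresis ratio exceeds 2 for control and collapses for the double perturbation", {
  p <- mito_params()
  grid <- c(0, exp(seq(log(0.02), log(2), length.out = 15)))
  hr_c <- hysteresis_ratio(p, "control", small_pop, grid)
  expect_gte(hr_c$ratio, 2)
  hr_d <- hysteresis_ratio(p, "wee1i_gwl_depleted", small_pop, grid)
  expect_lt(abs(hr_d$ratio - 1), 0.15)
})

test_that("quantile quadrature is converged: doubling nodes moves IC50 < 2%", {
  p <- mito_params()
  grid <- default_dose_grid()
  i64 <- ic50(population_dose_response(p, "control", "entry",
                                       population_spec(n_quantiles = 64), grid))
  i128 <- ic50(population_dose_response(p, "control", "entry",
                                        population_spec(n_quantiles = 128), grid))
  expect_lt(abs(i128 - i64) / i64, 0.02)
})

test_that("entry IC50s order by condition: gwl_depleted < control < wee1i", {
  p <- mito_params()
  grid <- c(0, exp(seq(log(0.02), log(2), length.out = 15)))
  e <- vapply(c("gwl_depleted", "control", "wee1i"), function(cond) {
    ic50(population_dose_response(p, cond, "entry", small_pop, grid))
  }, numeric(1))
  expect_lt(e[["gwl_depleted"]], e[["control"]])
  expect_lt(e[["control"]], e[["wee1i"]])
})
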