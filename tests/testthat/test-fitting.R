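# Objective behaviour and parameter recovery on synthetic data.

fit_grid <- c(0, exp(seq(log(0.02), log(2), length.out = 12)))

# noise-free curves for given truth, at the objective's own quadrature
truth_curves <- function(median_au, sd_au, conditions = c("control", "gwl_depleted"),
                         protocols = c("entry", "exit"), n_quantiles = 16,
                         grid = fit_grid) {
  cfg <- generator_config(conditions = conditions, protocols = protocols,
                          dose_grid = grid,
                          population = population_spec(median_au, sd_au,
                                                       n_quantiles),
                          seed = 1)
  generate_noise_free_curves(cfg)
}

test_that("objective is zero at the generating parameters and positive away from them", {
  curves <- cached("nf_small", truth_curves(8.18, 4.31))
  spec <- fit_spec(n_quantiles = 16)
  expect_lt(dr_objective(c(median_au = 8.18, sd_au = 4.31), curves, spec),
            1e-12)
  expect_equal(dr_objective(c(median_au = 8.18), list(), spec), 0)
  expect_gt(dr_objective(c(median_au = 8.18 * 1.5, sd_au = 4.31), curves,
                         spec), 0)
})

test_that("objective is deterministic and penalises invalid parameters finitely", {
  curves <- cached("nf_small", truth_curves(8.18, 4.31))
  spec <- fit_spec(n_quantiles = 16)
  v1 <- dr_objective(c(median_au = 6, sd_au = 3), curves, spec)
  v2 <- dr_objective(c(median_au = 6, sd_au = 3), curves, spec)
  expect_identical(v1, v2)
  expect_equal(dr_objective(c(median_au = -5, sd_au = 3), curves, spec), 1e6)
})

test_that("stage 1 recovers the generating cyclin B median from 50% levels", {
  curves <- cached("nf_small", truth_curves(8.18, 4.31))
  s1 <- fit_stage1_median(curves, fit_spec(n_quantiles = 16))
  expect_lt(abs(s1$median_au - 8.18) / 8.18, 0.05)
  curves4 <- truth_curves(4.0, 2.0)
  s1b <- fit_stage1_median(curves4, fit_spec(n_quantiles = 16))
  expect_lt(abs(s1b$median_au - 4.0) / 4.0, 0.05)
})

test_that("stage 1 excludes flat datasets and errors when none remain", {
  flat <- tibble::tibble(condition = "control", protocol = "entry",
                         dose_uM = c(0, 1, 2), repeat_id = 1,
                         n_mitotic = c(80, 80, 80), n_total = 100)
  expect_warning(expect_error(fit_stage1_median(flat), "unidentifiable"),
                 "excluded")
})

test_that("stage 2 recovers the spread, including the sd = 0 boundary", {
  curves <- cached("nf_small", truth_curves(8.18, 4.31))
  s2 <- fit_stage2_variance(curves, 8.18, fit_spec(n_quantiles = 16))
  expect_lt(abs(s2$sd_au - 4.31) / 4.31, 0.10)
  step_curves <- truth_curves(8.18, 0)
  s2z <- fit_stage2_variance(step_curves, 8.18, fit_spec(n_quantiles = 16))
  expect_lt(s2z$sd_au, 0.2)
})

test_that("recovery bias shrinks as the dose grid is refined", {
  coarse <- truth_curves(8.18, 4.31, conditions = "control",
                         grid = c(0, exp(seq(log(0.02), log(2), length.out = 6))))
  fine <- truth_curves(8.18, 4.31, conditions = "control",
                       grid = c(0, exp(seq(log(0.02), log(2), length.out = 24))))
  s_coarse <- fit_stage2_variance(coarse, 8.18, fit_spec(n_quantiles = 16))
  s_fine <- fit_stage2_variance(fine, 8.18, fit_spec(n_quantiles = 16))
  expect_lte(abs(s_fine$sd_au - 4.31), abs(s_coarse$sd_au - 4.31) + 0.05)
})

test_that("a free rate constant is recovered from noise-free data", {
  curves <- truth_curves(8.18, 4.31, conditions = "control",
                         protocols = "entry",
                         grid = c(0, exp(seq(log(0.02), log(2), length.out = 8))))
  fit <- fit_rate_constants(curves, free = list(kB55Sub = c(0.01, 0.4)),
                            spec = fit_spec(n_quantiles = 16, budget = 60))
  expect_lt(abs(fit$theta[["kB55Sub"]] - 0.0593) / 0.0593, 0.20)
})

test_that("rate-constant fitting respects budget and guards", {
  curves <- cached("nf_small", truth_curves(8.18, 4.31))
  z <- fit_rate_constants(curves, free = list(kB55Sub = c(0.01, 0.4)),
                          spec = fit_spec(budget = 0))
  expect_false(z$converged)
  expect_equal(z$evals, 0L)
  expect_equal(unname(z$theta), sqrt(0.01 * 0.4))
  expect_error(fit_rate_constants(curves,
                                  free = stats::setNames(
                                    rep(list(c(0.1, 1)), 7),
                                    names(mito_params())[1:7])),
               "at most 6")
  expect_error(fit_rate_constants(curves, free = list(bogus = c(0.1, 1))),
               "mito_params")
})

test_that("tidy and glance summarise fits broom-style", {
  curves <- cached("nf_small", truth_curves(8.18, 4.31))
  s1 <- fit_stage1_median(curves, fit_spec(n_quantiles = 16))
  td <- tidy(s1)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_true("median_au" %in% td$term)
  gl <- glance(s1)
  expect_equal(nrow(gl), 1)
  expect_true(is.numeric(gl$loss))
})

test_that("fit reports serialise to JSON with estimates and convergence", {
  curves <- cached("nf_small", truth_curves(8.18, 4.31))
  s1 <- fit_stage1_median(curves, fit_spec(n_quantiles = 16))
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_report(s1, f, seed = 17)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$estimates$median_au, s1$median_au)
  expect_equal(rep$seed, 17)
  expect_true(rep$converged)
})
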