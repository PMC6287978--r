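# Synthetic endpoint-assay generator: determinism, noise model, I/O.

tiny_config <- function(...) {
  generator_config(conditions = "control", protocols = "entry",
                   dose_grid = c(0, 0.1, 2), n_cells = 20, n_repeats = 2,
                   population = population_spec(n_quantiles = 16),
                   seed = 11, ...)
}

test_that("equal seeds give bit-identical datasets; subsets regenerate in isolation", {
  d1 <- generate_dataset(tiny_config())
  d2 <- generate_dataset(tiny_config())
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  # the same (condition, protocol, dose, repeat) stratum drawn alone matches
  cfg1 <- generator_config(conditions = "control", protocols = "entry",
                           dose_grid = c(0, 0.1, 2), n_cells = 20,
                           n_repeats = 1,
                           population = population_spec(n_quantiles = 16),
                           seed = 11)
  d3 <- generate_dataset(cfg1)
  expect_identical(
    as.data.frame(d1[d1$repeat_id == 1, ]),
    as.data.frame(d3))
})

test_that("a single deterministic cell is counted correctly at the extremes", {
  cfg <- generator_config(conditions = "control", protocols = "entry",
                          dose_grid = c(0, 2), n_cells = 1, n_repeats = 1,
                          population = population_spec(8.18, 0), seed = 1)
  d <- generate_dataset(cfg)
  expect_equal(d$n_mitotic[d$dose_uM == 0], 1)
  expect_equal(d$n_mitotic[d$dose_uM == 2], 0)
})

test_that("threshold shortcut equals direct per-cell simulation", {
  cfg <- generator_config(conditions = "control", protocols = c("entry", "exit"),
                          dose_grid = c(0, 0.1, 0.5), n_cells = 8,
                          n_repeats = 1,
                          population = population_spec(n_quantiles = 16),
                          seed = 21)
  dt <- generate_dataset(cfg, method = "threshold")
  ds <- generate_dataset(cfg, method = "simulate")
  expect_identical(dt$n_mitotic, ds$n_mitotic)
})

test_that("per-dose counts are binomial with the log-normal tail probability", {
  # counts are cells above the per-dose critical cyclin B; with iid log-normal
  # draws they must be Binomial(n, p), p from the distribution tail
  p <- mito_params()
  pop <- population_spec()
  cfg <- generator_config(conditions = "control", protocols = "entry",
                          dose_grid = c(0.05, 0.1, 0.15), n_cells = 100,
                          n_repeats = 200, population = pop, seed = 31)
  d <- generate_dataset(cfg)
  for (dose in cfg$dose_grid) {
    thr <- mitoswitch:::critical_cycb(p, "control", "entry", dose)
    prob <- 1 - plnorm(thr, pop$mu, pop$sigma)
    counts <- d$n_mitotic[d$dose_uM == dose]
    # chi-square goodness of fit over equal-probability binomial bins
    cuts <- unique(qbinom(seq(0, 1, length.out = 7), 100, prob))
    obs <- table(cut(counts, breaks = c(-1, cuts, 101)))
    expe <- diff(pbinom(c(-1, cuts, 101), 100, prob)) * length(counts)
    keep <- expe > 1e-9
    stat <- sum((as.numeric(obs)[keep] - expe[keep])^2 / expe[keep])
    pval <- pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
    expect_gt(pval, 0.01)
  }
})

test_that("empirical fractions converge to the noise-free curves (LLN)", {
  p <- mito_params()
  pop <- population_spec()
  cfg <- generator_config(conditions = "control", protocols = "entry",
                          dose_grid = c(0.05, 0.1, 0.2), n_cells = 10000,
                          n_repeats = 1, population = pop, seed = 41)
  d <- generate_dataset(cfg)
  nf <- generate_noise_free_curves(cfg)
  expect_lt(max(abs(d$n_mitotic / d$n_total - nf$fraction_mitotic)), 0.02)
})

test_that("control noise-free entry and exit curves cross 50% at different doses", {
  cfg <- generator_config(conditions = "control",
                          protocols = c("entry", "exit"),
                          dose_grid = default_dose_grid(15),
                          population = population_spec(n_quantiles = 16),
                          seed = 1)
  nf <- generate_noise_free_curves(cfg)
  e <- ic50(nf[nf$protocol == "entry", ])
  x <- ic50(nf[nf$protocol == "exit", ])
  expect_gt(x / e, 1.5)
})

test_that("datasets round-trip losslessly through the CSV reader", {
  d <- generate_dataset(tiny_config())
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, f)
  d2 <- read_dataset(f)
  expect_equal(as.data.frame(d)[, names(d2)], as.data.frame(d2),
               ignore_attr = TRUE)
  writeLines("a,b\n1,2", f)
  expect_error(read_dataset(f), "columns")
})

test_that("sd = 0 noise-free curves are step functions", {
  cfg <- generator_config(conditions = "control", protocols = "entry",
                          dose_grid = c(0, 0.05, 0.1, 0.15, 0.5),
                          population = population_spec(8.18, 0), seed = 1)
  nf <- generate_noise_free_curves(cfg)
  expect_true(all(nf$fraction_mitotic %in% c(0, 1)))
})
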