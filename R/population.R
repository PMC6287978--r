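# Population-level dose response: log-normal cyclin B heterogeneity,
# deterministic quantile quadrature, IC50 extraction, hysteresis ratio.

#' Log-normal parameters from natural-scale median and SD
#'
#' The cell population is heterogeneous only in total cyclin B, modelled as
#' log-normal with a given *median* and *arithmetic standard deviation* on the
#' natural (AU) scale. This solves for the underlying normal parameters:
#' `mu = log(median)` and `sigma` from the moment identity
#' `(exp(sigma^2) - 1) * exp(2*mu + sigma^2) = sd^2`, which is quadratic in
#' `exp(sigma^2)`.
#'
#' @param median_au median of the log-normal, AU (> 0).
#' @param sd_au arithmetic standard deviation, AU (>= 0).
#' @return Named numeric vector `c(mu, sigma)`.
#' @examples
#' lognormal_from_median_sd(8.18, 4.31)
#' @export
lognormal_from_median_sd <- function(median_au, sd_au) {
  if (median_au <= 0) stop("median must be > 0", call. = FALSE)
  if (sd_au < 0) stop("sd must be >= 0", call. = FALSE)
  mu <- log(median_au)
  if (sd_au == 0) return(c(mu = mu, sigma = 0))
  q <- sd_au^2 / exp(2 * mu)            # (x - 1) * x = q, x = exp(sigma^2)
  x <- (1 + sqrt(1 + 4 * q)) / 2
  if (x < 1) stop("no real sigma solves the moment equation", call. = FALSE)
  c(mu = mu, sigma = sqrt(log(x)))
}

#' Population specification
#'
#' @param median_au median total cyclin B, AU (default 8.18, the fitted
#'   population median).
#' @param sd_au arithmetic SD of total cyclin B, AU (default 4.31).
#' @param n_quantiles number of equal-probability strata for deterministic
#'   quadrature (midpoint rule; >= 16, default 64).
#' @return A list of class `mito_population`.
#' @export
population_spec <- function(median_au = 8.18, sd_au = 4.31,
                            n_quantiles = 64) {
  if (n_quantiles < 16) stop("n_quantiles must be >= 16", call. = FALSE)
  ln <- lognormal_from_median_sd(median_au, sd_au)
  structure(list(median_au = median_au, sd_au = sd_au,
                 n_quantiles = as.integer(n_quantiles),
                 mu = unname(ln["mu"]), sigma = unname(ln["sigma"])),
            class = "mito_population")
}

#' Deterministic quantile grid of the cyclin B distribution
#'
#' Midpoint quantiles of `n_quantiles` equal-probability strata:
#' `p_i = (i - 0.5) / n`. With `sd_au = 0` all nodes equal the median.
#'
#' @param spec a [population_spec()].
#' @return Numeric vector of cyclin B totals, AU, increasing.
#' @export
cycb_quantiles <- function(spec) {
  p <- (seq_len(spec$n_quantiles) - 0.5) / spec$n_quantiles
  if (spec$sigma == 0) return(rep(spec$median_au, spec$n_quantiles))
  stats::qlnorm(p, meanlog = spec$mu, sdlog = spec$sigma)
}

#' Default dose grid of the endpoint assay
#'
#' 25 log-spaced doses in `[0.01, 2]` uM plus 0, resolving both the tens-of-nM
#' (Greatwall-depleted) and the ~0.5 uM (control exit) regimes.
#'
#' @param n number of log-spaced points.
#' @param min_uM,max_uM grid limits, uM.
#' @return Sorted numeric vector of doses, uM (first element 0).
#' @export
default_dose_grid <- function(n = 25, min_uM = 0.01, max_uM = 2) {
  c(0, exp(seq(log(min_uM), log(max_uM), length.out = n)))
}

#' Population dose-response curve
#'
#' Fraction of cells mitotic at the assay endpoint versus inhibitor dose, for
#' one condition and protocol. Cells differ only in total cyclin B.
#'
#' Two evaluation modes: `"quantile"` (default) evaluates the per-cell
#' protocol on the deterministic midpoint-quantile grid of the cyclin B
#' distribution and averages the classifications; `"sample"` draws `n_cells`
#' log-normal cells with `seed`. Because the endpoint classification of a
#' given cell is non-increasing in dose, the per-cell classification across
#' the whole grid is resolved by binary search over the dose grid
#' (`exhaustive = FALSE`); set `exhaustive = TRUE` to force one simulation per
#' (cell, dose) pair (identical result, used for validation).
#'
#' @param params a [mito_params()] vector.
#' @param condition one of [mito_conditions()].
#' @param protocol `"entry"` or `"exit"`.
#' @param spec a [population_spec()].
#' @param dose_grid doses, uM.
#' @param mode `"quantile"` or `"sample"`.
#' @param n_cells,seed used by `mode = "sample"`.
#' @param cfg a [classification_config()].
#' @param exhaustive force per-(cell, dose) simulation.
#' @return A tibble of class `mito_curve` with `dose_uM`, `fraction_mitotic`,
#'   `condition`, `protocol`, `n_nodes`.
#' @examples
#' \donttest{
#' curve <- population_dose_response(mito_params(), "control", "entry",
#'                                   population_spec(n_quantiles = 16),
#'                                   dose_grid = c(0, 0.1, 0.3, 1))
#' }
#' @export
population_dose_response <- function(params, condition = "control",
                                     protocol = c("entry", "exit"),
                                     spec = population_spec(),
                                     dose_grid = default_dose_grid(),
                                     mode = c("quantile", "sample"),
                                     n_cells = 100, seed = 1L,
                                     cfg = classification_config(),
                                     exhaustive = FALSE) {
  protocol <- match.arg(protocol)
  mode <- match.arg(mode)
  validate_params(params)
  if (any(dose_grid < 0)) stop("doses must be >= 0", call. = FALSE)

  cells <- if (mode == "quantile") {
    cycb_quantiles(spec)
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    draws <- stats::rlnorm(n_cells, meanlog = spec$mu, sdlog = spec$sigma)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    draws
  }

  grid <- sort(dose_grid)
  mito <- matrix(FALSE, nrow = length(cells), ncol = length(grid))
  for (i in seq_along(cells)) {
    mito[i, ] <- cell_grid_classification(params, condition, protocol,
                                          cells[i], grid, cfg, exhaustive)
  }
  out <- tibble::tibble(
    dose_uM = grid,
    fraction_mitotic = colMeans(mito),
    condition = condition,
    protocol = protocol,
    n_nodes = length(cells)
  )
  class(out) <- c("mito_curve", class(tibble::tibble()))
  out
}

# Logical vector over the sorted dose grid for one cell. Uses monotonicity
# (mitotic at low dose, interphase at high dose, single flip) unless
# `exhaustive`; the binary search gives the identical grid classification.
cell_grid_classification <- function(params, condition, protocol, cycb,
                                     grid, cfg, exhaustive = FALSE) {
  eval_dose <- protocol_evaluator(params, condition, protocol, cycb, cfg)
  n <- length(grid)
  if (exhaustive) {
    return(vapply(grid, function(d) eval_dose(d) == "mitotic", logical(1)))
  }
  first <- eval_dose(grid[1]) == "mitotic"
  if (!first) return(rep(FALSE, n))
  if (n == 1) return(TRUE)
  last <- eval_dose(grid[n]) == "mitotic"
  if (last) return(rep(TRUE, n))
  # binary search for the last mitotic grid index
  lo <- 1L; hi <- n
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (eval_dose(grid[mid]) == "mitotic") lo <- mid else hi <- mid
  }
  c(rep(TRUE, lo), rep(FALSE, n - lo))
}

# Closure evaluating the protocol classification at a dose for one cell.
# For the exit protocol the shared inhibitor-free 90-min leg is cached.
protocol_evaluator <- function(params, condition, protocol, cycb, cfg) {
  p <- protocol_params(params, condition, cycb)
  if (protocol == "entry") {
    function(dose) {
      traj <- simulate_model(interphase_state(p), p, schedule = dose,
                             t_end = cfg$endpoint_time_min,
                             times = cfg$endpoint_time_min)
      classify_state(final_state(traj), p, cfg)
    }
  } else {
    pre <- simulate_model(interphase_state(p), p, schedule = 0,
                          t_end = 90, times = 90)
    y90 <- final_state(pre)
    function(dose) {
      traj <- simulate_model(y90, p, schedule = dose,
                             t_end = cfg$endpoint_time_min,
                             times = cfg$endpoint_time_min)
      classify_state(final_state(traj), p, cfg)
    }
  }
}

#' IC50 of a dose-response curve
#'
#' Dose at which the curve crosses 50% mitotic, by piecewise-linear
#' interpolation on the dose grid; with several crossings (numeric noise) the
#' first from low dose is used. A curve that never crosses 0.5 raises an
#' explicit error.
#'
#' @param curve a [population_dose_response()] tibble (or any data frame with
#'   `dose_uM` and `fraction_mitotic`).
#' @return IC50 in uM.
#' @examples
#' ic50(data.frame(dose_uM = c(0, 1), fraction_mitotic = c(1, 0)))
#' @export
ic50 <- function(curve) {
  d <- curve$dose_uM
  f <- curve$fraction_mitotic
  o <- order(d)
  d <- d[o]; f <- f[o]
  if (any(f == 0.5)) return(d[which(f == 0.5)[1]])
  cross <- which(diff(sign(f - 0.5)) != 0)
  if (!length(cross)) {
    stop("dose-response curve never crosses 50% mitotic", call. = FALSE)
  }
  i <- cross[1]
  d[i] + (0.5 - f[i]) * (d[i + 1] - d[i]) / (f[i + 1] - f[i])
}

#' Hysteresis ratio of exit over entry IC50
#'
#' Computes the entry and exit population dose-response curves for one
#' condition and returns `ic50(exit) / ic50(entry)` along with both IC50s.
#'
#' @inheritParams population_dose_response
#' @return A tibble with `condition`, `ic50_entry_uM`, `ic50_exit_uM`,
#'   `ratio`.
#' @export
hysteresis_ratio <- function(params, condition = "control",
                             spec = population_spec(),
                             dose_grid = default_dose_grid(),
                             cfg = classification_config()) {
  entry <- population_dose_response(params, condition, "entry", spec,
                                    dose_grid, cfg = cfg)
  exit <- population_dose_response(params, condition, "exit", spec,
                                   dose_grid, cfg = cfg)
  e <- ic50(entry); x <- ic50(exit)
  tibble::tibble(condition = condition, ic50_entry_uM = e,
                 ic50_exit_uM = x, ratio = x / e)
}
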