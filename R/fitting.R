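# Two-stage estimation of the cyclin B distribution from endpoint-assay
# dose-response data, plus an opt-in rate-constant fitter (seeded global
# screen + local refinement), with broom-style accessors.

#' Fit specification
#'
#' @param n_quantiles quadrature nodes used inside the objective (default 32;
#'   the acceptance-grade curves use 64, but the objective converges well
#'   before that).
#' @param median_bounds,sd_bounds search bounds for the two-stage cyclin B
#'   fit, AU.
#' @param budget maximum objective evaluations for [fit_rate_constants()].
#' @param seed seed for the global screen.
#' @param cfg a [classification_config()].
#' @return A list of class `mito_fit_spec`.
#' @export
fit_spec <- function(n_quantiles = 32, median_bounds = c(1, 30),
                     sd_bounds = c(0, 15), budget = 200, seed = 1L,
                     cfg = classification_config()) {
  stopifnot(median_bounds[1] > 0, diff(median_bounds) > 0,
            sd_bounds[1] >= 0, diff(sd_bounds) > 0, budget >= 0)
  structure(list(n_quantiles = n_quantiles, median_bounds = median_bounds,
                 sd_bounds = sd_bounds, budget = budget,
                 seed = as.integer(seed), cfg = cfg),
            class = "mito_fit_spec")
}

# split a stacked dataset tibble into per-(condition, protocol) groups with
# per-dose mean observed fractions
dataset_groups <- function(datasets) {
  if (inherits(datasets, "data.frame")) datasets <- list(datasets)
  df <- dplyr::bind_rows(lapply(datasets, tibble::as_tibble))
  if (!nrow(df)) return(df[0, ])
  df$fraction <- if ("n_mitotic" %in% names(df)) {
    df$n_mitotic / df$n_total
  } else if ("fraction_mitotic" %in% names(df)) {
    df$fraction_mitotic          # noise-free curves as infinite-N datasets
  } else {
    stop("datasets need n_mitotic/n_total or fraction_mitotic columns",
         call. = FALSE)
  }
  df |>
    dplyr::group_by(.data$condition, .data$protocol, .data$dose_uM) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop")
}

#' Least-squares objective against observed dose-response data
#'
#' Sum over all (condition, protocol, dose) cells of the squared difference
#' between the simulated fraction mitotic (deterministic quantile mode) and
#' the observed mean fraction. A simulation failure at a parameter vector
#' returns a large finite penalty (`1e6`) so optimizers continue.
#'
#' @param theta named numeric vector of free parameters; recognised names are
#'   `median_au`, `sd_au`, and any [mito_params()] rate constant or pool.
#' @param datasets a `mito_dataset` tibble (or list of them).
#' @param spec a [fit_spec()].
#' @param params base parameter set for entries not in `theta`.
#' @param population base population for `median_au`/`sd_au` not in `theta`.
#' @return Scalar loss (>= 0).
#' @export
dr_objective <- function(theta, datasets, spec = fit_spec(),
                         params = mito_params(),
                         population = population_spec()) {
  obs <- dataset_groups(datasets)
  if (!nrow(obs)) return(0)
  tryCatch({
    pars <- params
    med <- population$median_au
    sdv <- population$sd_au
    if (is.null(names(theta)) && length(theta)) {
      stop("theta must be named", call. = FALSE)
    }
    for (nm in names(theta)) {
      if (nm == "median_au") {
        med <- theta[[nm]]
      } else if (nm == "sd_au") {
        sdv <- theta[[nm]]
      } else if (nm %in% names(pars)) {
        pars[[nm]] <- theta[[nm]]
      } else {
        stop("unknown free parameter: ", nm, call. = FALSE)
      }
    }
    pars <- structure(pars, class = c("mito_params", "numeric"))
    validate_params(pars)
    pop <- population_spec(med, sdv, n_quantiles = spec$n_quantiles)
    loss <- 0
    groups <- unique(obs[, c("condition", "protocol")])
    for (g in seq_len(nrow(groups))) {
      sub <- obs[obs$condition == groups$condition[g] &
                 obs$protocol == groups$protocol[g], ]
      sim <- population_dose_response(pars, groups$condition[g],
                                      groups$protocol[g], pop,
                                      dose_grid = sub$dose_uM,
                                      cfg = spec$cfg)
      sim <- sim[match(round(sub$dose_uM, 12), round(sim$dose_uM, 12)), ]
      loss <- loss + sum((sim$fraction_mitotic - sub$fraction)^2)
    }
    loss
  }, error = function(e) 1e6)
}

# Empirical IC50 of one observed group; NA when no 50% crossing.
empirical_ic50 <- function(sub) {
  tryCatch(ic50(data.frame(dose_uM = sub$dose_uM,
                           fraction_mitotic = sub$fraction)),
           error = function(e) NA_real_)
}

#' Stage 1: fit the cyclin B median from 50% levels
#'
#' Matches simulated to empirical IC50s across every (condition, protocol)
#' group with a homogeneous population (`sd = 0`): for a homogeneous
#' population the simulated IC50 is the single-cell threshold dose of a cell
#' carrying the candidate median cyclin B, found by bisection. The median
#' minimises the summed squared IC50 differences (bounded 1-D optimisation).
#' Groups whose empirical curve never crosses 50% are excluded with a
#' warning; if none remain, an error is raised.
#'
#' @inheritParams dr_objective
#' @return A list of class `mito_fit` with `median_au`, `loss`, `groups`.
#' @export
fit_stage1_median <- function(datasets, spec = fit_spec(),
                              params = mito_params()) {
  obs <- dataset_groups(datasets)
  groups <- unique(obs[, c("condition", "protocol")])
  groups$ic50 <- vapply(seq_len(nrow(groups)), function(g) {
    empirical_ic50(obs[obs$condition == groups$condition[g] &
                       obs$protocol == groups$protocol[g], ])
  }, numeric(1))
  drop <- is.na(groups$ic50)
  if (any(drop)) {
    warning(sum(drop), " dataset group(s) without a 50% crossing excluded",
            call. = FALSE)
    groups <- groups[!drop, ]
  }
  if (!nrow(groups)) {
    stop("no dataset group crosses 50%; the median is unidentifiable",
         call. = FALSE)
  }
  dose_hi <- max(obs$dose_uM) * 1.2 + 0.1
  sim_ic50 <- function(median_au) {
    vapply(seq_len(nrow(groups)), function(g) {
      single_cell_threshold_dose(params, groups$condition[g],
                                 groups$protocol[g], median_au,
                                 c(0, dose_hi), spec$cfg)
    }, numeric(1))
  }
  obj <- function(m) {
    s <- sim_ic50(m)
    sum((s - groups$ic50)^2, na.rm = TRUE) +
      1e3 * sum(is.na(s))          # medians making a threshold undefined
  }
  opt <- stats::optimize(obj, interval = spec$median_bounds, tol = 1e-3)
  structure(list(stage = "median", median_au = opt$minimum,
                 loss = opt$objective, groups = groups),
            class = "mito_fit")
}

# Single-cell flip dose for a given cyclin B total: the dose below which the
# protocol classifies mitotic and above which interphase (bisection).
# NA when no flip exists inside `dose_range`.
single_cell_threshold_dose <- function(params, condition, protocol, cycb,
                                       dose_range, cfg) {
  f <- protocol_evaluator(params, condition, protocol, cycb, cfg)
  lo <- dose_range[1]; hi <- dose_range[2]
  if (f(lo) != "mitotic") return(NA_real_)
  if (f(hi) == "mitotic") return(NA_real_)
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (f(mid) == "mitotic") lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Stage 2: fit the cyclin B distribution spread
#'
#' With the median fixed from stage 1, minimises the full-curve least-squares
#' objective [dr_objective()] over the arithmetic SD of the log-normal
#' cyclin B distribution (bounded 1-D optimisation).
#'
#' @inheritParams dr_objective
#' @param median_au the stage-1 median, AU.
#' @return A list of class `mito_fit` with `sd_au`, `median_au`, `loss`.
#' @export
fit_stage2_variance <- function(datasets, median_au, spec = fit_spec(),
                                params = mito_params()) {
  obj <- function(s) {
    dr_objective(c(median_au = median_au, sd_au = s), datasets, spec,
                 params = params)
  }
  opt <- stats::optimize(obj, interval = spec$sd_bounds, tol = 1e-3)
  structure(list(stage = "variance", median_au = median_au,
                 sd_au = opt$minimum, loss = opt$objective),
            class = "mito_fit")
}

#' Canonical two-stage cyclin B distribution fit
#'
#' Runs [fit_stage1_median()] then [fit_stage2_variance()].
#'
#' @inheritParams dr_objective
#' @return A list of class `mito_fit` with `median_au`, `sd_au`, `loss`.
#' @export
fit_cycb_distribution <- function(datasets, spec = fit_spec(),
                                  params = mito_params()) {
  s1 <- fit_stage1_median(datasets, spec, params)
  s2 <- fit_stage2_variance(datasets, s1$median_au, spec, params)
  structure(list(stage = "two-stage", median_au = s1$median_au,
                 sd_au = s2$sd_au, loss = s2$loss,
                 stage1_loss = s1$loss),
            class = "mito_fit")
}

#' Opt-in rate-constant fitting
#'
#' Bounded minimisation of [dr_objective()] over up to six named rate
#' constants: a seeded Latin-hypercube global screen followed by `nlminb`
#' local refinement from the best screen point, within an evaluation budget.
#' With a zero budget the (geometric) mid-bound initial guess is returned
#' flagged non-converged.
#'
#' @inheritParams dr_objective
#' @param free named list of `c(lower, upper)` bounds, one per free rate
#'   constant (at most 6).
#' @param population population used while simulating (fixed).
#' @return A list of class `mito_fit` with `theta`, `loss`, `evals`,
#'   `converged`.
#' @export
fit_rate_constants <- function(datasets, free, spec = fit_spec(),
                               params = mito_params(),
                               population = population_spec()) {
  if (length(free) > 6) {
    stop("at most 6 free rate constants (identifiability guard)",
         call. = FALSE)
  }
  nm <- names(free)
  if (is.null(nm) || !all(nm %in% names(params))) {
    stop("free parameters must name mito_params fields", call. = FALSE)
  }
  lower <- vapply(free, `[`, numeric(1), 1)
  upper <- vapply(free, `[`, numeric(1), 2)
  if (any(lower <= 0) || any(!is.finite(upper))) {
    stop("bounds must be finite and positive", call. = FALSE)
  }
  evals <- 0L
  obj <- function(x) {
    evals <<- evals + 1L
    dr_objective(stats::setNames(x, nm), datasets, spec, params = params,
                 population = population)
  }
  x0 <- sqrt(lower * upper)
  if (spec$budget == 0) {
    return(structure(list(theta = stats::setNames(x0, nm), loss = NA_real_,
                          evals = 0L, converged = FALSE),
                     class = "mito_fit"))
  }
  n_screen <- max(4L, min(spec$budget %/% 3L, 40L))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  H <- lhs::randomLHS(n_screen, length(free))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  # screen on log scale between the bounds
  cand <- t(apply(H, 1, function(u) exp(log(lower) + u * (log(upper) - log(lower)))))
  cand <- rbind(x0, cand)
  losses <- apply(cand, 1, obj)
  best <- cand[which.min(losses), ]
  budget_left <- max(spec$budget - evals, 0L)
  converged <- FALSE
  theta <- best
  loss <- min(losses)
  if (budget_left > 0) {
    fit <- stats::nlminb(best, obj, lower = lower, upper = upper,
                         control = list(eval.max = budget_left,
                                        iter.max = budget_left))
    theta <- fit$par
    loss <- fit$objective
    converged <- fit$convergence == 0
  }
  structure(list(theta = stats::setNames(theta, nm), loss = loss,
                 evals = evals, converged = converged),
            class = "mito_fit")
}

#' @export
print.mito_fit <- function(x, ...) {
  cat("<mito_fit>", x$stage %||% "rate constants", "\n")
  utils::str(x[setdiff(names(x), "groups")], give.attr = FALSE)
  invisible(x)
}

#' Tidy a fitted object
#'
#' Broom-style accessors: `tidy()` returns one row per fitted parameter,
#' `glance()` a one-row model summary.
#'
#' @param x a `mito_fit` object.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.mito_fit <- function(x, ...) {
  if (!is.null(x$theta)) {
    return(tibble::tibble(term = names(x$theta),
                          estimate = as.numeric(x$theta)))
  }
  est <- c(median_au = x$median_au, sd_au = x$sd_au)
  est <- est[!is.na(names(est)) & !vapply(est, is.null, logical(1))]
  tibble::tibble(term = names(est), estimate = as.numeric(est))
}

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
glance.mito_fit <- function(x, ...) {
  tibble::tibble(stage = x$stage %||% "rate_constants",
                 loss = x$loss %||% NA_real_,
                 evals = x$evals %||% NA_integer_,
                 converged = x$converged %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSON fit report
#'
#' Serialises a `mito_fit` to JSON: fitted values, loss, evaluation count,
#' and convergence flag.
#'
#' @param fit a `mito_fit` object.
#' @param path output file.
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, seed = NULL) {
  td <- tidy(fit)
  report <- list(
    estimates = stats::setNames(as.list(td$estimate), td$term),
    stage = fit$stage %||% "rate_constants",
    loss = fit$loss %||% NA_real_,
    evals = fit$evals %||% NA_integer_,
    converged = fit$converged %||% TRUE,
    seed = seed
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
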