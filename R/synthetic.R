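# Synthetic endpoint-assay datasets: log-normal cyclin B heterogeneity,
# binomial counting noise over repeats, seeded reproducibly per stratum.

#' Generator configuration for synthetic endpoint-assay data
#'
#' Emulates the statistical structure of the endpoint bistability assay:
#' per dose and biological repeat, `n_cells` cells are drawn from the
#' log-normal cyclin B distribution, each cell runs the protocol, and the
#' mitotic cells are counted.
#'
#' @param true_params ground-truth [mito_params()].
#' @param conditions subset of [mito_conditions()].
#' @param protocols subset of `c("entry", "exit")`.
#' @param dose_grid doses, uM.
#' @param n_cells cells scored per repeat (default 100).
#' @param n_repeats biological repeats (default 3).
#' @param population a [population_spec()].
#' @param seed master seed; per-(condition, protocol, dose, repeat) streams
#'   are derived from it by a fixed counter scheme so any subset regenerates
#'   identically in isolation.
#' @param cfg a [classification_config()].
#' @return A list of class `mito_generator_config`.
#' @export
generator_config <- function(true_params = mito_params(),
                             conditions = mito_conditions(),
                             protocols = c("entry", "exit"),
                             dose_grid = default_dose_grid(),
                             n_cells = 100, n_repeats = 3,
                             population = population_spec(),
                             seed = 1L,
                             cfg = classification_config()) {
  validate_params(true_params)
  conditions <- match.arg(conditions, mito_conditions(), several.ok = TRUE)
  protocols <- match.arg(protocols, c("entry", "exit"), several.ok = TRUE)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  structure(list(true_params = true_params, conditions = conditions,
                 protocols = protocols, dose_grid = sort(dose_grid),
                 n_cells = as.integer(n_cells),
                 n_repeats = as.integer(n_repeats),
                 population = population, seed = as.integer(seed),
                 cfg = cfg),
            class = "mito_generator_config")
}

# Critical cyclin B at one dose: cells with CycBTot above the returned value
# classify mitotic, below interphase (classification is monotone increasing
# in cyclin B; validated in tests against direct per-cell simulation).
# Returns Inf when even `hi` stays interphase, 0 when even `lo` is mitotic.
critical_cycb <- function(params, condition, protocol, dose,
                          cfg = classification_config(),
                          lo = 1e-3, hi = 60, tol = 1e-4) {
  run <- function(cycb) {
    f <- protocol_evaluator(params, condition, protocol, cycb, cfg)
    f(dose) == "mitotic"
  }
  if (run(lo)) return(0)
  if (!run(hi)) return(Inf)
  while (hi / lo > 1 + tol) {
    mid <- sqrt(lo * hi)
    if (run(mid)) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

#' Generate a synthetic endpoint-assay dataset
#'
#' For each condition x protocol x dose x repeat, draws `n_cells` cyclin B
#' values from the log-normal population (derived seed), classifies each cell
#' by the in-silico protocol, and records the mitotic count. By default the
#' per-cell classification goes through the per-dose critical cyclin B level
#' (bisection once per dose, then a threshold comparison for every cell);
#' `method = "simulate"` integrates every cell explicitly (identical result,
#' used for validation).
#'
#' @param config a [generator_config()].
#' @param method `"threshold"` (default) or `"simulate"`.
#' @return A tibble of class `mito_dataset` with columns `condition`,
#'   `protocol`, `dose_uM`, `repeat_id`, `n_mitotic`, `n_total`, and
#'   attributes `seed` and `true_params`.
#' @export
generate_dataset <- function(config, method = c("threshold", "simulate")) {
  method <- match.arg(method)
  cfgs <- expand.grid(condition = config$conditions,
                      protocol = config$protocols,
                      stringsAsFactors = FALSE)
  rows <- list()
  for (k in seq_len(nrow(cfgs))) {
    cond <- cfgs$condition[k]
    prot <- cfgs$protocol[k]
    thresholds <- if (method == "threshold") {
      vapply(config$dose_grid, function(d) {
        critical_cycb(config$true_params, cond, prot, d, config$cfg)
      }, numeric(1))
    } else NULL
    for (di in seq_along(config$dose_grid)) {
      dose <- config$dose_grid[di]
      for (r in seq_len(config$n_repeats)) {
        cells <- draw_cells(config, cond, prot, di, r)
        n_mit <- if (method == "threshold") {
          sum(cells > thresholds[di])
        } else {
          sum(vapply(cells, function(cb) {
            f <- protocol_evaluator(config$true_params, cond, prot, cb,
                                    config$cfg)
            f(dose) == "mitotic"
          }, logical(1)))
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          condition = cond, protocol = prot, dose_uM = dose,
          repeat_id = r, n_mitotic = n_mit, n_total = config$n_cells
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- config$seed
  attr(out, "true_params") <- config$true_params
  class(out) <- c("mito_dataset", class(tibble::tibble()))
  out
}

# Derived seed stream: master seed offset by a fixed counter over
# (condition index, protocol index, dose index, repeat); keeps any subset
# reproducible in isolation. Offsets stay well below 2^31.
draw_cells <- function(config, condition, protocol, dose_index, repeat_id) {
  ci <- match(condition, mito_conditions())
  pi_ <- match(protocol, c("entry", "exit"))
  counter <- ((ci * 7 + pi_) * 1009 + dose_index) * 101 + repeat_id
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed((config$seed + counter) %% .Machine$integer.max)
  cells <- stats::rlnorm(config$n_cells, meanlog = config$population$mu,
                         sdlog = config$population$sigma)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  cells
}

#' Noise-free population curves for a generator configuration
#'
#' Deterministic quantile-mode dose-response curves on the same grid, the
#' infinite-cell limit of [generate_dataset()]; the fitting module's
#' recovery tests use them as ground truth.
#'
#' @param config a [generator_config()].
#' @return A tibble of stacked [population_dose_response()] curves.
#' @export
generate_noise_free_curves <- function(config) {
  combos <- expand.grid(condition = config$conditions,
                        protocol = config$protocols,
                        stringsAsFactors = FALSE)
  purrr::pmap_dfr(combos, function(condition, protocol) {
    population_dose_response(config$true_params, condition, protocol,
                             config$population, config$dose_grid,
                             cfg = config$cfg)
  })
}

#' Read / write endpoint-assay datasets
#'
#' CSV schema: `condition, protocol, dose_uM, repeat_id, n_mitotic, n_total`.
#'
#' @param path CSV file path.
#' @return `read_dataset()` returns a `mito_dataset` tibble.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "protocol", "dose_uM", "repeat_id",
            "n_mitotic", "n_total")
  if (!all(need %in% names(df))) {
    stop("dataset CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$n_mitotic < 0 | df$n_mitotic > df$n_total) ||
      any(df$dose_uM < 0)) {
    stop("dataset violates count/dose bounds", call. = FALSE)
  }
  out <- tibble::as_tibble(df[, need])
  class(out) <- c("mito_dataset", class(tibble::tibble()))
  out
}

#' @param dataset a `mito_dataset` tibble.
#' @rdname read_dataset
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset)[, c("condition", "protocol",
                                              "dose_uM", "repeat_id",
                                              "n_mitotic", "n_total")],
                   path, row.names = FALSE)
  invisible(path)
}
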