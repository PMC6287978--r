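# Reproducible end-to-end analysis: config loading with schema validation,
# the full result bundle (sweeps, folds, dose-response, IC50s, prophase scan,
# multistability census), and run manifests.

.config_defaults <- function() {
  list(
    params_variant = "xpp",
    params = list(),                  # named overrides of mito_params fields
    conditions = mito_conditions(),
    median_au = 8.18,
    sd_au = 4.31,
    n_quantiles = 64,
    dose_grid_n = 25,
    dose_min_uM = 0.01,
    dose_max_uM = 2,
    census_doses = 41,
    prophase_doses = c(0.5, 1.0),
    prophase_readd_min = 25,
    prophase_nodes = 17,
    mitotic_threshold = 0.30,
    endpoint_time_min = 240,
    seed = 1
  )
}

#' Load and validate a pipeline configuration
#'
#' Config files are YAML mappings. Unknown keys are rejected by name; missing
#' keys take the canonical defaults (XPP parameter set, fitted population
#' median 8.18 AU / SD 4.31 AU, 64 quantile nodes, 25 log-spaced doses in
#' `[0.01, 2]` uM plus 0). An empty file yields all defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A list of class `mito_config` including the resolved `params`
#'   vector and `population`.
#' @export
load_config <- function(path = NULL) {
  defaults <- .config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg <- utils::modifyList(defaults, user)
  bad_cond <- setdiff(cfg$conditions, mito_conditions())
  if (length(bad_cond)) {
    stop("unknown condition(s) in config: ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  }
  params <- do.call(mito_params, c(cfg$params, list(variant = cfg$params_variant)))
  structure(c(cfg, list(
    resolved_params = params,
    population = population_spec(cfg$median_au, cfg$sd_au, cfg$n_quantiles),
    classify = classification_config(cfg$mitotic_threshold,
                                     cfg$endpoint_time_min),
    dose_grid = default_dose_grid(cfg$dose_grid_n, cfg$dose_min_uM,
                                  cfg$dose_max_uM)
  )), class = "mito_config")
}

#' Run the full model analysis pipeline
#'
#' Executes, per condition: signal-response up/down sweeps, fold points,
#' entry and exit population dose-response curves with IC50s; then the
#' prophase-capture scan over the cyclin B quantile grid at the configured
#' re-addition doses, and the multistability census over dose. Writes one CSV
#' per table, an `ic50.json` summary, and a `manifest.json` recording the
#' config, seed, parameter hash, package version and timestamps. All
#' randomness flows from the manifest-recorded seed, so a rerun reproduces
#' the outputs bit-identically.
#'
#' @param outdir output directory (created if needed).
#' @param config a [load_config()] result (default: all defaults).
#' @param quiet suppress progress lines.
#' @return Invisibly, a named list of the result tables.
#' @export
run_pipeline <- function(outdir, config = load_config(), quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  params <- config$resolved_params
  pop <- config$population
  ccfg <- config$classify
  grid <- config$dose_grid

  branches <- list(); folds <- list(); curves <- list(); ic <- list()
  for (cond in config$conditions) {
    t1 <- Sys.time()
    up <- sweep_signal_response(params, cond, grid, "up")
    dn <- sweep_signal_response(params, cond, grid, "down")
    branches[[cond]] <- dplyr::bind_rows(up, dn) |>
      dplyr::mutate(condition = cond, .before = 1)
    folds[[cond]] <- fold_points(params, cond, c(0, max(grid)), cfg = ccfg)
    say("sweep+folds     %-20s %5.1f s", cond,
        as.numeric(Sys.time() - t1, units = "secs"))
    for (prot in c("entry", "exit")) {
      t1 <- Sys.time()
      cu <- population_dose_response(params, cond, prot, pop, grid, cfg = ccfg)
      curves[[paste(cond, prot)]] <- cu
      ic[[paste(cond, prot)]] <- tibble::tibble(
        condition = cond, protocol = prot,
        ic50_uM = tryCatch(ic50(cu), error = function(e) NA_real_)
      )
      say("dose-response   %-20s %-5s %5.1f s", cond, prot,
          as.numeric(Sys.time() - t1, units = "secs"))
    }
  }
  branches <- dplyr::bind_rows(branches)
  folds <- dplyr::bind_rows(folds)
  curves <- dplyr::bind_rows(curves)
  ic50s <- dplyr::bind_rows(ic)

  # prophase-capture scan over the cyclin B quantile grid
  t1 <- Sys.time()
  pro_nodes <- cycb_quantiles(population_spec(pop$median_au, pop$sd_au,
                                              max(config$prophase_nodes, 16)))
  prophase <- purrr::map_dfr(config$prophase_doses, function(d) {
    fp_cache <- list()
    labs <- vapply(pro_nodes, function(cb) {
      key <- sprintf("%.6f", cb)
      p <- protocol_params(params, "control", cb)
      if (is.null(fp_cache[[key]])) {
        fp_cache[[key]] <<- find_fixed_points(p, dose = d)
      }
      run_prophase_protocol(params, "control", d,
                            readd_time = config$prophase_readd_min,
                            cycb_tot = cb, cfg = ccfg,
                            fixed_points = fp_cache[[key]])
    }, character(1))
    tibble::tibble(dose_uM = d, cycb_au = pro_nodes, outcome = labs)
  })
  say("prophase scan   %5.1f s", as.numeric(Sys.time() - t1, units = "secs"))

  # multistability census
  t1 <- Sys.time()
  census_grid <- seq(0, max(grid), length.out = config$census_doses)
  census <- purrr::map_dfr(config$conditions, function(cond) {
    cs <- count_stable_states(params, cond, census_grid)
    dplyr::mutate(cs$per_dose, condition = cond, .before = 1)
  })
  census_max <- census |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(max_stable = max(.data$n_stable), .groups = "drop")
  say("census          %5.1f s", as.numeric(Sys.time() - t1, units = "secs"))

  utils::write.csv(branches, file.path(outdir, "branches.csv"), row.names = FALSE)
  utils::write.csv(folds, file.path(outdir, "fold_points.csv"), row.names = FALSE)
  utils::write.csv(curves, file.path(outdir, "dose_response.csv"), row.names = FALSE)
  utils::write.csv(ic50s, file.path(outdir, "ic50.csv"), row.names = FALSE)
  utils::write.csv(prophase, file.path(outdir, "prophase_scan.csv"), row.names = FALSE)
  utils::write.csv(census, file.path(outdir, "census.csv"), row.names = FALSE)
  jsonlite::write_json(
    stats::setNames(as.list(ic50s$ic50_uM),
                    paste(ic50s$condition, ic50s$protocol, sep = "_")),
    file.path(outdir, "ic50.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(outdir, config, t0)

  invisible(list(branches = branches, folds = folds, curves = curves,
                 ic50s = ic50s, prophase = prophase, census = census,
                 census_max = census_max))
}

write_manifest <- function(outdir, config, t0) {
  cfg <- config[setdiff(names(config),
                        c("resolved_params", "population", "classify",
                          "dose_grid"))]
  manifest <- list(
    command = "run_pipeline",
    package = "mitoswitch",
    version = as.character(utils::packageVersion("mitoswitch")),
    seed = config$seed,
    config = cfg,
    params = as.list(stats::setNames(as.numeric(config$resolved_params),
                                     names(config$resolved_params))),
    params_hash = param_hash(config$resolved_params),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# cheap dependency-free content hash of a parameter vector
param_hash <- function(params) {
  s <- paste(names(params), format(as.numeric(params), digits = 15),
             collapse = ";")
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}
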