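# Parameter sets, experimental conditions, and flat-file parameter I/O.

# Fixed internal order of the parameter vector handed to the compiled RHS
# (the 35th slot, "inhibitor", is appended at call time).
.par_order <- c(
  "kaPP1", "kaPP1a", "kiPP1", "kCdk1PP1", "kPP1Gwl",
  "kass", "kdis", "kcatB55", "kGwlENSA", "kPPXGwl",
  "kCdk1Sub", "kCdk1Gwl", "kB55Gwl", "kB55Sub", "kCdk2Gwl",
  "kCdc25S", "kCdc25F", "kWee1S", "kWee1F", "kCdk1Wee1",
  "kCdk1Cdc25", "kPPXY15", "kCdk2Wee1", "kCdk2Cdc25", "kB55Wee1",
  "kB55Cdc25", "CycBTot", "Cdk2Tot", "PP1Tot", "ENSATot",
  "B55Tot", "GwlTot", "SubTot", "Kd"
)

.params_xpp <- c(
  kaPP1 = 0.0115, kaPP1a = 0.7054, kiPP1 = 0.0018, kCdk1PP1 = 0.7549,
  kPP1Gwl = 18.4724, kass = 617.2807, kdis = 0.0088, kcatB55 = 1.0338,
  kGwlENSA = 20.8811, kPPXGwl = 0.1560, kCdk1Sub = 0.0080,
  kCdk1Gwl = 0.2393, kB55Gwl = 496.5636, kB55Sub = 0.0593,
  kCdk2Gwl = 0.1916, kCdc25S = 0.0050, kCdc25F = 0.9411,
  kWee1S = 0.0050, kWee1F = 47.2937, kCdk1Wee1 = 1.3132,
  kCdk1Cdc25 = 1.3132, kPPXY15 = 0.0050, kCdk2Wee1 = 0.1096,
  kCdk2Cdc25 = 0.1096, kB55Wee1 = 0.5511, kB55Cdc25 = 0.5511,
  CycBTot = 8.1808, Cdk2Tot = 1, PP1Tot = 1, ENSATot = 1,
  B55Tot = 0.25, GwlTot = 1, SubTot = 1, Kd = 0.025
)

# Rounded values as printed in the descriptive parameter table.
.params_table <- c(
  kaPP1 = 0.01, kaPP1a = 0.70, kiPP1 = 0.002, kCdk1PP1 = 0.75,
  kPP1Gwl = 18.47, kass = 617, kdis = 0.009, kcatB55 = 1,
  kGwlENSA = 21, kPPXGwl = 0.16, kCdk1Sub = 0.008,
  kCdk1Gwl = 0.24, kB55Gwl = 496, kB55Sub = 0.06,
  kCdk2Gwl = 0.19, kCdc25S = 0.005, kCdc25F = 0.94,
  kWee1S = 0.005, kWee1F = 47, kCdk1Wee1 = 1.31,
  kCdk1Cdc25 = 1.31, kPPXY15 = 0.005, kCdk2Wee1 = 0.11,
  kCdk2Cdc25 = 0.11, kB55Wee1 = 0.55, kB55Cdc25 = 0.55,
  CycBTot = 8.18, Cdk2Tot = 1, PP1Tot = 1, ENSATot = 1,
  B55Tot = 0.25, GwlTot = 1, SubTot = 1, Kd = 0.025
)

#' Model parameter set
#'
#' Builds the named parameter vector of the two-switch mitotic control model:
#' 26 mass-action rate constants (`min^-1`, second-order constants in
#' `AU^-1 min^-1`), 7 total protein pools (arbitrary concentration units, AU),
#' and the dissociation constant `Kd` of the ATP-analog Cdk1 inhibitor (uM).
#' Total Wee1 and Cdc25 are normalised to 1 and are not free parameters.
#'
#' Two reference parameterisations ship with the package: `"xpp"`, the
#' higher-precision values used to draw the model's bifurcation diagrams
#' (the canonical set), and `"table"`, the same values rounded as in the
#' descriptive parameter table.
#'
#' @param ... named overrides of individual parameters (e.g. `Kd = 0.05`).
#' @param variant `"xpp"` (default, canonical) or `"table"` (rounded).
#' @return A named numeric vector of class `mito_params` with 34 entries.
#' @examples
#' p <- mito_params()
#' p[["kass"]]
#' mito_params(CycBTot = 4)[["CycBTot"]]
#' @export
mito_params <- function(..., variant = c("xpp", "table")) {
  variant <- match.arg(variant)
  p <- if (variant == "xpp") .params_xpp else .params_table
  dots <- c(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots)))) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), .par_order)
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  p <- p[.par_order]
  validate_params(p)
  structure(p, class = c("mito_params", "numeric"))
}

validate_params <- function(p) {
  if (!is.numeric(p) || length(p) != length(.par_order) ||
      !identical(names(p), .par_order)) {
    stop("parameter set must be a named numeric vector in canonical order",
         call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("all rate constants and total pools must be finite and >= 0",
         call. = FALSE)
  }
  if (p[["Kd"]] <= 0) stop("Kd must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.mito_params <- function(x, ...) {
  cat("<mito_params> two-switch mitotic control model parameters\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Experimental condition labels
#'
#' The four conditions of the endpoint hysteresis assay. Each maps to a
#' deterministic transformation of the parameter set (see
#' [apply_condition()]).
#'
#' @return Character vector of the four condition labels.
#' @export
mito_conditions <- function() {
  c("control", "wee1i", "gwl_depleted", "wee1i_gwl_depleted")
}

#' Apply an experimental condition to a parameter set
#'
#' `control` leaves the parameters unchanged; `wee1i` (Wee1 inhibition) sets
#' both Wee1 catalytic constants `kWee1S` and `kWee1F` to 0; `gwl_depleted`
#' (Greatwall siRNA) sets the total Greatwall pool `GwlTot` to 0;
#' `wee1i_gwl_depleted` applies both. The input is never modified.
#'
#' @param params a [mito_params()] vector.
#' @param condition one of [mito_conditions()].
#' @return A new `mito_params` vector.
#' @examples
#' apply_condition(mito_params(), "wee1i")[["kWee1F"]]
#' @export
apply_condition <- function(params, condition) {
  validate_params(params)
  condition <- match.arg(condition, mito_conditions())
  if (condition %in% c("wee1i", "wee1i_gwl_depleted")) {
    params[c("kWee1S", "kWee1F")] <- 0
  }
  if (condition %in% c("gwl_depleted", "wee1i_gwl_depleted")) {
    params[["GwlTot"]] <- 0
  }
  structure(params, class = c("mito_params", "numeric"))
}

#' Read / write flat parameter files
#'
#' Parameter files are flat `key: value` text (YAML scalar mapping) whose keys
#' are exactly the `mito_params` field names. Unknown keys are rejected.
#' Two reference files ship in `inst/extdata/`: `params_xpp.yaml` and
#' `params_table.yaml`.
#'
#' @param path file path.
#' @return `read_params()` returns a `mito_params` vector; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (length(raw) && (is.null(names(raw)) || any(!nzchar(names(raw))))) {
    stop("parameter file must be a flat key: value mapping", call. = FALSE)
  }
  do.call(mito_params, raw)
}

#' @param params a [mito_params()] vector.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  validate_params(params)
  yaml::write_yaml(as.list(stats::setNames(as.numeric(params), names(params))),
                   path, precision = 15)
  invisible(path)
}

# parameter vector for the compiled RHS: canonical order + inhibitor dose
par_with_dose <- function(params, inhibitor) {
  c(as.numeric(params), inhibitor)
}
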