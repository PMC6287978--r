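# Model state, rate functions, right-hand side (pure-R reference), and
# conservation relations.

# Fixed state order; also the serialisation order of the 10-tuple.
.state_order <- c(
  "Subp", "CycBCdk1", "PP1", "pENSATot", "Gwlp",
  "PP2AB55", "Wee1", "Wee1pp", "Cdc25", "Cdc25pp"
)

#' Interphase (G2-arrest) initial state
#'
#' The printed interphase arrest state used to start every in-silico protocol:
#' no substrate phosphorylation, no active Cdk1:CycB, fully active PP1, no
#' phospho-ENSA or active Greatwall, all PP2A:B55 free (`B55Tot`), Wee1 in its
#' unphosphorylated fast form, Cdc25 unphosphorylated.
#'
#' @param params a [mito_params()] vector (supplies `PP1Tot` and `B55Tot`).
#' @return A named numeric vector of class `mito_state` (10 variables, AU).
#' @examples
#' interphase_state(mito_params())
#' @export
interphase_state <- function(params = mito_params()) {
  validate_params(params)
  mito_state(c(
    Subp = 0, CycBCdk1 = 0, PP1 = params[["PP1Tot"]], pENSATot = 0,
    Gwlp = 0, PP2AB55 = params[["B55Tot"]], Wee1 = 1, Wee1pp = 0,
    Cdc25 = 1, Cdc25pp = 0
  ))
}

#' Construct / validate a model state
#'
#' A model state holds the 10 dynamic concentrations (AU) in fixed order:
#' `Subp`, `CycBCdk1`, `PP1`, `pENSATot`, `Gwlp`, `PP2AB55`, `Wee1`,
#' `Wee1pp`, `Cdc25`, `Cdc25pp`. The complexed pool `pENSA:B55` and the
#' singly phosphorylated `Wee1p`/`Cdc25p` forms are derived, never stored
#' (see [derived_pools()]).
#'
#' @param x named numeric vector with exactly the 10 state variables.
#' @return A named numeric vector of class `mito_state`.
#' @export
mito_state <- function(x) {
  if (!is.numeric(x) || length(x) != 10 ||
      !setequal(names(x), .state_order)) {
    stop("state must be a named numeric vector of the 10 model variables",
         call. = FALSE)
  }
  x <- x[.state_order]
  if (any(!is.finite(x))) stop("state must be finite", call. = FALSE)
  structure(x, class = c("mito_state", "numeric"))
}

validate_state <- function(state, params, tol = 1e-7) {
  state <- mito_state(state)
  validate_params(params)
  upper <- c(params[["SubTot"]], params[["CycBTot"]], params[["PP1Tot"]],
             params[["ENSATot"]], params[["GwlTot"]], params[["B55Tot"]],
             1, 1, 1, 1)
  if (any(state < -tol) || any(state > upper + tol)) {
    stop("state outside its invariant pool bounds", call. = FALSE)
  }
  invisible(state)
}

# Clamp tiny negative solver drift to 0 (and tiny pool overshoot down);
# violations beyond `tol` are an integration failure and raise.
clamp_state <- function(x, params, tol = 1e-9) {
  upper <- c(params[["SubTot"]], params[["CycBTot"]], params[["PP1Tot"]],
             params[["ENSATot"]], params[["GwlTot"]], params[["B55Tot"]],
             1, 1, 1, 1)
  if (any(x < -tol * pmax(upper, 1)) || any(x > upper * (1 + tol) + tol)) {
    stop("integrator output violates pool bounds beyond tolerance",
         call. = FALSE)
  }
  pmin(pmax(x, 0), upper)
}

#' Effective enzyme activities (rate functions)
#'
#' Computes the four lumped activities of the model at a given state and
#' inhibitor dose. Cdk1 inhibition by the ATP analog is rapid-equilibrium, so
#' `VCdk1 = CycBCdk1 / (1 + inhibitor / Kd)`. Wee1 and Cdc25 activities are
#' the weighted sum of their less- and more-active forms; the stored `Wee1`
#' variable is the unphosphorylated, catalytically *fast* form, so
#' `VWee1 = kWee1S * (1 - Wee1) + kWee1F * Wee1`, while for Cdc25 the doubly
#' phosphorylated form is fast: `VCdc25 = kCdc25S * (1 - Cdc25pp) +
#' kCdc25F * Cdc25pp`. Greatwall activity is `VGwl = kGwlENSA * Gwlp`.
#'
#' @param state a [mito_state()] vector.
#' @param params a [mito_params()] vector.
#' @param inhibitor 1NM-PP1 concentration, uM (scalar, >= 0).
#' @return Named numeric vector `c(VCdk1, VWee1, VCdc25, VGwl)`.
#' @examples
#' rate_functions(interphase_state(), mito_params(), inhibitor = 0.025)
#' @export
rate_functions <- function(state, params, inhibitor = 0) {
  validate_params(params)
  state <- validate_state(state, params)
  if (!is.numeric(inhibitor) || length(inhibitor) != 1 ||
      !is.finite(inhibitor) || inhibitor < 0) {
    stop("inhibitor dose must be a single finite value >= 0", call. = FALSE)
  }
  c(
    VCdk1 = state[["CycBCdk1"]] / (1 + inhibitor / params[["Kd"]]),
    VWee1 = params[["kWee1S"]] * (1 - state[["Wee1"]]) +
      params[["kWee1F"]] * state[["Wee1"]],
    VCdc25 = params[["kCdc25S"]] * (1 - state[["Cdc25pp"]]) +
      params[["kCdc25F"]] * state[["Cdc25pp"]],
    VGwl = params[["kGwlENSA"]] * state[["Gwlp"]]
  )
}

#' Conserved derived pools
#'
#' The three algebraic conservation relations: the pENSA-bound phosphatase
#' complex `pENSA:B55 = B55Tot - PP2AB55`, and the singly phosphorylated
#' intermediates `Wee1p = 1 - Wee1 - Wee1pp` and
#' `Cdc25p = 1 - Cdc25 - Cdc25pp`.
#'
#' @inheritParams rate_functions
#' @param tol negativity tolerance (AU); larger violations signal an
#'   integration failure upstream and raise an error.
#' @return Named numeric vector `c(complex, Wee1p, Cdc25p)`.
#' @export
derived_pools <- function(state, params, tol = 1e-7) {
  validate_params(params)
  state <- mito_state(state)
  out <- c(
    complex = params[["B55Tot"]] - state[["PP2AB55"]],
    Wee1p = 1 - state[["Wee1"]] - state[["Wee1pp"]],
    Cdc25p = 1 - state[["Cdc25"]] - state[["Cdc25pp"]]
  )
  if (any(out < -tol)) {
    stop("conservation relation violated beyond tolerance", call. = FALSE)
  }
  if (out[["complex"]] > state[["pENSATot"]] + tol) {
    stop("pENSA:B55 complex exceeds total phospho-ENSA", call. = FALSE)
  }
  out
}

#' Model right-hand side (reference implementation)
#'
#' Time derivative of the 10 state variables under mass-action kinetics.
#' This pure-R implementation is written directly from the model equations
#' and mirrors the compiled RHS used by the integrator; their agreement is
#' asserted in the test suite.
#'
#' @inheritParams rate_functions
#' @param check validate inputs (set `FALSE` in inner loops).
#' @return Named numeric vector of derivatives, AU/min, in state order.
#' @examples
#' mito_rhs(interphase_state(), mito_params(), inhibitor = 2)
#' @export
mito_rhs <- function(state, params, inhibitor = 0, check = TRUE) {
  if (check) {
    validate_params(params)
    state <- validate_state(state, params)
    if (inhibitor < 0) stop("inhibitor dose must be >= 0", call. = FALSE)
  }
  p <- as.list(params)
  s <- as.list(state)
  v <- rate_functions(state, params, inhibitor)
  dp <- derived_pools(state, params, tol = Inf)

  kin_w1 <- p$kCdk1Wee1 * v[["VCdk1"]] + p$kCdk2Wee1 * p$Cdk2Tot
  kin_25 <- p$kCdk1Cdc25 * v[["VCdk1"]] + p$kCdk2Cdc25 * p$Cdk2Tot
  pho_w1 <- p$kPPXY15 + p$kB55Wee1 * s$PP2AB55
  pho_25 <- p$kPPXY15 + p$kB55Cdc25 * s$PP2AB55

  d <- c(
    Subp = p$kCdk1Sub * v[["VCdk1"]] * (p$SubTot - s$Subp) -
      p$kB55Sub * s$PP2AB55 * s$Subp,
    CycBCdk1 = v[["VCdc25"]] * (p$CycBTot - s$CycBCdk1) -
      v[["VWee1"]] * s$CycBCdk1,
    PP1 = (p$kaPP1 + p$kaPP1a * s$PP1) * (p$PP1Tot - s$PP1) -
      (p$kiPP1 + p$kCdk1PP1 * v[["VCdk1"]]) * s$PP1,
    pENSATot = v[["VGwl"]] * (p$ENSATot - s$pENSATot) -
      p$kcatB55 * dp[["complex"]],
    Gwlp = (p$kCdk1Gwl * v[["VCdk1"]] + p$kCdk2Gwl * p$Cdk2Tot) *
      (p$GwlTot - s$Gwlp) -
      (p$kB55Gwl * s$PP2AB55 + p$kPPXGwl + p$kPP1Gwl * s$PP1) * s$Gwlp,
    PP2AB55 = (p$kdis + p$kcatB55) * dp[["complex"]] -
      p$kass * s$PP2AB55 * (s$pENSATot - dp[["complex"]]),
    Wee1 = pho_w1 * dp[["Wee1p"]] - kin_w1 * s$Wee1,
    Wee1pp = kin_w1 * dp[["Wee1p"]] - pho_w1 * s$Wee1pp,
    Cdc25 = pho_25 * dp[["Cdc25p"]] - kin_25 * s$Cdc25,
    Cdc25pp = kin_25 * dp[["Cdc25p"]] - pho_25 * s$Cdc25pp
  )
  d
}

# Fast compiled RHS evaluation (unvalidated): used by the fixed-point solver,
# steady-state residuals and numerical Jacobians.
rhs_c <- function(state, params, inhibitor) {
  .Call(C_mito_rhs, as.numeric(state), par_with_dose(params, inhibitor))
}

# Central finite-difference Jacobian of the RHS at `state` (10 x 10).
rhs_jacobian <- function(state, params, inhibitor, rel_step = 1e-7) {
  x <- as.numeric(state)
  p <- par_with_dose(params, inhibitor)
  J <- matrix(0, 10, 10)
  for (j in seq_len(10)) {
    h <- rel_step * max(abs(x[j]), 1e-3)
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (.Call(C_mito_rhs, xp, p) - .Call(C_mito_rhs, xm, p)) / (2 * h)
  }
  J
}
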