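# Time integration under piecewise-constant inhibitor schedules, steady-state
# finding, mitotic classification, and the three in-silico protocols.

#' Piecewise-constant inhibitor schedule
#'
#' A schedule is a tibble of segments `(start_min, dose_uM)`: the inhibitor
#' concentration is `dose_uM` from `start_min` until the next breakpoint.
#' Start times must be strictly increasing and begin at 0; doses >= 0.
#'
#' @param start_min numeric vector of segment start times (min).
#' @param dose_uM numeric vector of 1NM-PP1 doses (uM), same length.
#' @return A tibble of class `mito_schedule`.
#' @examples
#' inhibitor_schedule(c(0, 90), c(0, 2))  # inhibitor-free, then 2 uM at 90 min
#' @export
inhibitor_schedule <- function(start_min = 0, dose_uM = 0) {
  if (length(start_min) != length(dose_uM) || !length(start_min)) {
    stop("start_min and dose_uM must be equal-length, non-empty", call. = FALSE)
  }
  if (start_min[1] != 0 || is.unsorted(start_min, strictly = TRUE)) {
    stop("schedule times must start at 0 and be strictly increasing",
         call. = FALSE)
  }
  if (any(dose_uM < 0) || any(!is.finite(dose_uM))) {
    stop("doses must be finite and >= 0", call. = FALSE)
  }
  structure(tibble::tibble(start_min = as.numeric(start_min),
                           dose_uM = as.numeric(dose_uM)),
            class = c("mito_schedule", class(tibble::tibble())))
}

schedule_dose_at <- function(schedule, t) {
  idx <- findInterval(t, schedule$start_min)
  schedule$dose_uM[pmax(idx, 1L)]
}

#' Mitotic classification configuration
#'
#' @param mitotic_threshold fraction of total substrate that must be
#'   phosphorylated to call a cell mitotic (default 0.30, the
#'   immunofluorescence-calibrated interphase/M-phase boundary).
#' @param endpoint_time_min endpoint-assay incubation time after the final
#'   treatment (default 240 min, the 4-hr fixation point).
#' @return A list of class `mito_classify_config`.
#' @export
classification_config <- function(mitotic_threshold = 0.30,
                                  endpoint_time_min = 240) {
  if (mitotic_threshold <= 0 || mitotic_threshold >= 1) {
    stop("mitotic_threshold must be in (0, 1)", call. = FALSE)
  }
  if (endpoint_time_min <= 0) stop("endpoint_time_min must be > 0", call. = FALSE)
  structure(list(mitotic_threshold = mitotic_threshold,
                 endpoint_time_min = endpoint_time_min),
            class = "mito_classify_config")
}

#' Integrate the model under an inhibitor schedule
#'
#' Stiff adaptive integration (lsoda, compiled right-hand side), restarted
#' exactly at every schedule breakpoint so the dose discontinuity is never
#' interpolated across. Output states are clamped for sub-tolerance negative
#' solver drift; larger invariant violations raise.
#'
#' @param state0 initial [mito_state()].
#' @param params a [mito_params()] vector.
#' @param schedule an [inhibitor_schedule()] (or a single constant dose in uM).
#' @param t_end final time, min (>= 0).
#' @param times optional output times (min); default 241 evenly spaced points.
#' @param rtol,atol solver tolerances.
#' @return A tibble of class `mito_trajectory` with columns `time_min`, the
#'   10 state variables, `dose_uM`, and `VCdk1`.
#' @examples
#' tr <- simulate_model(interphase_state(), mito_params(), schedule = 0,
#'                      t_end = 60)
#' tail(tr, 1)
#' @export
simulate_model <- function(state0, params, schedule = 0, t_end,
                           times = NULL, rtol = 1e-8, atol = 1e-10) {
  validate_params(params)
  state0 <- validate_state(state0, params)
  if (is.numeric(schedule) && !inherits(schedule, "mito_schedule")) {
    schedule <- inhibitor_schedule(0, schedule)
  }
  if (t_end < 0) stop("t_end must be >= 0", call. = FALSE)
  if (is.null(times)) times <- seq(0, t_end, length.out = 241)
  times <- sort(unique(c(0, times[times <= t_end], t_end)))

  if (t_end == 0) {
    out <- matrix(as.numeric(state0), nrow = 1,
                  dimnames = list(NULL, .state_order))
    return(trajectory_tibble(0, out, schedule, params))
  }

  breaks <- schedule$start_min[schedule$start_min < t_end]
  seg_start <- breaks
  seg_end <- c(breaks[-1], t_end)
  y <- as.numeric(state0)
  rows_t <- numeric(0)
  rows_y <- NULL
  for (i in seq_along(seg_start)) {
    dose <- schedule$dose_uM[i]
    tt <- times[times >= seg_start[i] & times <= seg_end[i]]
    tt <- sort(unique(c(seg_start[i], tt, seg_end[i])))
    sol <- deSolve::ode(
      y = stats::setNames(y, .state_order), times = tt,
      func = "mito_derivs", parms = par_with_dose(params, dose),
      dllname = "mitoswitch", initfunc = "mito_initmod",
      method = "lsoda", rtol = rtol, atol = atol, maxsteps = 50000
    )
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("integration failed in [%g, %g] min (last good time %g)",
                   seg_start[i], seg_end[i], max(sol[, 1])), call. = FALSE)
    }
    m <- unname(sol[, -1, drop = FALSE])
    m <- t(apply(m, 1, clamp_state, params = params))
    keep <- sol[, 1] %in% times & (i == 1 | sol[, 1] > seg_start[i])
    rows_t <- c(rows_t, sol[keep, 1])
    rows_y <- rbind(rows_y, m[keep, , drop = FALSE])
    y <- m[nrow(m), ]
  }
  colnames(rows_y) <- .state_order
  trajectory_tibble(rows_t, rows_y, schedule, params)
}

trajectory_tibble <- function(times, states, schedule, params) {
  dose <- schedule_dose_at(schedule, times)
  out <- tibble::as_tibble(as.data.frame(states))
  out <- tibble::add_column(out, time_min = times, .before = 1)
  out$dose_uM <- dose
  out$VCdk1 <- out$CycBCdk1 / (1 + dose / params[["Kd"]])
  class(out) <- c("mito_trajectory", class(tibble::tibble()))
  out
}

# Last state of a trajectory as a mito_state.
final_state <- function(traj) {
  mito_state(unlist(traj[nrow(traj), .state_order]))
}

#' Relax to a steady state at constant dose
#'
#' Integrates in chunks until the max-norm of the right-hand side falls below
#' `tol` (AU/min) or `t_max` is exceeded. Non-convergence is reported through
#' the `converged` flag, never as an error.
#'
#' @inheritParams simulate_model
#' @param dose constant inhibitor dose, uM.
#' @param tol residual max-norm convergence criterion (AU/min).
#' @param t_max giving-up time, min.
#' @return A list with `state` (final [mito_state()]), `converged` (logical),
#'   and `t` (integration time used, min).
#' @export
steady_state <- function(state0, params, dose = 0, tol = 1e-10,
                         t_max = 10000) {
  validate_params(params)
  y <- as.numeric(validate_state(state0, params))
  t <- 0
  chunk <- 250
  repeat {
    res <- max(abs(.Call(C_mito_rhs, y, par_with_dose(params, dose))))
    if (res < tol) {
      return(list(state = mito_state(stats::setNames(y, .state_order)),
                  converged = TRUE, t = t))
    }
    if (t >= t_max) {
      return(list(state = mito_state(stats::setNames(y, .state_order)),
                  converged = FALSE, t = t))
    }
    sol <- suppressWarnings(deSolve::ode(
      y = stats::setNames(y, .state_order), times = c(0, chunk),
      func = "mito_derivs", parms = par_with_dose(params, dose),
      dllname = "mitoswitch", initfunc = "mito_initmod",
      method = "lsoda", rtol = 1e-9, atol = 1e-11, maxsteps = 200000
    ))
    last <- max(which(stats::complete.cases(sol)))
    if (sol[last, 1] <= 0) {  # solver made no progress: give up cleanly
      return(list(state = mito_state(stats::setNames(y, .state_order)),
                  converged = FALSE, t = t))
    }
    y <- clamp_state(unname(sol[last, -1]), params)
    t <- t + sol[last, 1]
    chunk <- min(chunk * 2, 1000)
  }
}

#' Classify a state as interphase or mitotic
#'
#' A cell is mitotic iff the phosphorylated fraction of the generic
#' Cdk1/PP2A:B55 substrate reaches the threshold: `Subp / SubTot >=
#' mitotic_threshold` (boundary inclusive).
#'
#' @inheritParams rate_functions
#' @param cfg a [classification_config()].
#' @return `"mitotic"` or `"interphase"`.
#' @examples
#' classify_state(interphase_state(), mito_params())
#' @export
classify_state <- function(state, params, cfg = classification_config()) {
  state <- mito_state(state)
  frac <- state[["Subp"]] / params[["SubTot"]]
  if (frac >= cfg$mitotic_threshold) "mitotic" else "interphase"
}

#' In-silico endpoint protocols
#'
#' The three single-cell experimental schedules of the endpoint hysteresis
#' assay, each starting from the printed interphase arrest state with the
#' cell's own total cyclin B (`cycb_tot`):
#'
#' * **entry** — release into a constant inhibitor dose at `t = 0`; classify
#'   at `endpoint_time_min` (default 240 min).
#' * **exit** — release inhibitor-free for 90 min (the cell enters mitosis),
#'   then add the dose; classify `endpoint_time_min` later.
#' * **prophase** — release inhibitor-free, re-add the dose at `readd_time`
#'   (default 25 min), relax to steady state, and label by the nearest stable
#'   attractor at that dose: lowest-`Subp` attractor `"back_to_interphase"`,
#'   highest `"mitotic"`, any middle branch `"intermediate"`.
#'
#' @param params a [mito_params()] vector (before condition perturbation).
#' @param condition one of [mito_conditions()].
#' @param dose constant 1NM-PP1 dose, uM.
#' @param cycb_tot total cyclin B of this cell, AU.
#' @param cfg a [classification_config()].
#' @return `run_entry_protocol()` / `run_exit_protocol()` return
#'   `"mitotic"` or `"interphase"`; `run_prophase_protocol()` returns one of
#'   `"back_to_interphase"`, `"intermediate"`, `"mitotic"`.
#' @examples
#' \donttest{
#' run_entry_protocol(mito_params(), "control", dose = 2)
#' }
#' @export
run_entry_protocol <- function(params, condition = "control", dose,
                               cycb_tot = params[["CycBTot"]],
                               cfg = classification_config()) {
  p <- protocol_params(params, condition, cycb_tot)
  traj <- simulate_model(interphase_state(p), p, schedule = dose,
                         t_end = cfg$endpoint_time_min,
                         times = cfg$endpoint_time_min)
  classify_state(final_state(traj), p, cfg)
}

#' @rdname run_entry_protocol
#' @export
run_exit_protocol <- function(params, condition = "control", dose,
                              cycb_tot = params[["CycBTot"]],
                              cfg = classification_config()) {
  p <- protocol_params(params, condition, cycb_tot)
  sched <- inhibitor_schedule(c(0, 90), c(0, dose))
  t_end <- 90 + cfg$endpoint_time_min
  traj <- simulate_model(interphase_state(p), p, schedule = sched,
                         t_end = t_end, times = t_end)
  classify_state(final_state(traj), p, cfg)
}

#' @param readd_time time of inhibitor re-addition after release, min.
#' @param fixed_points optional precomputed result of [find_fixed_points()]
#'   at (`params` after condition/`cycb_tot`, `dose`); computed if missing.
#' @rdname run_entry_protocol
#' @export
run_prophase_protocol <- function(params, condition = "control", dose,
                                  readd_time = 25,
                                  cycb_tot = params[["CycBTot"]],
                                  cfg = classification_config(),
                                  fixed_points = NULL) {
  if (readd_time <= 0) stop("readd_time must be > 0", call. = FALSE)
  p <- protocol_params(params, condition, cycb_tot)
  sched <- inhibitor_schedule(c(0, readd_time), c(0, dose))
  traj <- simulate_model(interphase_state(p), p, schedule = sched,
                         t_end = readd_time, times = readd_time)
  ss <- steady_state(final_state(traj), p, dose = dose)
  if (is.null(fixed_points)) {
    fixed_points <- find_fixed_points(p, dose = dose)
  }
  stable <- fixed_points[fixed_points$stable, , drop = FALSE]
  if (!nrow(stable)) {
    # no stable root found (should not happen); fall back to threshold label
    return(if (classify_state(ss$state, p, cfg) == "mitotic") "mitotic"
           else "back_to_interphase")
  }
  scale <- pool_scales(p)
  d <- apply(as.matrix(stable[, .state_order]), 1, function(r) {
    max(abs((r - as.numeric(ss$state)) / scale))
  })
  nearest <- which.min(d)
  if (nrow(stable) == 1) {
    # monostable at this dose: label by the threshold, intermediate unreachable
    return(if (classify_state(ss$state, p, cfg) == "mitotic") "mitotic"
           else "back_to_interphase")
  }
  lab <- rep("intermediate", nrow(stable))
  lab[which.min(stable$Subp)] <- "back_to_interphase"
  lab[which.max(stable$Subp)] <- "mitotic"
  lab[nearest]
}

protocol_params <- function(params, condition, cycb_tot) {
  validate_params(params)
  if (cycb_tot < 0) stop("cycb_tot must be >= 0", call. = FALSE)
  p <- apply_condition(params, condition)
  p[["CycBTot"]] <- cycb_tot
  structure(p, class = c("mito_params", "numeric"))
}

# per-variable normalisation scale (each variable's total pool)
pool_scales <- function(params) {
  c(params[["SubTot"]], max(params[["CycBTot"]], 1e-6), params[["PP1Tot"]],
    params[["ENSATot"]], max(params[["GwlTot"]], 1e-6), params[["B55Tot"]],
    1, 1, 1, 1)
}

#' Fixed-step RK4 reference integration
#'
#' Independent fixed-step fourth-order Runge-Kutta integrator (compiled),
#' used as the cross-check oracle for the adaptive stiff solver.
#'
#' @inheritParams steady_state
#' @param t_end final time, min.
#' @param dt fixed step, min (default 0.001).
#' @param save_every save state every this many steps.
#' @return A tibble with `time_min` and the 10 state variables.
#' @export
rk4_reference <- function(state0, params, dose = 0, t_end, dt = 0.001,
                          save_every = 1000) {
  validate_params(params)
  y0 <- as.numeric(validate_state(state0, params))
  n_steps <- round(t_end / dt)
  m <- .Call(C_mito_rk4, y0, par_with_dose(params, dose),
             dt, n_steps, save_every)
  colnames(m) <- .state_order
  out <- tibble::as_tibble(as.data.frame(m))
  tibble::add_column(out,
    time_min = seq(0, by = dt * save_every, length.out = nrow(m)),
    .before = 1)
}
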