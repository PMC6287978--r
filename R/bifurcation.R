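# Steady-state structure: multi-start fixed-point finding, stability,
# quasi-static signal-response sweeps, fold (saddle-node) points, and the
# multistability census over inhibitor dose.

#' Find all fixed points at a given dose
#'
#' Multi-start damped Newton iteration on the right-hand side, seeded from a
#' Latin-hypercube of the invariant state box plus the two protocol endpoint
#' states (interphase relaxed at the dose; mitotic state relaxed from an
#' inhibitor-free mitotic start). Roots are merged when closer than `1e-6` in
#' pool-normalised max-norm and discarded when outside the invariant box by
#' more than `1e-6`. Stability is read off the eigenvalues of the
#' finite-difference Jacobian: stable iff every real part `< -1e-9`.
#'
#' @param params a [mito_params()] vector (condition already applied).
#' @param dose constant inhibitor dose, uM.
#' @param n_starts number of Latin-hypercube starts (>= 8).
#' @param seed seed for the Latin-hypercube draw (fixed default keeps the
#'   search deterministic).
#' @return A tibble with the 10 state variables, `stable` (logical),
#'   `max_re_eig`, and `residual` (max-norm of the RHS at the root).
#' @examples
#' \donttest{
#' fp <- find_fixed_points(mito_params(), dose = 2)
#' sum(fp$stable)
#' }
#' @export
find_fixed_points <- function(params, dose, n_starts = 64, seed = 1L) {
  validate_params(params)
  if (n_starts < 8) stop("n_starts must be >= 8", call. = FALSE)
  scale <- pool_scales(params)
  upper <- c(params[["SubTot"]], params[["CycBTot"]], params[["PP1Tot"]],
             params[["ENSATot"]], params[["GwlTot"]], params[["B55Tot"]],
             1, 1, 1, 1)

  starts <- list()
  # protocol endpoints, relaxed (cheap, robust seeds for the outer branches)
  ss_int <- steady_state(interphase_state(params), params, dose = dose,
                         tol = 1e-9, t_max = 4000)
  starts[[1]] <- as.numeric(ss_int$state)
  mit0 <- steady_state(interphase_state(params), params, dose = 0,
                       tol = 1e-9, t_max = 4000)
  ss_mit <- steady_state(mit0$state, params, dose = dose,
                         tol = 1e-9, t_max = 4000)
  starts[[2]] <- as.numeric(ss_mit$state)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  H <- lhs::randomLHS(n_starts, 10)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  for (i in seq_len(n_starts)) starts[[i + 2]] <- H[i, ] * upper

  roots <- list()
  for (x0 in starts) {
    r <- newton_root(x0, params, dose, upper)
    if (is.null(r)) next
    dup <- FALSE
    for (rt in roots) {
      if (max(abs((rt - r) / scale)) < 1e-6) { dup <- TRUE; break }
    }
    if (!dup) roots[[length(roots) + 1]] <- r
  }
  if (!length(roots)) stop("no fixed point found (solver failure)", call. = FALSE)

  rows <- lapply(roots, function(r) {
    J <- rhs_jacobian(r, params, dose)
    ev <- eigen(J, only.values = TRUE)$values
    mre <- max(Re(ev))
    res <- max(abs(rhs_c(r, params, dose)))
    out <- tibble::as_tibble(as.data.frame(t(stats::setNames(r, .state_order))))
    out$stable <- mre < -1e-9
    out$max_re_eig <- mre
    out$residual <- res
    out
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$Subp)
}

# Damped Newton on rhs(x) = 0; returns the root or NULL.
newton_root <- function(x0, params, dose, upper, tol = 1e-11,
                        max_iter = 200) {
  x <- pmin(pmax(as.numeric(x0), 0), upper)
  f <- rhs_c(x, params, dose)
  nf <- max(abs(f))
  for (it in seq_len(max_iter)) {
    if (nf < tol) break
    J <- rhs_jacobian(x, params, dose)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- tryCatch(rhs_c(xn, params, dose), error = function(e) NULL)
      nfn <- if (is.null(fn)) Inf else max(abs(fn))
      if (nfn < nf || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (nfn >= nf && nf >= tol) return(NULL)  # stalled
    x <- xn; f <- fn; nf <- nfn
  }
  if (nf >= tol) return(NULL)
  # discard roots outside the invariant box (beyond 1e-6)
  if (any(x < -1e-6) || any(x > upper + 1e-6)) return(NULL)
  pmin(pmax(x, 0), upper)
}

#' Quasi-static signal-response sweep over dose
#'
#' Traces a steady-state branch by continuation: at each grid dose the steady
#' state is relaxed starting from the previous dose's endpoint. Direction
#' `"up"` starts from the mitotic state at the lowest dose; `"down"` starts
#' from the interphase state at the highest dose. The up/down pair
#' reconstructs the hysteresis loop.
#'
#' @param params a [mito_params()] vector.
#' @param condition one of [mito_conditions()].
#' @param dose_grid sorted vector of doses, uM.
#' @param direction `"up"` or `"down"`.
#' @return A tibble of class `mito_branch` with `dose_uM`, `direction`,
#'   `sub_frac` (Subp/SubTot), the 10 state variables, and `converged`.
#' @export
sweep_signal_response <- function(params, condition = "control", dose_grid,
                                  direction = c("up", "down")) {
  direction <- match.arg(direction)
  p <- apply_condition(params, condition)
  if (!length(dose_grid)) {
    out <- tibble::tibble(dose_uM = numeric(0), direction = character(0),
                          sub_frac = numeric(0), converged = logical(0))
    class(out) <- c("mito_branch", class(tibble::tibble()))
    return(out)
  }
  grid <- sort(dose_grid)
  if (direction == "down") grid <- rev(grid)

  y <- if (direction == "up") {
    steady_state(interphase_state(p), p, dose = 0, tol = 1e-9,
                 t_max = 4000)$state
  } else {
    interphase_state(p)
  }
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    ss <- steady_state(y, p, dose = grid[i], tol = 1e-9, t_max = 6000)
    y <- ss$state
    st <- tibble::as_tibble(as.data.frame(t(as.numeric(y))))
    names(st) <- .state_order
    st$dose_uM <- grid[i]
    st$converged <- ss$converged
    rows[[i]] <- st
  }
  out <- dplyr::bind_rows(rows)
  out$direction <- direction
  out$sub_frac <- out$Subp / p[["SubTot"]]
  out <- dplyr::select(out, "dose_uM", "direction", "sub_frac",
                       dplyr::all_of(.state_order), "converged")
  out <- dplyr::arrange(out, .data$dose_uM)
  class(out) <- c("mito_branch", class(tibble::tibble()))
  out
}

#' Fold (saddle-node) doses of the entry and exit branches
#'
#' `fold_entry` is the dose above which the mitotic-entry path no longer
#' reaches the high branch when started from interphase at that dose
#' (the interphase branch appears); `fold_exit` is the dose above which the
#' mitotic branch, continued up-dose from the inhibitor-free mitotic state,
#' collapses to interphase. Both are located by bisection on branch identity
#' (threshold crossing of the steady-state substrate fraction) and refined to
#' `refine_tol`. A monostable system has no folds: both are returned `NA`
#' ("absent"), never 0.
#'
#' @inheritParams sweep_signal_response
#' @param dose_range numeric length-2 search interval, uM.
#' @param refine_tol bisection tolerance, uM.
#' @param cfg a [classification_config()] (threshold separating branches).
#' @return A tibble with `condition`, `fold_entry_uM`, `fold_exit_uM`.
#' @export
fold_points <- function(params, condition = "control", dose_range = c(0, 2),
                        refine_tol = 1e-4, cfg = classification_config()) {
  stopifnot(refine_tol > 0, length(dose_range) == 2)
  p <- apply_condition(params, condition)
  thr <- cfg$mitotic_threshold
  lo <- dose_range[1]; hi <- dose_range[2]

  # steady branch fraction reached from interphase / from mitosis at a dose
  int_frac <- function(d) {
    ss <- steady_state(interphase_state(p), p, dose = d, tol = 1e-9,
                       t_max = 6000)
    ss$state[["Subp"]] / p[["SubTot"]]
  }
  mit_state0 <- steady_state(interphase_state(p), p, dose = 0, tol = 1e-9,
                             t_max = 4000)$state
  mit_frac <- function(d) {
    ss <- steady_state(mit_state0, p, dose = d, tol = 1e-9, t_max = 6000)
    ss$state[["Subp"]] / p[["SubTot"]]
  }

  fold_entry <- NA_real_
  if (int_frac(lo) >= thr && int_frac(hi) < thr) {
    a <- lo; b <- hi
    while (b - a > refine_tol) {
      m <- (a + b) / 2
      if (int_frac(m) >= thr) a <- m else b <- m
    }
    fold_entry <- (a + b) / 2
  }
  fold_exit <- NA_real_
  if (mit_frac(lo) >= thr && mit_frac(hi) < thr) {
    a <- lo; b <- hi
    while (b - a > refine_tol) {
      m <- (a + b) / 2
      if (mit_frac(m) >= thr) a <- m else b <- m
    }
    fold_exit <- (a + b) / 2
  }
  # a monostable switch: entry and exit paths collapse at the same dose
  if (!is.na(fold_entry) && !is.na(fold_exit) &&
      abs(fold_exit - fold_entry) <= 2 * refine_tol) {
    fold_entry <- NA_real_
    fold_exit <- NA_real_
  }
  tibble::tibble(condition = condition, fold_entry_uM = fold_entry,
                 fold_exit_uM = fold_exit)
}

#' Count coexisting stable steady states over a dose grid
#'
#' Wraps [find_fixed_points()] over a grid and reports the per-dose number of
#' stable fixed points and the maximum over the grid.
#'
#' @inheritParams sweep_signal_response
#' @param n_starts passed to [find_fixed_points()].
#' @return A list with `per_dose` (tibble `dose_uM`, `n_stable`) and
#'   `max_stable`.
#' @export
count_stable_states <- function(params, condition = "control", dose_grid,
                                n_starts = 64) {
  p <- apply_condition(params, condition)
  counts <- vapply(dose_grid, function(d) {
    fp <- find_fixed_points(p, dose = d, n_starts = n_starts)
    sum(fp$stable)
  }, integer(1))
  list(per_dose = tibble::tibble(dose_uM = dose_grid, n_stable = counts),
       max_stable = max(counts))
}
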