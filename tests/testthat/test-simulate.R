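# Integration, schedules, classification, and the in-silico protocols.

test_that("schedules are validated and zero-length integration returns the start", {
  expect_error(inhibitor_schedule(c(1, 2), c(0, 1)), "start at 0")
  expect_error(inhibitor_schedule(c(0, 0), c(0, 1)), "strictly increasing")
  expect_error(inhibitor_schedule(0, -1), ">= 0")
  p <- mito_params()
  tr <- simulate_model(interphase_state(p), p, schedule = 1, t_end = 0)
  expect_equal(nrow(tr), 1)
  expect_equal(unlist(tr[1, names(interphase_state(p))]),
               unclass(interphase_state(p)))
})

test_that("classification threshold is 30% of total substrate, boundary inclusive", {
  p <- mito_params()
  s <- unclass(interphase_state(p))
  expect_equal(classify_state(mito_state(s), p), "interphase")
  s[["Subp"]] <- 0.299
  expect_equal(classify_state(mito_state(s), p), "interphase")
  s[["Subp"]] <- 0.30
  expect_equal(classify_state(mito_state(s), p), "mitotic")
})

test_that("entry and exit protocols reproduce the endpoint assay behaviour", {
  p <- mito_params()
  expect_equal(run_entry_protocol(p, "control", dose = 0), "mitotic")
  expect_equal(run_entry_protocol(p, "control", dose = 2), "interphase")
  expect_equal(run_entry_protocol(p, "control", dose = 0, cycb_tot = 0),
               "interphase")
  expect_equal(run_exit_protocol(p, "control", dose = 2), "interphase")
  expect_equal(run_exit_protocol(p, "control", dose = 0), "mitotic")
})

test_that("an intermediate dose blocks entry but does not force exit (hysteresis)", {
  p <- mito_params()
  expect_equal(run_entry_protocol(p, "control", dose = 0.25), "interphase")
  expect_equal(run_exit_protocol(p, "control", dose = 0.25), "mitotic")
})

test_that("endpoint classification saturates by 3 hr", {
  p <- mito_params()
  for (dose in c(0, 0.05, 0.11, 0.3, 1)) {
    c180 <- run_entry_protocol(p, "control", dose,
                               cfg = classification_config(endpoint_time_min = 180))
    c240 <- run_entry_protocol(p, "control", dose)
    expect_equal(c180, c240)
  }
})

test_that("steady_state relaxes to a verified fixed point and stays on one", {
  p <- mito_params()
  ss <- steady_state(interphase_state(p), p, dose = 2)
  expect_true(ss$converged)
  expect_lt(ss$state[["Subp"]] / p[["SubTot"]], 0.30)
  # restarting at the fixed point returns immediately, unchanged
  again <- steady_state(ss$state, p, dose = 2)
  expect_true(again$converged)
  expect_equal(again$t, 0)
  expect_equal(as.numeric(again$state), as.numeric(ss$state))
  ss0 <- steady_state(interphase_state(p), p, dose = 0)
  expect_true(ss0$converged)
  expect_gt(ss0$state[["Subp"]] / p[["SubTot"]], 0.30)
})

test_that("integration restarts cleanly across schedule breakpoints", {
  p <- mito_params()
  sched <- inhibitor_schedule(c(0, 90), c(0, 2))
  tr <- simulate_model(interphase_state(p), p, sched, t_end = 330,
                       times = c(89, 90, 91, 330))
  expect_equal(tr$dose_uM[tr$time_min == 89], 0)
  expect_equal(tr$dose_uM[tr$time_min == 91], 2)
  # piecing the two legs manually gives the same endpoint
  leg1 <- simulate_model(interphase_state(p), p, 0, t_end = 90, times = 90)
  leg2 <- simulate_model(mitoswitch:::final_state(leg1), p, 2, t_end = 240,
                         times = 240)
  expect_equal(unlist(tr[nrow(tr), names(interphase_state(p))]),
               unlist(leg2[nrow(leg2), names(interphase_state(p))]),
               tolerance = 1e-7)
})

test_that("prophase protocol maps attractors to the three outcome labels", {
  p <- mito_params()
  expect_equal(run_prophase_protocol(p, "control", dose = 0), "mitotic")
  expect_equal(run_prophase_protocol(p, "control", dose = 2),
               "back_to_interphase")
  # a cell in the tristable band, re-inhibited inside the G2-M transition,
  # is captured on the intermediate branch
  expect_equal(run_prophase_protocol(p, "control", dose = 0.5,
                                     readd_time = 8, cycb_tot = 24),
               "intermediate")
})

test_that("adaptive stiff solver agrees with the fixed-step RK4 oracle", {
  p <- mito_params()
  set.seed(1)
  for (i in 1:4) {
    s0 <- random_box_state(p)
    dose <- runif(1, 0, 2)
    tt <- seq(0, 240, by = 1)
    tr <- simulate_model(s0, p, dose, 240, times = tt)
    rk <- rk4_reference(s0, p, dose, 240, dt = 0.001, save_every = 1000)
    expect_lt(max(abs(as.matrix(tr[, 2:11]) - as.matrix(rk[, 2:11]))), 1e-5)
  }
})
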