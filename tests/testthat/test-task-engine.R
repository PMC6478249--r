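test_that("coin drift has the right fixed point, limit and closed form", {
  quiet <- task_params(sigma_walk = 0)
  # no press, no noise, at the default column: invariant point
  expect_equal(step_coin(0.5, FALSE, quiet, x_default = 0.5), 0.5)
  # infinitely fast drift collapses to the default column in one step
  fast <- task_params(lambda_drift = 1e9, sigma_walk = 0)
  expect_equal(step_coin(0.9, FALSE, fast, x_default = 0.5), 0.5,
               tolerance = 1e-12)
  # deterministic part of one unit step: 0.5 + 0.4 * exp(-1)
  unit <- task_params(dt = 1, lambda_drift = 1, sigma_walk = 0)
  expect_equal(step_coin(0.9, FALSE, unit, x_default = 0.5),
               0.5 + 0.4 * exp(-1), tolerance = 1e-12)
  expect_error(step_coin(NaN, FALSE, quiet, 0.5), "finite")
  expect_error(step_coin(1.2, FALSE, quiet, 0.5), "range")
})

test_that("compiled stepper and R reference trace identical trajectories", {
  params <- task_params()
  for (pol in c("absent", "ideal")) {
    spec <- trial_spec("Withdraw", if (pol == "absent") "NoGo" else "Go")
    policy <- if (pol == "absent") policy_absent() else policy_ideal()
    set.seed(321)
    log <- simulate_trial(spec, params, policy, keep_trajectory = TRUE)
    set.seed(321)
    ref <- oracle_replay_trial(spec, params, policy_kind = pol)
    expect_equal(log$trajectory, ref$trajectory, tolerance = 1e-12)
    expect_equal(log$press_times, ref$press_times, tolerance = 1e-12)
    expect_equal(log$final_x, ref$final_x, tolerance = 1e-12)
  }
})

test_that("without presses the default route wins NoGo and loses Go trials", {
  params <- task_params()
  for (frame in c("Approach", "Withdraw")) {
    nogo <- simulate_trials(trial_spec(frame, "NoGo"), 10000, params,
                            policy_absent(), seed = 11)
    expect_gt(mean(nogo$outcome == "win"), 0.99)
    go <- simulate_trials(trial_spec(frame, "Go"), 10000, params,
                          policy_absent(), seed = 12)
    expect_gt(mean(go$outcome == "lose"), 0.99)
    expect_true(all(nogo$outcome %in% c("win", "lose", "incomplete")))
    # classification is a function of the final position alone
    expect_identical(go$outcome,
                     classify_outcome(go$final_x, trial_spec(frame, "Go"),
                                      params))
  }
})

test_that("outcome classification partitions the screen", {
  params <- task_params()
  spec <- trial_spec("Approach", "Go")   # desired machine, punitive dot
  expect_identical(classify_outcome(params$x_machine, spec, params), "win")
  expect_identical(classify_outcome(params$x_dot, spec, params), "lose")
  mid <- (params$x_machine + params$x_dot) / 2
  expect_identical(classify_outcome(mid, spec, params), "incomplete")
  # inclusive window edge (binary-exact geometry so the boundary is exact)
  exact <- task_params(x_machine = 0.5, x_dot = 1, window_width = 0.25,
                       press_mu = 0.0625)
  expect_identical(classify_outcome(0.5 + 0.125, spec, exact), "win")
  expect_identical(classify_outcome(0.5 + 0.126, spec, exact), "incomplete")
  expect_error(classify_outcome(1.5, spec, params), "0, 1")
  # overlapping windows are impossible by construction
  expect_error(task_params(window_width = 0.5), "overlap")
})

test_that("identical seeds reproduce identical trial logs", {
  spec <- trial_spec("Withdraw", "Go")
  a <- simulate_trial(spec, policy = policy_rate(6, latency = 0.3), seed = 99)
  b <- simulate_trial(spec, policy = policy_rate(6, latency = 0.3), seed = 99)
  expect_identical(a$press_times, b$press_times)
  expect_identical(a$final_x, b$final_x)
  expect_identical(a$outcome, b$outcome)
  c <- simulate_trial(spec, policy = policy_rate(6, latency = 0.3), seed = 100)
  expect_false(identical(a$final_x, c$final_x))
  expect_true(is.na(simulate_trial(spec, policy = policy_absent(),
                                   seed = 1)$first_press_latency))
})

test_that("win probability peaks at intermediate press vigor", {
  params <- task_params()
  spec <- trial_spec("Withdraw", "Go")
  winp <- vapply(c(low = 4, near_optimal = 6.8, overshooting = 8.8),
                 function(r) {
    mean(simulate_trials(spec, 1500, params, policy_rate(r),
                         seed = 7000 + round(10 * r))$outcome == "win")
  }, numeric(1))
  expect_gt(winp[["near_optimal"]], winp[["low"]])
  expect_gt(winp[["near_optimal"]], winp[["overshooting"]])
})

test_that("noise-free dynamics give a deterministic press count", {
  det <- task_params(sigma_walk = 0, press_sigma = 0)
  s <- required_presses_stat(det, n_trials = 200, seed = 1)
  expect_identical(s$sd, 0)
  ref <- oracle_replay_trial(trial_spec("Withdraw", "Go"), det,
                             policy_kind = "ideal")
  expect_equal(s$mean, length(ref$press_times))

  # with no drift, presses needed to first reach a fixed window scale
  # inversely with the press size
  first_entry <- function(mu) {
    p <- task_params(lambda_drift = 0, sigma_walk = 0, press_mu = mu,
                     press_sigma = 0, window_width = 0.05)
    simulate_trials(trial_spec("Withdraw", "Go"), 1, p, policy_ideal(),
                    seed = 1)$n_presses
  }
  arith <- function(mu) ceiling((0.4 - 0.025) / mu)
  expect_equal(first_entry(0.012), arith(0.012))
  expect_equal(first_entry(0.024), arith(0.024))
  expect_lte(abs(first_entry(0.012) - 2 * first_entry(0.024)), 2)
})

test_that("calibration reaches the press target and sets the window width", {
  cal <- calibrate_params(n_trials = 800, seed = 55)
  info <- attr(cal, "calibration")
  expect_lt(abs(info$mean - 32.12), 0.5)
  expect_equal(cal$window_width, 4 * cal$press_mu)
  # definitional product for a user-chosen press size
  expect_equal(task_params(press_mu = 0.01)$window_width, 0.04)
  # an unreachable target is reported as a calibration failure
  expect_error(calibrate_params(target_mean_presses = 1e4, n_trials = 300,
                                seed = 1),
               "calibration failure")
})

test_that("policies respect the press-rate cap", {
  expect_error(simulate_trial(trial_spec("Approach", "Go"),
                              policy = policy_rate(50)),
               "max_press_rate")
  expect_error(pit_policy("rate"), "press rate")
})
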