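#' Advance the coin by one time step
#'
#' Reference (pure R) implementation of the per-step coin dynamics:
#' \deqn{x' = x_{def} + (x - x_{def}) e^{-\lambda \Delta t} + \epsilon +
#'   \mathrm{pressed} \cdot \mathrm{dir} \cdot N(\mu_k, \sigma_k)}
#' with \eqn{\epsilon \sim N(0, \sigma_{walk}\sqrt{\Delta t})} and the result
#' clamped to \[0, 1\]. One walk draw is consumed on every call (also when
#' `sigma_walk` is zero) so that a step-by-step R trajectory consumes the
#' RNG stream exactly like the compiled trial simulator.
#'
#' @param x Current coin position in \[0, 1\].
#' @param pressed Logical flag: was the key pressed during this step?
#' @param params A [task_params()] object.
#' @param x_default Horizontal coordinate of the trial's default target.
#' @param press_direction +1 or -1: the direction of press displacements
#'   (away from the default target).
#' @return The new position, a number in \[0, 1\].
#' @examples
#' p <- task_params(sigma_walk = 0)
#' step_coin(0.5, FALSE, p, x_default = 0.5)  # fixed point of the drift
#' @export
step_coin <- function(x, pressed, params, x_default, press_direction = 1) {
  stopifnot(inherits(params, "pit_task_params"))
  .assert_scalar_num(x, "x", lower = 0, upper = 1)
  .assert_scalar_num(x_default, "x_default", lower = 0, upper = 1)
  if (!press_direction %in% c(-1, 1))
    stop("`press_direction` must be +1 or -1", call. = FALSE)
  eps <- rnorm(1L, 0, params$sigma_walk * sqrt(params$dt))
  xn <- x_default + (x - x_default) * exp(-params$lambda_drift * params$dt) + eps
  if (isTRUE(pressed)) {
    xn <- xn + press_direction * rnorm(1L, params$press_mu, params$press_sigma)
  }
  min(1, max(0, xn))
}

# Resolve per-trial geometry (start, default/desired coordinates, press
# direction) from a trial spec.
.trial_geometry <- function(spec, params) {
  xg <- .target_x(spec$desired_target, params)
  xd <- .target_x(spec$default_target, params)
  x0 <- params$x_start %||% xd
  other <- .target_x(setdiff(c("machine", "dot"), spec$default_target), params)
  dir <- if (xg != xd) sign(xg - xd) else sign(other - xd)
  list(x_start = x0, x_default = xd, x_desired = xg, press_dir = as.integer(dir))
}

.policy_kind_code <- c(absent = 0L, ideal = 1L, rate = 2L)

# Low-level batch simulation. `trials` is a data.frame with columns
# kind (integer code), rate, latency, press_dir, x_start, x_default,
# x_desired. Returns the raw list from the compiled kernel.
.sim_batch <- function(trials, params, keep_trajectory = FALSE) {
  sim_trials_cpp(as.integer(trials$kind), as.numeric(trials$rate),
                 as.numeric(trials$latency), as.integer(trials$press_dir),
                 as.numeric(trials$x_start), as.numeric(trials$x_default),
                 as.numeric(trials$x_desired),
                 params$dt, params$response_duration, params$lambda_drift,
                 params$sigma_walk, params$press_mu, params$press_sigma,
                 params$window_width / 2, keep_trajectory)
}

.policy_row <- function(spec, params, policy) {
  g <- .trial_geometry(spec, params)
  rate <- switch(policy$kind,
                 absent = 0,
                 ideal = policy$rate %||% params$max_press_rate,
                 rate = policy$rate)
  if (rate > params$max_press_rate)
    stop(sprintf("policy rate %g exceeds max_press_rate %g",
                 rate, params$max_press_rate), call. = FALSE)
  data.frame(kind = .policy_kind_code[[policy$kind]], rate = rate,
             latency = policy$latency, press_dir = g$press_dir,
             x_start = g$x_start, x_default = g$x_default,
             x_desired = g$x_desired)
}

#' Simulate a single coin-task trial
#'
#' Advances the coin for `response_duration / dt` steps under the given
#' responder policy (no presses occur during the preview; the trial clock
#' starts at response onset) and classifies the final position with
#' [classify_outcome()].
#'
#' @param spec A [trial_spec()].
#' @param params A [task_params()] object.
#' @param policy A [pit_policy()].
#' @param seed Optional integer; when given, the RNG is seeded locally so
#'   that identical `(spec, params, policy, seed)` give identical logs.
#' @param keep_trajectory Keep the full per-step position vector?
#' @return A `pit_trial` log: a list with fields `spec`, `press_times`
#'   (seconds on the response-period clock), `n_presses`,
#'   `first_press_latency` (`NA` when no press occurred), `final_x`,
#'   `outcome` (`"win"`, `"lose"` or `"incomplete"`), `response_duration`,
#'   and optionally `trajectory`.
#' @examples
#' log <- simulate_trial(trial_spec("Withdraw", "Go"), seed = 1)
#' log$outcome
#' @export
simulate_trial <- function(spec, params = task_params(),
                           policy = policy_ideal(), seed = NULL,
                           keep_trajectory = FALSE) {
  stopifnot(inherits(spec, "pit_trial_spec"), inherits(policy, "pit_policy"))
  if (!is.null(seed)) set.seed(seed)
  row <- .policy_row(spec, params, policy)
  res <- .sim_batch(row, params, keep_trajectory)
  times <- res$press_times[[1L]]
  out <- list(spec = spec,
              press_times = times,
              n_presses = length(times),
              first_press_latency = if (length(times)) times[1L] else NA_real_,
              final_x = res$final_x[[1L]],
              outcome = classify_outcome(res$final_x[[1L]], spec, params),
              response_duration = params$response_duration)
  if (keep_trajectory) out$trajectory <- res$trajectory[[1L]]
  structure(out, class = "pit_trial")
}

#' @export
print.pit_trial <- function(x, ...) {
  cat(sprintf("%s %s trial: %d presses, outcome = %s, final x = %.3f\n",
              x$spec$frame, x$spec$go, x$n_presses, x$outcome, x$final_x))
  invisible(x)
}

#' Simulate many replicate trials of one specification
#'
#' @inheritParams simulate_trial
#' @param n Number of replicate trials.
#' @return A tibble with one row per trial: `n_presses`,
#'   `first_press_latency`, `final_x`, `outcome`, and a `press_times`
#'   list-column.
#' @export
simulate_trials <- function(spec, n, params = task_params(),
                            policy = policy_ideal(), seed = NULL) {
  stopifnot(inherits(spec, "pit_trial_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  row <- .policy_row(spec, params, policy)
  trials <- row[rep(1L, n), , drop = FALSE]
  res <- .sim_batch(trials, params)
  n_presses <- lengths(res$press_times)
  tibble(
    trial = seq_len(n),
    n_presses = n_presses,
    first_press_latency = vapply(res$press_times,
                                 function(t) if (length(t)) t[1L] else NA_real_,
                                 numeric(1)),
    final_x = res$final_x,
    outcome = classify_outcome(res$final_x, spec, params),
    press_times = res$press_times)
}

#' Classify a trial outcome from the coin's final position
#'
#' A trial is a `"win"` when the final position lies within half a window
#' width (inclusive) of the desired target, a `"lose"` when it lies within
#' the punitive target's window, and `"incomplete"` otherwise. Window
#' geometry is validated at [task_params()] construction so the two windows
#' cannot overlap.
#'
#' @param final_x Final coin position(s) in \[0, 1\]; vectorized.
#' @inheritParams simulate_trial
#' @return A character vector of outcomes.
#' @export
classify_outcome <- function(final_x, spec, params = task_params()) {
  stopifnot(inherits(spec, "pit_trial_spec"),
            inherits(params, "pit_task_params"))
  if (any(!is.finite(final_x)) || any(final_x < 0 | final_x > 1))
    stop("`final_x` must lie in [0, 1]", call. = FALSE)
  xg <- .target_x(spec$desired_target, params)
  xp <- .target_x(setdiff(c("machine", "dot"), spec$desired_target), params)
  hw <- params$window_width / 2
  ifelse(abs(final_x - xg) <= hw, "win",
         ifelse(abs(final_x - xp) <= hw, "lose", "incomplete"))
}

#' Press-count statistics of the ideal responder
#'
#' Simulates Go trials under the ideal bang-bang policy and summarizes the
#' number of key presses among trials that end in a win. Under the packaged
#' calibrated defaults the mean reproduces the 32.12 presses per 5-s trial
#' that the task dynamics were designed around.
#'
#' @param params A [task_params()] object.
#' @param n_trials Number of Go trials to simulate (at least 100);
#'   Approach-Go and Withdraw-Go are interleaved evenly.
#' @param seed Optional integer seed.
#' @return A list with `mean`, `sd`, `n_win` and `n_trials`.
#' @examples
#' required_presses_stat(n_trials = 200, seed = 1)$mean
#' @export
required_presses_stat <- function(params = task_params(), n_trials = 5000,
                                  seed = NULL) {
  stopifnot(n_trials >= 100)
  if (!is.null(seed)) set.seed(seed)
  specs <- list(trial_spec("Approach", "Go"), trial_spec("Withdraw", "Go"))
  rows <- do.call(rbind, lapply(specs, .policy_row,
                                params = params, policy = policy_ideal()))
  trials <- rows[rep(1:2, length.out = n_trials), , drop = FALSE]
  res <- .sim_batch(trials, params)
  counts <- lengths(res$press_times)
  hw <- params$window_width / 2
  won <- abs(res$final_x - trials$x_desired) <= hw
  if (!any(won))
    stop("no winning trials; task parameters are not calibrated",
         call. = FALSE)
  list(mean = mean(counts[won]), sd = sd(counts[won]),
       n_win = sum(won), n_trials = n_trials)
}

#' Calibrate the task dynamics to a target press count
#'
#' Tunes the mean press displacement `press_mu` (holding the
#' `press_sigma`/`press_mu` and `window_width`/`press_mu` ratios fixed) by
#' bisection on Monte-Carlo estimates of [required_presses_stat()], so that
#' the ideal responder needs `target_mean_presses` key presses on average to
#' win a Go trial, with the target window `window_in_presses` mean presses
#' wide. The calibration is deterministic given `seed`: every candidate is
#' evaluated with the same seed.
#'
#' @param base A [task_params()] object supplying all non-calibrated fields.
#' @param target_mean_presses Target mean press count among winning trials.
#' @param window_in_presses Width of the target window in mean presses.
#' @param tol Acceptable deviation of the achieved mean from the target.
#' @param n_trials Monte-Carlo trials per bisection step.
#' @param max_iter Maximum bisection steps before giving up.
#' @param seed Integer seed used for every Monte-Carlo evaluation.
#' @param interval Search interval for `press_mu`.
#' @return A calibrated `pit_task_params` object; the achieved mean and sd
#'   are attached as attribute `"calibration"`.
#' @export
calibrate_params <- function(base = task_params(),
                             target_mean_presses = 32.12,
                             window_in_presses = 4,
                             tol = 0.5,
                             n_trials = 2000,
                             max_iter = 40,
                             seed = 171,
                             interval = c(0.004, 0.05)) {
  stopifnot(inherits(base, "pit_task_params"))
  sigma_ratio <- base$press_sigma / base$press_mu
  build <- function(mu) {
    task_params(dt = base$dt, response_duration = base$response_duration,
                preview_duration = base$preview_duration,
                lambda_drift = base$lambda_drift, press_mu = mu,
                press_sigma = sigma_ratio * mu, sigma_walk = base$sigma_walk,
                window_width = window_in_presses * mu,
                x_machine = base$x_machine, x_dot = base$x_dot,
                x_start = base$x_start, max_press_rate = base$max_press_rate)
  }
  mean_at <- function(mu) {
    # a displacement too small to ever reach the window counts as infinite
    tryCatch(
      required_presses_stat(build(mu), n_trials = n_trials, seed = seed)$mean,
      error = function(e) Inf)
  }
  lo <- interval[1]; hi <- interval[2]
  f_lo <- mean_at(lo); f_hi <- mean_at(hi)
  if (f_lo < target_mean_presses || f_hi > target_mean_presses)
    stop("calibration failure: target press count not bracketed by the ",
         "search interval", call. = FALSE)
  mid <- NA_real_; f_mid <- NA_real_
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- mean_at(mid)
    if (abs(f_mid - target_mean_presses) <= tol * 0.5) break
    if (f_mid > target_mean_presses) lo <- mid else hi <- mid
    if (i == max_iter)
      stop("calibration failure: no convergence within `max_iter` ",
           "bisection steps", call. = FALSE)
  }
  out <- build(mid)
  check <- required_presses_stat(out, n_trials = max(n_trials, 2000),
                                 seed = seed)
  if (abs(check$mean - target_mean_presses) > tol)
    stop("calibration failure: achieved mean ", round(check$mean, 2),
         " outside tolerance", call. = FALSE)
  attr(out, "calibration") <- list(press_mu = mid, mean = check$mean,
                                   sd = check$sd, target = target_mean_presses)
  out
}
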