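#' Parameters of the coin approach/withdraw task
#'
#' Physical and timing constants of the simulated coin game. The coin moves
#' on a horizontal screen axis normalized to \[0, 1\]. At each time step of
#' length `dt` it relaxes exponentially (rate `lambda_drift`) toward the
#' column of the trial's default target, receives Gaussian random-walk noise
#' with scale `sigma_walk`, and, if the space key was pressed during that
#' step, an additional signed displacement drawn from
#' `Normal(press_mu, press_sigma)` directed away from the default target.
#' A trial is won when the coin's final position lies within a window of
#' horizontal length `window_width` centred on the desired target.
#'
#' The packaged defaults are calibrated (see [calibrate_params()]) so that
#' the ideal responder needs on average 32.12 key presses over a 5-s trial
#' to win, and so that the target window is four mean key presses wide.
#'
#' @param dt Step duration in seconds. Default 1/60 s (one monitor frame).
#' @param response_duration Length of the response period in seconds.
#' @param preview_duration Length of the pre-response preview in seconds.
#'   No presses are possible during the preview; all times in trial logs are
#'   on the response-period clock.
#' @param lambda_drift Exponential relaxation rate toward the default
#'   target, in 1/s.
#' @param press_mu Mean horizontal displacement per key press, in normalized
#'   screen units.
#' @param press_sigma SD of the displacement per press. Defaults to
#'   `0.3 * press_mu`; negative draws (momentary backward jumps) are allowed.
#' @param sigma_walk Random-walk noise scale, in screen units per sqrt(s).
#' @param window_width Horizontal length of a target window. Defaults to
#'   `4 * press_mu` (a window approximately four key presses wide).
#' @param x_machine,x_dot Horizontal coordinates of the vending machine and
#'   of the black dot, both in \[0, 1\].
#' @param x_start Optional fixed start column for the coin. The default
#'   (`NULL`) starts the coin in the column of the trial's default target
#'   (bottom-middle for machine-default trials, bottom-right for
#'   dot-default trials).
#' @param max_press_rate Cap on responder press rates, in presses/s.
#'
#' @return An object of class `pit_task_params` (a validated list).
#' @examples
#' p <- task_params()
#' p$window_width / p$press_mu   # the window is four mean presses wide
#' @export
task_params <- function(dt = 1 / 60,
                        response_duration = 5,
                        preview_duration = 1,
                        lambda_drift = 0.05,
                        press_mu = 0.013793,
                        press_sigma = NULL,
                        sigma_walk = 0.002,
                        window_width = NULL,
                        x_machine = 0.5,
                        x_dot = 0.9,
                        x_start = NULL,
                        max_press_rate = 9) {
  press_sigma <- press_sigma %||% (0.3 * press_mu)
  window_width <- window_width %||% (4 * press_mu)
  .assert_scalar_num(dt, "dt", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(response_duration, "response_duration",
                     lower = 0, strict_lower = TRUE)
  .assert_scalar_num(preview_duration, "preview_duration", lower = 0)
  .assert_scalar_num(lambda_drift, "lambda_drift", lower = 0)
  .assert_scalar_num(press_mu, "press_mu", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(press_sigma, "press_sigma", lower = 0)
  .assert_scalar_num(sigma_walk, "sigma_walk", lower = 0)
  .assert_scalar_num(window_width, "window_width",
                     lower = 0, strict_lower = TRUE)
  .assert_scalar_num(x_machine, "x_machine", lower = 0, upper = 1)
  .assert_scalar_num(x_dot, "x_dot", lower = 0, upper = 1)
  .assert_scalar_num(max_press_rate, "max_press_rate",
                     lower = 0, strict_lower = TRUE)
  if (!is.null(x_start)) .assert_scalar_num(x_start, "x_start",
                                            lower = 0, upper = 1)
  if (abs(x_machine - x_dot) <= window_width)
    stop("target windows overlap: |x_machine - x_dot| must exceed ",
         "window_width", call. = FALSE)
  structure(
    list(dt = dt, response_duration = response_duration,
         preview_duration = preview_duration, lambda_drift = lambda_drift,
         press_mu = press_mu, press_sigma = press_sigma,
         sigma_walk = sigma_walk, window_width = window_width,
         x_machine = x_machine, x_dot = x_dot, x_start = x_start,
         max_press_rate = max_press_rate),
    class = "pit_task_params")
}

#' @export
print.pit_task_params <- function(x, ...) {
  cat("Coin-task parameters\n")
  cat(sprintf("  dt = %.4g s, response period = %g s (preview %g s)\n",
              x$dt, x$response_duration, x$preview_duration))
  cat(sprintf("  drift lambda = %g /s, walk sigma = %g /sqrt(s)\n",
              x$lambda_drift, x$sigma_walk))
  cat(sprintf("  press displacement: N(%.5g, %.5g), window width = %.5g (%.3g presses)\n",
              x$press_mu, x$press_sigma, x$window_width,
              x$window_width / x$press_mu))
  cat(sprintf("  targets: machine at %g, dot at %g; max press rate %g /s\n",
              x$x_machine, x$x_dot, x$max_press_rate))
  invisible(x)
}

#' Specification of one coin-task trial
#'
#' Derives the rewarded ("desired") and default targets from the trial's
#' framing and Go/NoGo assignment. In the Approach frame the vending machine
#' rewards and the dot punishes; in the Withdraw frame the dot rewards and
#' the machine punishes. On Go trials the coin's default route leads to the
#' undesired (punitive) target, so key presses are needed; on NoGo trials
#' the default route already leads to the desired target.
#'
#' @param frame `"Approach"` or `"Withdraw"`.
#' @param go `"Go"` or `"NoGo"`.
#' @param cs Pavlovian background: `"none"` (gray), `"CS+"` or `"CS-"`.
#' @return An object of class `pit_trial_spec` with fields `frame`, `go`,
#'   `cs`, `desired_target` and `default_target` (each `"machine"` or
#'   `"dot"`).
#' @examples
#' trial_spec("Withdraw", "Go")$default_target  # "machine"
#' @export
trial_spec <- function(frame = c("Approach", "Withdraw"),
                       go = c("Go", "NoGo"),
                       cs = c("none", "CS+", "CS-")) {
  frame <- match.arg(frame)
  go <- match.arg(go)
  cs <- match.arg(cs)
  desired <- if (frame == "Approach") "machine" else "dot"
  other <- if (desired == "machine") "dot" else "machine"
  default <- if (go == "Go") other else desired
  structure(list(frame = frame, go = go, cs = cs,
                 desired_target = desired, default_target = default),
            class = "pit_trial_spec")
}

#' @export
print.pit_trial_spec <- function(x, ...) {
  cat(sprintf("%s %s trial (cs = %s): desired = %s, default = %s\n",
              x$frame, x$go, x$cs, x$desired_target, x$default_target))
  invisible(x)
}

.target_x <- function(target, params) {
  switch(target, machine = params$x_machine, dot = params$x_dot,
         stop("unknown target: ", target))
}

#' Responder policies for the coin task
#'
#' Three kinds of responder are available. `"absent"` never presses.
#' `"ideal"` is a bang-bang controller that presses at its rate cap whenever
#' the coin is outside the desired window on the default-target side, and
#' stops inside it; it is used to calibrate the task dynamics. `"rate"` is a
#' free-running stochastic responder that presses with constant hazard
#' `rate` from `latency` seconds after response onset, regardless of coin
#' position; it emulates a human pressing with a given vigor and is the
#' policy the synthetic cohort generator drives.
#'
#' @param kind One of `"ideal"`, `"absent"`, `"rate"`.
#' @param rate Press rate in presses/s. For `"ideal"` the default (`NULL`)
#'   is the task's `max_press_rate`; required for `"rate"`.
#' @param latency Seconds after response onset before pressing can start
#'   (used by `"rate"`).
#' @return An object of class `pit_policy`.
#' @export
pit_policy <- function(kind = c("ideal", "absent", "rate"),
                       rate = NULL, latency = 0) {
  kind <- match.arg(kind)
  if (kind == "rate" && is.null(rate))
    stop("a `rate` policy needs a press rate", call. = FALSE)
  if (!is.null(rate)) .assert_scalar_num(rate, "rate", lower = 0)
  .assert_scalar_num(latency, "latency", lower = 0)
  structure(list(kind = kind, rate = rate, latency = latency),
            class = "pit_policy")
}

#' @rdname pit_policy
#' @export
policy_ideal <- function(rate = NULL) pit_policy("ideal", rate = rate)

#' @rdname pit_policy
#' @export
policy_absent <- function() pit_policy("absent")

#' @rdname pit_policy
#' @param ... Passed on to [pit_policy()].
#' @export
policy_rate <- function(rate, ...) pit_policy("rate", rate = rate, ...)
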