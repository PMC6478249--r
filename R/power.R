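#' Power of the paired t-test via the noncentral t distribution
#'
#' Exact power of a paired t-test for a standardized paired effect size
#' `d`: with `n` pairs the test statistic follows a noncentral t
#' distribution with `n - 1` degrees of freedom and noncentrality
#' `d * sqrt(n)`, and power is the probability mass beyond the central-t
#' critical value. This is the same model conventional power software uses
#' for paired designs, so published sample-size claims reproduce without
#' external tools.
#'
#' @param d Standardized paired effect size (mean of differences over SD of
#'   differences).
#' @param n Number of pairs (>= 2).
#' @param alpha Type-I error level, in (0, 1).
#' @param sided `"one"` or `"two"`.
#' @return The power, a probability.
#' @examples
#' power_paired_t(d = 0.42, n = 37, alpha = 0.05, sided = "one")
#' @export
power_paired_t <- function(d, n, alpha = 0.05, sided = c("one", "two")) {
  sided <- match.arg(sided)
  .assert_scalar_num(d, "d")
  .assert_scalar_num(n, "n", lower = 2)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  df <- n - 1
  ncp <- d * sqrt(n)
  if (sided == "one") {
    tc <- qt(1 - alpha, df)
    pt(tc, df, ncp = ncp, lower.tail = FALSE)
  } else {
    tc <- qt(1 - alpha / 2, df)
    pt(-tc, df, ncp = ncp) + pt(tc, df, ncp = ncp, lower.tail = FALSE)
  }
}

#' Smallest sample size reaching a target power
#'
#' Returns the minimal integer number of pairs for which
#' [power_paired_t()] meets `target_power`.
#'
#' @inheritParams power_paired_t
#' @param target_power Desired power, in (0, 1).
#' @param n_max Safety cap on the search.
#' @return An integer sample size.
#' @examples
#' required_n(d = 0.42, target_power = 0.80, alpha = 0.05, sided = "one")
#' @export
required_n <- function(d, target_power = 0.80, alpha = 0.05,
                       sided = c("one", "two"), n_max = 1e6) {
  sided <- match.arg(sided)
  if (!is.numeric(target_power) || target_power <= 0 || target_power >= 1)
    stop("`target_power` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("no finite sample size reaches the target power when d <= 0",
         call. = FALSE)
  n <- 2L
  while (n <= n_max) {
    if (power_paired_t(d, n, alpha, sided) >= target_power) return(n)
    n <- n + 1L
  }
  stop("no n <= n_max reaches the target power", call. = FALSE)
}

#' Monte-Carlo power of the paired t-test
#'
#' Simulation oracle for the analytic power: paired difference scores are
#' drawn from `Normal(d, 1)` and the rejection fraction at level `alpha` is
#' returned.
#'
#' @inheritParams power_paired_t
#' @param reps Number of simulated cohorts (>= 1000).
#' @param seed Optional integer seed.
#' @return The estimated power; the Monte-Carlo standard error is attached
#'   as attribute `"se"`.
#' @export
mc_power <- function(d, n, alpha = 0.05, sided = c("one", "two"),
                     reps = 10000, seed = NULL) {
  sided <- match.arg(sided)
  stopifnot(reps >= 1000, n >= 2)
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(reps * n, mean = d, sd = 1), nrow = reps)
  m <- rowMeans(X)
  s <- sqrt((rowSums(X^2) - reps_rowmean_sq(X, m)) / (n - 1))
  tstat <- m / (s / sqrt(n))
  df <- n - 1
  rej <- if (sided == "one") tstat > qt(1 - alpha, df)
         else abs(tstat) > qt(1 - alpha / 2, df)
  est <- mean(rej)
  attr(est, "se") <- sqrt(est * (1 - est) / reps)
  est
}

# rowwise n * mean^2 helper (keeps mc_power readable)
reps_rowmean_sq <- function(X, m) ncol(X) * m^2
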