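#' Paired t-test with Cohen's d
#'
#' Tests the paired CS+/CS- contrast and reports Cohen's d for paired data,
#' defined on the difference scores: `d = mean(diff) / sd(diff)`, so that
#' `d = t / sqrt(n)` exactly.
#'
#' @param x_plus,x_minus Paired observations (equal length >= 2).
#' @param sided `"two"` (default) or `"one"`; the one-sided alternative is
#'   `x_plus > x_minus`, the direction of conditioned facilitation.
#' @return A `pit_ttest` list: `t`, `df`, `p`, `cohens_d`, `n_pairs`,
#'   `sided`.
#' @examples
#' set.seed(1)
#' d <- rnorm(20, 0.3); paired_t(d + rnorm(20), rnorm(20))$cohens_d
#' @export
paired_t <- function(x_plus, x_minus, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (length(x_plus) != length(x_minus) || length(x_plus) < 2L)
    stop("`x_plus` and `x_minus` must be paired vectors of length >= 2",
         call. = FALSE)
  diffs <- x_plus - x_minus
  if (any(!is.finite(diffs))) stop("non-finite values", call. = FALSE)
  if (sd(diffs) == 0)
    stop("zero-variance differences: paired t is undefined", call. = FALSE)
  ht <- t.test(x_plus, x_minus, paired = TRUE,
               alternative = if (sided == "one") "greater" else "two.sided")
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, cohens_d = mean(diffs) / sd(diffs),
                 n_pairs = length(diffs), sided = sided),
            class = "pit_ttest")
}

#' @export
print.pit_ttest <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.4g (%s-sided), d = %.3f, n = %d\n",
              x$df, x$t, x$p, x$sided, x$cohens_d, x$n_pairs))
  invisible(x)
}

#' Bonferroni correction for a planned family of tests
#'
#' Multiplies each p-value by the family size `m` and caps at 1. Unlike
#' [stats::p.adjust()], `m` may exceed the number of p-values supplied
#' (e.g. correcting a reported subset of a larger planned family); an `m`
#' smaller than the number of tests is an error.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Number of tests in the family (default `length(p)`).
#' @return Adjusted p-values.
#' @examples
#' bonferroni_adjust(0.017, m = 2)  # 0.034
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p))
    stop("`m` must be at least the number of tests supplied", call. = FALSE)
  pmin(1, m * p)
}
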