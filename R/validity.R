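#' Reversed regression fit of a threat-learning measure
#'
#' Quantifies how well a measure separates CS+ from CS- across subjects:
#' the CS type (coded +1/-1) is regressed on the measure value together
#' with single-subject intercepts, by ordinary least squares. This setup is
#' formally equivalent to a paired t-test on the measure; the residual sum
#' of squares feeds the AIC-based evidence comparison. With a constant
#' measure the fit degenerates gracefully to the intercepts-only model.
#'
#' @param table A data frame with columns `subject`, `cs` (exactly two
#'   levels, `"CS+"`/`"CS-"`, one row per subject per level) and `value`;
#'   at least 3 subjects.
#' @param measure Optional measure name carried into the result.
#' @return A `pit_modelfit` list: `measure`, `n` (observations, 2 x
#'   subjects), `r` (regressors: subject intercepts + 1 slope), `rss`,
#'   `aic`.
#' @export
fit_reversed_regression <- function(table, measure = NA_character_) {
  stopifnot(is.data.frame(table),
            all(c("subject", "cs", "value") %in% names(table)))
  lev <- sort(unique(table$cs))
  if (!identical(lev, sort(c("CS+", "CS-"))))
    stop("`cs` must contain exactly the levels CS+ and CS-", call. = FALSE)
  subs <- unique(table$subject)
  if (length(subs) < 3L) stop("need at least 3 subjects", call. = FALSE)
  counts <- table(table$subject, table$cs)
  if (nrow(table) != 2L * length(subs) || any(counts != 1L))
    stop("need exactly one value per subject per CS level", call. = FALSE)
  if (any(!is.finite(table$value))) stop("non-finite measure values",
                                         call. = FALSE)
  y <- ifelse(table$cs == "CS+", 1, -1)
  X <- cbind(stats::model.matrix(~ 0 + factor(table$subject)), table$value)
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  r <- length(subs) + 1L
  structure(list(measure = measure, n = n, r = r, rss = rss,
                 aic = aic_from_rss(rss, n, r)),
            class = "pit_modelfit")
}

#' @export
print.pit_modelfit <- function(x, ...) {
  cat(sprintf("reversed regression [%s]: n = %d, r = %d, RSS = %.4g, AIC = %.2f\n",
              x$measure, x$n, x$r, x$rss, x$aic))
  invisible(x)
}

#' Akaike information criterion from a residual sum of squares
#'
#' `AIC = n log(RSS / n) + 2 (r + 1)` with natural logarithm, for a
#' least-squares model with `n` observations and `r` regressors.
#'
#' @param rss Residual sum of squares (> 0; an exactly zero RSS yields
#'   `-Inf` with a warning).
#' @param n Number of observations.
#' @param r Number of regressors.
#' @return The AIC value.
#' @examples
#' aic_from_rss(70, 70, 36)  # log term vanishes: 2 * (36 + 1) = 74
#' @export
aic_from_rss <- function(rss, n, r) {
  .assert_scalar_num(n, "n", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(r, "r", lower = 0)
  if (!is.numeric(rss) || length(rss) != 1L || is.na(rss) || rss < 0)
    stop("`rss` must be a single non-negative number", call. = FALSE)
  if (rss == 0) {
    warning("RSS is exactly zero; AIC is -Inf (perfect fit)", call. = FALSE)
    return(-Inf)
  }
  n * log(rss / n) + 2 * (r + 1)
}

#' Log Bayes factor from AIC values
#'
#' `LBF = (AIC - AIC_ref) / 2`; smaller values indicate a better model and
#' an absolute difference above 3 is conventionally regarded as decisive.
#'
#' @param aic AIC value(s).
#' @param aic_ref Reference AIC.
#' @return The log Bayes factor(s) relative to the reference.
#' @export
lbf <- function(aic, aic_ref) {
  if (any(!is.finite(c(aic, aic_ref))))
    stop("AIC inputs must be finite", call. = FALSE)
  (aic - aic_ref) / 2
}

#' Compare the predictive validity of threat-learning measures
#'
#' Fits the reversed regression to each measure, converts the residual sums
#' of squares to AIC, and expresses every measure's evidence as a log Bayes
#' factor relative to a reference measure (the behavioral PIT measure by
#' convention). All models must share the same n and r -- the same
#' subjects, one value per subject per CS level -- so AIC differences
#' reduce to RSS ratios.
#'
#' @param tables Named list of measure tables (see
#'   [fit_reversed_regression()]); [measure_tables()] builds it from a
#'   synthetic cohort.
#' @param reference Name of the reference measure, default `"PIT"`.
#' @return A tibble with one row per measure: `measure`, `n`, `r`, `rss`,
#'   `aic`, `lbf`, `decisive` (`|lbf| > 3`).
#' @examples
#' coh <- sample_cohort(make_design(2), n_subjects = 12, seed = 3, phases = 3)
#' compare_measures(measure_tables(coh))
#' @export
compare_measures <- function(tables, reference = "PIT") {
  stopifnot(is.list(tables), length(tables) >= 2L,
            !is.null(names(tables)), all(nzchar(names(tables))))
  if (!reference %in% names(tables))
    stop("reference measure '", reference, "' not among the tables",
         call. = FALSE)
  subj_sets <- lapply(tables, function(t) sort(unique(t$subject)))
  if (!all(vapply(subj_sets, identical, logical(1), subj_sets[[1L]])))
    stop("all measures must cover the same subjects", call. = FALSE)
  fits <- mapply(fit_reversed_regression, tables, names(tables),
                 SIMPLIFY = FALSE)
  out <- dplyr::bind_rows(lapply(fits, function(f)
    tibble(measure = f$measure, n = f$n, r = f$r, rss = f$rss,
           aic = f$aic)))
  out$lbf <- lbf(out$aic, out$aic[out$measure == reference])
  out$decisive <- abs(out$lbf) > 3
  out
}

#' Correlations of CS discrimination across measures
#'
#' Two complementary views of whether different threat-learning readouts
#' index the same underlying memory: (i) Pearson correlations of the
#' per-subject CS+ minus CS- differences between all measure pairs, and
#' (ii) residual correlations computed on the subject x CS values after
#' subtracting each CS level's grand mean within each measure.
#'
#' @param tables Named list of measure tables (>= 4 subjects, identical
#'   subject sets).
#' @return A list with components `difference` and `residual`, each a list
#'   of square matrices `r` and `p`.
#' @export
cross_measure_correlations <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2L, !is.null(names(tables)))
  subj <- sort(unique(tables[[1L]]$subject))
  if (length(subj) < 4L) stop("need at least 4 subjects", call. = FALSE)
  aligned <- lapply(tables, function(t) {
    if (!identical(sort(unique(t$subject)), subj) ||
        nrow(t) != 2L * length(subj) ||
        any(table(t$subject, t$cs) != 1L))
      stop("all measures need one value per subject per CS level for the ",
           "same subjects", call. = FALSE)
    t <- t[order(t$subject, t$cs), ]
    if (sd(t$value) == 0) stop("zero-variance measure", call. = FALSE)
    t
  })
  diffs <- vapply(aligned, function(t) {
    t$value[t$cs == "CS+"] - t$value[t$cs == "CS-"]
  }, numeric(length(subj)))
  resids <- vapply(aligned, function(t) {
    stats::ave(t$value, t$cs, FUN = function(v) v - mean(v))
  }, numeric(2L * length(subj)))
  corr_with_p <- function(M) {
    k <- ncol(M)
    r <- cor(M)
    p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      p[i, j] <- if (i == j) 0 else cor.test(M[, i], M[, j])$p.value
    }
    list(r = r, p = p)
  }
  list(difference = corr_with_p(diffs), residual = corr_with_p(resids))
}
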