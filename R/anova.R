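#' Repeated-measures ANOVA with partitioned error variance
#'
#' Fits a fully within-subject factorial ANOVA in which every effect is
#' tested against its own subject-by-effect interaction error term (the
#' univariate `aov` error-stratum approach). For effects with more than one
#' numerator degree of freedom the Greenhouse-Geisser sphericity estimate
#' \eqn{\epsilon} and the corrected p-value are reported; effect sizes are
#' generalized \eqn{\eta^2} with all error variance -- including the
#' between-subject variance -- in the denominator, so that values are
#' comparable across designs.
#'
#' @param data A data frame with one observation per subject x cell (use
#'   [summarize_conditions()] or aggregate first; duplicated cells are an
#'   error, as are incomplete designs).
#' @param dv Name of the dependent-variable column.
#' @param within Names of one to three within-subject factor columns.
#' @param subject Name of the subject identifier column.
#' @return A tibble with one row per effect: `effect`, `df_num`, `df_den`,
#'   `F`, `epsilon`, `p` (uncorrected), `p_gg` (Greenhouse-Geisser
#'   corrected; equal to `p` for single-df effects), `ges`.
#' @examples
#' coh <- sample_cohort(make_design(1), n_subjects = 6, seed = 8, phases = 3)
#' summ <- summarize_conditions(coh$events, phase = 3)
#' rm_anova(summ, dv = "response_rate", within = c("cs", "frame", "go"))
#' @export
rm_anova <- function(data, dv, within, subject = "subject") {
  stopifnot(is.data.frame(data), length(within) >= 1, length(within) <= 3)
  miss <- setdiff(c(dv, within, subject), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df <- as.data.frame(data[c(subject, within, dv)])
  df[[subject]] <- factor(df[[subject]])
  for (w in within) df[[w]] <- factor(df[[w]])
  if (any(is.na(df[[dv]])))
    stop("missing values in the dependent variable", call. = FALSE)
  n_cells <- prod(vapply(within, function(w) nlevels(df[[w]]), integer(1)))
  key <- interaction(df[c(subject, within)], drop = TRUE)
  if (anyDuplicated(key))
    stop("more than one observation per subject x cell; aggregate first",
         call. = FALSE)
  if (nrow(df) != nlevels(df[[subject]]) * n_cells)
    stop("incomplete design: every subject needs every cell", call. = FALSE)

  rhs <- paste(within, collapse = " * ")
  form <- stats::as.formula(
    paste0(dv, " ~ ", rhs, " + Error(", subject, "/(", rhs, "))"))
  sm <- summary(aov(form, data = df))

  eff_rows <- list()
  ss_err_total <- 0
  for (stratum in sm) {
    tab <- stratum[[1L]]
    rn <- trimws(rownames(tab))
    res <- rn == "Residuals"
    ss_err_total <- ss_err_total + sum(tab[res, "Sum Sq"])
    for (i in which(!res)) {
      eff_rows[[rn[i]]] <- list(
        effect = rn[i], df_num = tab[i, "Df"],
        df_den = tab[res, "Df"][1L], ss = tab[i, "Sum Sq"],
        F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
    }
  }

  out <- lapply(eff_rows, function(e) {
    facs <- strsplit(e$effect, ":", fixed = TRUE)[[1L]]
    eps <- .gg_epsilon_effect(df, dv, subject, facs)
    p_gg <- if (e$df_num > 1)
      pf(e$F, eps * e$df_num, eps * e$df_den, lower.tail = FALSE)
    else e$p
    tibble(effect = e$effect, df_num = e$df_num, df_den = e$df_den,
           F = e$F, epsilon = eps, p = e$p, p_gg = p_gg,
           ges = e$ss / (e$ss + ss_err_total))
  })
  dplyr::bind_rows(out)
}

# orthonormal polynomial-free contrasts for a k-level factor
.orth_contrasts <- function(k) {
  M <- stats::contr.helmert(k)
  sweep(M, 2L, sqrt(colSums(M^2)), "/")
}

# Greenhouse-Geisser epsilon for one effect: collapse the data to the
# effect's cells (averaging over the remaining factors), take the
# between-subject covariance of the cell scores, and evaluate the Box
# epsilon on the effect's orthonormal contrast space.
.gg_epsilon_effect <- function(df, dv, subject, facs) {
  ks <- vapply(facs, function(f) nlevels(df[[f]]), integer(1))
  if (prod(ks - 1L) == 1L) return(1)
  cellmeans <- tapply(df[[dv]], df[c(subject, facs)], mean)
  Y <- matrix(cellmeans, nrow = nlevels(df[[subject]]))
  S <- cov(Y)
  # cells vary fastest in the first factor (tapply array order)
  M <- Reduce(kronecker, rev(lapply(ks, .orth_contrasts)))
  E <- crossprod(M, S %*% M)
  q <- ncol(M)
  eps <- sum(diag(E))^2 / (q * sum(E * E))
  min(1, max(1 / q, eps))
}

#' Greenhouse-Geisser sphericity estimate from a cell covariance matrix
#'
#' Computes the Box/Greenhouse-Geisser \eqn{\hat\epsilon} of a k x k
#' covariance matrix of within-subject cell scores, treated as one factor
#' with k levels. The estimate lies in (1/(k-1), 1\]; it equals 1 exactly
#' when k = 2 or when the covariance is compound symmetric (sphericity
#' holds).
#'
#' @param cell_covariance A symmetric k x k covariance matrix, k >= 2.
#' @return The epsilon estimate.
#' @examples
#' gg_epsilon(diag(3) + 0.3)  # compound symmetry: 1
#' @export
gg_epsilon <- function(cell_covariance) {
  S <- as.matrix(cell_covariance)
  k <- nrow(S)
  if (k < 2L || ncol(S) != k)
    stop("`cell_covariance` must be a square matrix with k >= 2",
         call. = FALSE)
  if (any(!is.finite(S)) || max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("`cell_covariance` must be a finite symmetric matrix",
         call. = FALSE)
  M <- .orth_contrasts(k)
  E <- crossprod(M, S %*% M)
  if (sum(E * E) <= 0) stop("degenerate (singular) covariance",
                            call. = FALSE)
  eps <- sum(diag(E))^2 / ((k - 1) * sum(E * E))
  min(1, max(1 / (k - 1), eps))
}
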