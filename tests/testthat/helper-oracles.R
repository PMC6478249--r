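# Independent oracles used across the test files. Each one recomputes a
# quantity by a different route than the package implementation.

# Brute-force repeated-measures ANOVA by inclusion-exclusion sums of
# squares over all factor subsets (subject treated as a random factor).
# Returns one row per within effect with its F ratio against the
# subject-by-effect interaction term.
oracle_rm_anova <- function(df, dv, within, subject = "subject") {
  y <- df[[dv]]
  facs <- c(subject, within)
  levels_of <- vapply(facs, function(f) length(unique(df[[f]])), integer(1))
  names(levels_of) <- facs

  effect_ss <- function(members) {
    u <- rep(0, length(y))
    subsets <- list(character(0))
    for (m in members) subsets <- c(subsets, lapply(subsets, c, m))
    for (F_ in subsets) {
      sgn <- (-1)^(length(members) - length(F_))
      mF <- if (length(F_) == 0) mean(y)
            else stats::ave(y, df[F_], FUN = mean)
      u <- u + sgn * mF
    }
    sum(u^2)
  }
  effect_df <- function(members) prod(levels_of[members] - 1L)

  all_effects <- list(character(0))
  for (w in within) all_effects <- c(all_effects, lapply(all_effects, c, w))
  all_effects <- all_effects[lengths(all_effects) > 0]

  rows <- lapply(all_effects, function(e) {
    err <- c(subject, e)
    data.frame(effect = paste(e, collapse = ":"),
               df_num = effect_df(e), df_den = effect_df(err),
               F = (effect_ss(e) / effect_df(e)) /
                   (effect_ss(err) / effect_df(err)))
  })
  do.call(rbind, rows)
}

# Textbook Greenhouse-Geisser epsilon via the double-centering formula on
# the raw covariance matrix.
oracle_gg <- function(S) {
  k <- nrow(S)
  sbar <- mean(S)
  srow <- rowMeans(S)
  sdiag <- mean(diag(S))
  num <- k^2 * (sdiag - sbar)^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(srow^2) + k^2 * sbar^2)
  num / den
}

# Reversed-regression RSS by explicit normal equations on a hand-built
# design matrix (subject indicator columns plus the measure).
oracle_reversed_rss <- function(table) {
  subs <- sort(unique(table$subject))
  X <- cbind(outer(table$subject, subs, "==") * 1, table$value)
  y <- ifelse(table$cs == "CS+", 1, -1)
  beta <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% beta)^2)
}

# Step-by-step R replay of a simulated trial using step_coin() (absent
# policy) or an explicit bang-bang controller (ideal policy), consuming
# the RNG stream in the same order as the compiled kernel.
oracle_replay_trial <- function(spec, params, policy_kind = "absent",
                                rate = NULL) {
  xg <- if (spec$desired_target == "machine") params$x_machine else params$x_dot
  xd <- if (spec$default_target == "machine") params$x_machine else params$x_dot
  other <- if (spec$default_target == "machine") params$x_dot else params$x_machine
  dir <- if (xg != xd) sign(xg - xd) else sign(other - xd)
  rate <- rate %||% params$max_press_rate
  n_steps <- round(params$response_duration / params$dt)
  hw <- params$window_width / 2
  x <- xd
  traj <- numeric(n_steps + 1)
  traj[1] <- x
  press_times <- numeric(0)
  last_press <- -1e12
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * params$dt
    press <- policy_kind == "ideal" && dir != 0 &&
      dir * (xg - x) > hw && (t - last_press >= 1 / rate - 1e-12)
    x <- step_coin(x, press, params, xd, if (dir == 0) 1L else dir)
    if (press) {
      press_times <- c(press_times, t)
      last_press <- t
    }
    traj[s + 1] <- x
  }
  list(trajectory = traj, press_times = press_times, final_x = x)
}

# Dense-grid piecewise-linear interpolation oracle for the shock
# calibration: walk a fine grid of currents, interpolate the rating within
# each segment, and return the first grid current whose rating reaches the
# target.
oracle_us_current <- function(current, rating, target, grid_n = 200000) {
  ord <- order(current)
  current <- current[ord]
  rating <- rating[ord]
  grid <- seq(min(current), max(current), length.out = grid_n)
  seg <- findInterval(grid, current, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), length(current) - 1L)
  w <- (grid - current[seg]) / (current[seg + 1L] - current[seg])
  r <- rating[seg] + w * (rating[seg + 1L] - rating[seg])
  hit <- which(r >= target)
  if (length(hit) == 0) return(max(current))
  grid[hit[1L]]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Shared Monte-Carlo replicates of the Experiment-2 study conditions
# (n = 35 subjects, default effects): per replicate the recovered
# Withdraw-Go d and whether the predictive-validity AIC ranking is
# heart period < SCR < PIT. Computed once per session and reused.
.exp2_rep_cache <- new.env(parent = emptyenv())
get_exp2_reps <- function(n_reps = 300, seed = 2024) {
  key <- sprintf("reps_%d_%d", n_reps, seed)
  if (!is.null(.exp2_rep_cache[[key]])) return(.exp2_rep_cache[[key]])
  des <- make_design(2)
  set.seed(seed)
  d <- numeric(n_reps)
  ord <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    coh <- sample_cohort(des, n_subjects = 35, phases = 3)
    tabs <- measure_tables(coh)
    cm <- compare_measures(tabs)
    a <- setNames(cm$aic, cm$measure)
    pit <- tabs$PIT
    d[i] <- paired_t(pit$value[pit$cs == "CS+"],
                     pit$value[pit$cs == "CS-"])$cohens_d
    ord[i] <- a[["heart_period"]] < a[["SCR"]] && a[["SCR"]] < a[["PIT"]]
  }
  .exp2_rep_cache[[key]] <- list(d = d, ord = ord)
  .exp2_rep_cache[[key]]
}

# small random measure table builder used in several validity tests
random_measure_table <- function(n_subjects, delta = 0, sd_diff = 1,
                                 sd_subj = 1) {
  subs <- sprintf("S%02d", seq_len(n_subjects))
  base <- rnorm(n_subjects, 0, sd_subj)
  diff <- rnorm(n_subjects, delta, sd_diff)
  tibble::tibble(subject = rep(subs, 2),
                 cs = rep(c("CS+", "CS-"), each = n_subjects),
                 value = c(base + diff / 2, base - diff / 2))
}
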