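#' Effect-size configuration for synthetic cohorts
#'
#' Population-level effect structure used by [sample_cohort()]. The PIT
#' effect is an additive CS+ press-rate increment confined by default to
#' Withdraw-Go trials; its size is chosen inside the generator so that the
#' standardized paired CS+/CS- difference in measured response rate equals
#' `pit_d` at the population level (the generator accounts analytically for
#' between-subject effect heterogeneity and for the trial-count-dependent
#' measurement noise of the design it is given).
#'
#' @param pit_d Target paired Cohen's d of the Withdraw-Go CS+ vs CS-
#'   response-rate contrast. Default 0.40, the confirmation-sample value.
#' @param pit_delta_sd Between-subject SD of the individual PIT rate
#'   increment, in presses/s.
#' @param delta_approach_go,delta_approach_nogo,delta_withdraw_nogo CS+
#'   press-rate increments (presses/s) for the remaining conditions;
#'   0 by default.
#' @param baseline_go_rate,go_rate_sd Mean and between-subject SD of the
#'   baseline Go press rate, presses/s.
#' @param nogo_press_rate Lapse press rate on NoGo trials, presses/s.
#' @param latency_meanlog,latency_sdlog Log-normal parameters of the first
#'   press latency (seconds after response onset) on Go trials.
#' @param withdraw_latency_shift Additive latency shift (s) on Withdraw
#'   trials; participants initiate withdrawal slightly later than approach.
#' @param psychophys Per-measure amplitude model, a tibble as returned by
#'   [default_psychophys_effects()].
#' @return An object of class `pit_effects`.
#' @examples
#' cfg <- effect_config(pit_d = 0)   # null PIT effect
#' @export
effect_config <- function(pit_d = 0.40,
                          pit_delta_sd = 0.45,
                          delta_approach_go = 0,
                          delta_approach_nogo = 0,
                          delta_withdraw_nogo = 0,
                          baseline_go_rate = 6.0,
                          go_rate_sd = 0.5,
                          nogo_press_rate = 0.1,
                          latency_meanlog = log(0.35),
                          latency_sdlog = 0.25,
                          withdraw_latency_shift = 0.08,
                          psychophys = default_psychophys_effects()) {
  .assert_scalar_num(pit_d, "pit_d")
  .assert_scalar_num(pit_delta_sd, "pit_delta_sd", lower = 0,
                     strict_lower = TRUE)
  .assert_scalar_num(baseline_go_rate, "baseline_go_rate", lower = 0)
  .assert_scalar_num(go_rate_sd, "go_rate_sd", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(nogo_press_rate, "nogo_press_rate", lower = 0)
  stopifnot(is.data.frame(psychophys),
            all(c("measure", "mean_plus", "mean_minus", "sigma_subject",
                  "sigma_within", "d") %in% names(psychophys)))
  structure(list(pit_d = pit_d, pit_delta_sd = pit_delta_sd,
                 delta_approach_go = delta_approach_go,
                 delta_approach_nogo = delta_approach_nogo,
                 delta_withdraw_nogo = delta_withdraw_nogo,
                 baseline_go_rate = baseline_go_rate,
                 go_rate_sd = go_rate_sd,
                 nogo_press_rate = nogo_press_rate,
                 latency_meanlog = latency_meanlog,
                 latency_sdlog = latency_sdlog,
                 withdraw_latency_shift = withdraw_latency_shift,
                 psychophys = psychophys),
            class = "pit_effects")
}

#' Psychophysiological amplitude model of the synthetic cohort
#'
#' Condition-level amplitude estimates (one per subject per CS level) are
#' drawn from an additive model `amplitude = mean_cs + subject + noise`
#' with `subject ~ N(0, sigma_subject)` shared across CS levels and
#' independent `noise ~ N(0, sigma_within)` per level, so that the paired
#' CS+/CS- difference has SD `sqrt(2) * sigma_within` and standardized size
#' `d`. The default means and variance components are chosen to match the
#' confirmation sample: SCR 0.39 vs 0.30 uS (d = 0.673), pupil 3.16 vs
#' 3.02 mm (d = 0.52), heart period 13.86 vs -15.52 ms (d = 0.78), with
#' per-level SDs recovered from the reported standard errors at n = 35.
#'
#' @param d Named vector of target paired effect sizes for `SCR`, `pupil`
#'   and `heart_period`. Setting an element to 0 keeps that measure's
#'   default noise model but removes the CS separation (both levels get the
#'   midpoint mean).
#' @return A tibble with columns `measure`, `unit`, `mean_plus`,
#'   `mean_minus`, `sigma_subject`, `sigma_within`, `d`.
#' @export
default_psychophys_effects <- function(d = c(SCR = 0.673, pupil = 0.52,
                                             heart_period = 0.78)) {
  base <- tibble(
    measure = c("SCR", "pupil", "heart_period"),
    unit = c("uS", "mm", "ms"),
    mean_plus = c(0.39, 3.16, 13.86),
    mean_minus = c(0.30, 3.02, -15.52),
    sem_plus = c(0.05, 0.08, 6.92),
    sem_minus = c(0.04, 0.07, 3.94),
    d_default = c(0.673, 0.52, 0.78),
    n_ref = 35L)
  if (is.null(names(d)) || !all(base$measure %in% names(d)))
    stop("`d` must be a named vector covering SCR, pupil and heart_period",
         call. = FALSE)
  base$d <- as.numeric(d[base$measure])
  if (any(base$d < 0)) stop("psychophysiological d must be >= 0",
                            call. = FALSE)
  delta0 <- base$mean_plus - base$mean_minus
  # paired-difference SD implied by the requested d (default model when d = 0)
  sd_diff <- ifelse(base$d > 0, delta0 / base$d, delta0 / base$d_default)
  sigma_within <- sd_diff / sqrt(2)
  level_var <- ((base$sem_plus^2 + base$sem_minus^2) / 2) * base$n_ref
  sigma_subject <- sqrt(pmax(level_var - sigma_within^2,
                             (0.1 * sqrt(level_var))^2))
  mid <- (base$mean_plus + base$mean_minus) / 2
  tibble(measure = base$measure, unit = base$unit,
         mean_plus = ifelse(base$d > 0, base$mean_plus, mid),
         mean_minus = ifelse(base$d > 0, base$mean_minus, mid),
         sigma_subject = sigma_subject, sigma_within = sigma_within,
         d = base$d)
}

# Analytic per-trial variance of the measured response rate (presses/s over
# the full response period) for the free-running responder: binomial press
# noise plus latency-induced variation of the effective pressing time.
.rate_trial_var <- function(rate, params, mean_latency, var_latency) {
  T <- params$response_duration
  adj <- T / (T - mean_latency)
  p <- min(rate * adj * params$dt, 1)
  rate * (1 - p) / T + (rate * adj)^2 * var_latency / T^2
}

#' Generate a complete synthetic PIT study dataset
#'
#' Draws a cohort of synthetic subjects, drives the coin-task engine with
#' per-subject free-running responder policies through the instrumental
#' (phase 1) and transfer (phase 3) trial lists of `design`, records the
#' Pavlovian phase-2 trial list, and draws condition-level
#' psychophysiological amplitudes. The Withdraw-Go CS+ press-rate increment
#' is sized so that the downstream response-rate pipeline recovers
#' `effects$pit_d` at the population level; per-subject shock intensities
#' are derived from simulated rating curves via [calibrate_us_intensity()].
#'
#' @param design A [make_design()] object.
#' @param n_subjects Number of subjects; defaults to the study samples
#'   (21 for Experiment 1, 35 for Experiment 2).
#' @param effects An [effect_config()].
#' @param params A [task_params()] object.
#' @param seed Optional integer seed; a given seed yields a byte-identical
#'   dataset.
#' @param phases Which task phases to realize as event logs (subset of
#'   1:3). Psychophysiological amplitudes and subject profiles are always
#'   generated.
#' @return An object of class `pit_cohort`: a list with tibbles `events`
#'   (long format: subject, phase, block, trial_index, frame, go, cs,
#'   event_type in press/outcome, time_s on the response-period clock,
#'   value), `psychophys` (subject, measure, cs, amplitude, unit),
#'   `subjects` (profiles incl. shock current in mA), plus `design`,
#'   `params`, `effects`.
#' @examples
#' coh <- sample_cohort(make_design(2), n_subjects = 4, seed = 1, phases = 3)
#' dplyr::count(coh$events, .data$event_type)
#' @export
sample_cohort <- function(design, n_subjects = NULL,
                          effects = effect_config(),
                          params = task_params(), seed = NULL,
                          phases = 1:3) {
  stopifnot(inherits(design, "pit_design"), inherits(effects, "pit_effects"),
            inherits(params, "pit_task_params"))
  if (!all(phases %in% 1:3)) stop("`phases` must be a subset of 1:3",
                                  call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_subjects <- n_subjects %||% (if (design$experiment == 1) 21L else 35L)
  stopifnot(n_subjects >= 2)
  subj_ids <- sprintf("S%03d", seq_len(n_subjects))
  T <- params$response_duration

  # latency moments (log-normal), per frame
  mu_L <- exp(effects$latency_meanlog + effects$latency_sdlog^2 / 2)
  var_L <- mu_L^2 * (exp(effects$latency_sdlog^2) - 1)
  mu_L_frame <- c(Approach = mu_L,
                  Withdraw = mu_L + effects$withdraw_latency_shift)

  # size the population PIT increment so that the measured Withdraw-Go
  # paired d equals the configured target under this design's trial counts
  wg <- design$phase3$n_trials[design$phase3$frame == "Withdraw" &
                                 design$phase3$go == "Go" &
                                 design$phase3$cs == "CS+"]
  n_wg <- sum(wg)
  v_meas <- .rate_trial_var(effects$baseline_go_rate, params,
                            mu_L_frame[["Withdraw"]], var_L) / n_wg
  sd_diff <- sqrt(effects$pit_delta_sd^2 + 2 * v_meas)
  delta_mean <- effects$pit_d * sd_diff

  subjects <- tibble(
    subject = subj_ids,
    baseline_go_rate = pmin(pmax(rnorm(n_subjects, effects$baseline_go_rate,
                                       effects$go_rate_sd), 1),
                            params$max_press_rate - 1),
    pit_delta = rnorm(n_subjects, delta_mean, effects$pit_delta_sd),
    us_current_mA = vapply(seq_len(n_subjects), function(i) {
      thr <- runif(1, 5, 10)
      cur <- sort(runif(14, 0.15 * thr, thr))
      rating <- pmin(pmax(100 * (cur / thr)^1.2 + rnorm(14, 0, 4), 0), 100)
      calibrate_us_intensity(cur, rating, threshold_current = thr)
    }, numeric(1)))

  sim_phase <- function(phase_no, cond_tbl) {
    has_cs <- "cs" %in% names(cond_tbl)
    per_subj <- lapply(subj_ids, function(sid) {
      rows <- cond_tbl[rep(seq_len(nrow(cond_tbl)), cond_tbl$n_trials), ]
      rows$n_trials <- NULL
      # random order within each block
      ord <- order(rows$block, sample.int(nrow(rows)))
      rows <- rows[ord, ]
      rows$subject <- sid
      rows$trial_index <- seq_len(nrow(rows))
      rows
    })
    trials <- dplyr::bind_rows(per_subj)
    if (!has_cs) trials$cs <- "none"
    prof <- subjects[match(trials$subject, subjects$subject), ]

    is_go <- trials$go == "Go"
    is_withdraw <- trials$frame == "Withdraw"
    # CS+ press-rate increment by condition (PIT effect); the Withdraw-Go
    # increment carries the subject's individual effect size
    delta <- rep(0, nrow(trials))
    plus <- trials$cs == "CS+"
    delta[plus & is_withdraw & is_go] <-
      prof$pit_delta[plus & is_withdraw & is_go]
    delta[plus & !is_withdraw & is_go] <- effects$delta_approach_go
    delta[plus & !is_withdraw & !is_go] <- effects$delta_approach_nogo
    delta[plus & is_withdraw & !is_go] <- effects$delta_withdraw_nogo
    target_rate <- ifelse(is_go, prof$baseline_go_rate + delta,
                          effects$nogo_press_rate + delta)
    target_rate <- pmax(target_rate, 0)
    latency <- ifelse(is_go,
                      rlnorm(nrow(trials), effects$latency_meanlog,
                             effects$latency_sdlog) +
                        ifelse(trials$frame == "Withdraw",
                               effects$withdraw_latency_shift, 0),
                      0)
    # raise the press hazard so the rate measured over the full response
    # period (latency included) matches the target on average
    adj <- ifelse(is_go, T / (T - mu_L_frame[trials$frame]), 1)
    press_rate <- pmin(target_rate * adj, params$max_press_rate)

    # vectorized trial geometry: Approach rewards the machine, Withdraw the
    # dot; Go trials default to the punitive target, NoGo to the desired one
    xg <- ifelse(is_withdraw, params$x_dot, params$x_machine)
    xp <- ifelse(is_withdraw, params$x_machine, params$x_dot)
    xd <- ifelse(is_go, xp, xg)
    x0 <- if (is.null(params$x_start)) xd else rep(params$x_start,
                                                  nrow(trials))
    dir <- as.integer(sign(ifelse(is_go, xg - xd, xp - xd)))
    sim <- .sim_batch(
      data.frame(kind = 2L, rate = press_rate, latency = latency,
                 press_dir = dir, x_start = x0, x_default = xd,
                 x_desired = xg),
      params)
    hw <- params$window_width / 2
    outcome <- ifelse(abs(sim$final_x - xg) <= hw, "win",
                      ifelse(abs(sim$final_x - xp) <= hw, "lose",
                             "incomplete"))
    n_press <- lengths(sim$press_times)
    key <- tibble(subject = trials$subject, phase = phase_no,
                  block = trials$block, trial_index = trials$trial_index,
                  frame = trials$frame, go = trials$go, cs = trials$cs)
    press_rows <- key[rep(seq_len(nrow(key)), n_press), ]
    press_rows$event_type <- "press"
    press_rows$time_s <- unlist(sim$press_times)
    press_rows$value <- NA_character_
    out_rows <- key
    out_rows$event_type <- "outcome"
    out_rows$time_s <- T
    out_rows$value <- outcome
    ev <- dplyr::bind_rows(press_rows, out_rows)
    dplyr::arrange(ev, .data$subject, .data$trial_index, .data$time_s,
                   dplyr::desc(.data$event_type))
  }

  events <- list()
  if (1 %in% phases) events$p1 <- sim_phase(1L, design$phase1)
  if (2 %in% phases) {
    p2 <- dplyr::bind_rows(lapply(subj_ids, function(sid) {
      rows <- design$phase2[rep(seq_len(nrow(design$phase2)),
                                design$phase2$n_trials), ]
      rows <- rows[sample.int(nrow(rows)), ]
      tibble(subject = sid, phase = 2L, block = 1L,
             trial_index = seq_len(nrow(rows)), frame = NA_character_,
             go = NA_character_, cs = rows$cs, event_type = "outcome",
             time_s = design$timing$cs_duration,
             value = ifelse(rows$reinforced, "shock", "none"))
    }))
    events$p2 <- p2
  }
  if (3 %in% phases) events$p3 <- sim_phase(3L, design$phase3)
  events <- dplyr::bind_rows(events)

  pp <- effects$psychophys
  psychophys <- dplyr::bind_rows(lapply(seq_len(nrow(pp)), function(m) {
    u <- rnorm(n_subjects, 0, pp$sigma_subject[m])
    tibble(subject = rep(subj_ids, 2L),
           measure = pp$measure[m],
           cs = rep(c("CS+", "CS-"), each = n_subjects),
           amplitude = c(pp$mean_plus[m] + u +
                           rnorm(n_subjects, 0, pp$sigma_within[m]),
                         pp$mean_minus[m] + u +
                           rnorm(n_subjects, 0, pp$sigma_within[m])),
           unit = pp$unit[m])
  }))
  psychophys <- dplyr::arrange(psychophys, .data$measure, .data$subject,
                               dplyr::desc(.data$cs))

  structure(list(events = events, psychophys = psychophys,
                 subjects = subjects, design = design, params = params,
                 effects = effects),
            class = "pit_cohort")
}

#' @export
print.pit_cohort <- function(x, ...) {
  cat(sprintf("Synthetic PIT cohort: Experiment %d design, %d subjects\n",
              x$design$experiment, nrow(x$subjects)))
  cat(sprintf("  %d events across phases {%s}; %d psychophysiological amplitudes\n",
              nrow(x$events),
              paste(sort(unique(x$events$phase)), collapse = ","),
              nrow(x$psychophys)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `events.csv`, `psychophys.csv`, `subjects.csv` and `design.json`
#' into `dir`. Output is deterministic: the same cohort gives byte-identical
#' files.
#'
#' @param cohort A [sample_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pit_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$events, file.path(dir, "events.csv"))
  readr::write_csv(cohort$psychophys, file.path(dir, "psychophys.csv"))
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  jsonlite::write_json(
    list(experiment = cohort$design$experiment,
         phase1 = cohort$design$phase1, phase2 = cohort$design$phase2,
         phase3 = cohort$design$phase3, timing = cohort$design$timing),
    file.path(dir, "design.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Interpolate the shock intensity used during the task
#'
#' Shock calibration presents a series of perceivable currents below the
#' pain threshold; participants rate each on a 0 (no sensation) to 100
#' (clearly painful) scale. The task current is obtained by piecewise-linear
#' interpolation of current as a function of rating, evaluated at
#' `100 * fraction` (85% of the rating scale by default) and clamped to the
#' tested current range. When the rating series is non-monotone, the first
#' crossing of the target rating from below is used (the conservative,
#' lower-current choice). `interpolate_on = "current"` instead returns
#' `fraction * threshold_current`, the alternative reading of "85% of the
#' threshold".
#'
#' @param current Tested currents in mA (positive, at most
#'   `threshold_current`).
#' @param rating Ratings in \[0, 100\], same length as `current` (>= 2
#'   points).
#' @param threshold_current Upper threshold current in mA.
#' @param fraction Fraction of the scale (or of the threshold current) to
#'   target.
#' @param interpolate_on `"rating"` (default) or `"current"`.
#' @return The interpolated current in mA.
#' @examples
#' calibrate_us_intensity(seq(1, 9, 2), seq(0, 100, 25), 9)  # 7.8
#' @export
calibrate_us_intensity <- function(current, rating, threshold_current,
                                   fraction = 0.85,
                                   interpolate_on = c("rating", "current")) {
  interpolate_on <- match.arg(interpolate_on)
  .assert_scalar_num(threshold_current, "threshold_current", lower = 0,
                     strict_lower = TRUE)
  .assert_scalar_num(fraction, "fraction", lower = 0, upper = 1)
  if (length(current) < 2L || length(current) != length(rating))
    stop("need at least two (current, rating) points of equal length",
         call. = FALSE)
  if (any(!is.finite(current)) || any(current <= 0) ||
      any(current > threshold_current + 1e-9))
    stop("currents must be positive and at most `threshold_current`",
         call. = FALSE)
  if (any(!is.finite(rating)) || any(rating < 0 | rating > 100))
    stop("ratings must lie in [0, 100]", call. = FALSE)
  if (interpolate_on == "current")
    return(fraction * threshold_current)
  ord <- order(current)
  current <- current[ord]; rating <- rating[ord]
  target <- 100 * fraction
  if (rating[1L] >= target) return(current[1L])
  for (i in seq_len(length(current) - 1L)) {
    r0 <- rating[i]; r1 <- rating[i + 1L]
    if (r0 < target && r1 >= target) {
      w <- (target - r0) / (r1 - r0)
      return(current[i] + w * (current[i + 1L] - current[i]))
    }
  }
  current[length(current)]  # never crossed: top of the tested range
}
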