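#' Behavioral dependent variables of a single trial
#'
#' `response_rate()` is the number of key presses per second averaged over
#' the entire response period; `first_press_latency()` is the time of the
#' first press on the response-period clock (the 1-s preview, during which
#' no presses are possible, is not part of this clock), `NA` when no press
#' occurred; `accuracy()` is the proportion of trials whose coin reached
#' the required target (losses and incomplete trials both count as
#' not-correct).
#'
#' @param trial A `pit_trial` log from [simulate_trial()].
#' @return `response_rate()`: presses/s; `first_press_latency()`: seconds
#'   or `NA`.
#' @examples
#' tr <- simulate_trial(trial_spec("Approach", "Go"), seed = 2)
#' response_rate(tr)
#' @export
response_rate <- function(trial) {
  stopifnot(inherits(trial, "pit_trial"))
  trial$n_presses / trial$response_duration
}

#' @rdname response_rate
#' @export
first_press_latency <- function(trial) {
  stopifnot(inherits(trial, "pit_trial"))
  trial$first_press_latency
}

#' @rdname response_rate
#' @param trials A list of `pit_trial` logs, or a character vector of
#'   outcomes (`"win"`/`"lose"`/`"incomplete"`).
#' @export
accuracy <- function(trials) {
  outcomes <- if (is.character(trials)) trials
              else vapply(trials, function(t) {
                stopifnot(inherits(t, "pit_trial")); t$outcome
              }, character(1))
  if (length(outcomes) == 0L) stop("empty condition cell", call. = FALSE)
  if (!all(outcomes %in% c("win", "lose", "incomplete")))
    stop("unknown outcome value", call. = FALSE)
  mean(outcomes == "win")
}

#' Per-subject condition summaries from an event log
#'
#' Aggregates a long-format event log into one row per subject and
#' condition cell: mean response rate (equivalently total presses over
#' total time, since all trials share the response duration), response
#' accuracy, mean first-press latency and the trial count. Latency follows
#' the measure's availability rules: on NoGo cells it is computed only from
#' incorrect trials, and it is `NA` for cells without any qualifying press.
#'
#' @param events Event tibble as produced by [sample_cohort()] (columns
#'   subject, phase, block, trial_index, frame, go, cs, event_type,
#'   time_s, value).
#' @param phase Task phase to summarize (1 or 3).
#' @param by Condition columns defining the cells, a subset of
#'   `c("cs", "frame", "go", "block")`.
#' @param response_duration Response-period length in seconds.
#' @return A tibble with one row per subject x cell: the `by` columns plus
#'   `n_trials`, `response_rate`, `accuracy`, `latency`. Cells missing for
#'   some subject (possible in externally supplied logs) trigger a warning
#'   and are kept as explicit `NA` rows.
#' @examples
#' coh <- sample_cohort(make_design(1), n_subjects = 3, seed = 1, phases = 3)
#' summarize_conditions(coh$events, phase = 3)
#' @export
summarize_conditions <- function(events, phase = 3,
                                 by = c("cs", "frame", "go"),
                                 response_duration = 5) {
  stopifnot(is.data.frame(events),
            all(c("subject", "phase", "trial_index", "event_type",
                  "time_s") %in% names(events)))
  if (!all(by %in% c("cs", "frame", "go", "block")))
    stop("`by` must be a subset of cs, frame, go, block", call. = FALSE)
  ev <- dplyr::filter(events, .data$phase == !!phase)
  if (nrow(ev) == 0L) stop("no events for phase ", phase, call. = FALSE)

  keys <- c("subject", "block", "trial_index", "frame", "go", "cs")
  presses <- dplyr::filter(ev, .data$event_type == "press")
  per_press <- dplyr::summarise(
    dplyr::group_by(presses, dplyr::across(dplyr::all_of(keys))),
    n_presses = dplyr::n(), first_press = min(.data$time_s),
    .groups = "drop")
  outcomes <- dplyr::select(
    dplyr::filter(ev, .data$event_type == "outcome"),
    dplyr::all_of(keys), outcome = "value")
  trials <- dplyr::left_join(outcomes, per_press, by = keys)
  trials$n_presses[is.na(trials$n_presses)] <- 0L
  trials$rate <- trials$n_presses / response_duration
  trials$correct <- trials$outcome == "win"
  # latency availability: NoGo only on incorrect trials
  trials$lat <- ifelse(trials$go == "NoGo" & trials$correct,
                       NA_real_, trials$first_press)

  grp <- c("subject", by)
  out <- dplyr::summarise(
    dplyr::group_by(trials, dplyr::across(dplyr::all_of(grp))),
    n_trials = dplyr::n(),
    response_rate = mean(.data$rate),
    accuracy = mean(.data$correct),
    latency = if (all(is.na(.data$lat))) NA_real_
              else mean(.data$lat, na.rm = TRUE),
    .groups = "drop")

  # flag (and keep as NA rows) any subject x cell combination with no trial
  full <- do.call(.grid_tbl, c(list(subject = unique(trials$subject)),
                               lapply(setNames(by, by),
                                      function(b) unique(trials[[b]]))))
  out <- dplyr::left_join(full, out, by = grp)
  if (any(is.na(out$n_trials)))
    warning("some subject x condition cells contain no trials",
            call. = FALSE)
  dplyr::arrange(out, dplyr::across(dplyr::all_of(grp)))
}

#' Extract the behavioral PIT measure (Withdraw-Go response rate)
#'
#' Returns the per-subject, per-CS response-rate table of Withdraw-Go
#' trials -- the behavioral threat-learning measure whose predictive
#' validity is compared against psychophysiological readouts.
#'
#' @param summary A [summarize_conditions()] result containing `cs`,
#'   `frame`, `go` columns.
#' @param blocks Optional block subset (requires `block` in the summary's
#'   grouping); e.g. `1` for a block-1-only measure.
#' @return A tibble with columns `subject`, `cs`, `value`.
#' @export
pit_measure_table <- function(summary, blocks = NULL) {
  stopifnot(all(c("subject", "cs", "frame", "go", "response_rate") %in%
                  names(summary)))
  tbl <- dplyr::filter(summary, .data$frame == "Withdraw", .data$go == "Go",
                       .data$cs %in% c("CS+", "CS-"))
  if (!is.null(blocks)) {
    if (!"block" %in% names(tbl))
      stop("summary has no `block` column; summarize with by = ",
           "c('cs','frame','go','block')", call. = FALSE)
    tbl <- dplyr::filter(tbl, .data$block %in% blocks)
  }
  out <- dplyr::summarise(dplyr::group_by(tbl, .data$subject, .data$cs),
                          value = mean(.data$response_rate),
                          .groups = "drop")
  dplyr::arrange(out, .data$subject, dplyr::desc(.data$cs))
}

#' Per-measure subject x CS tables of a synthetic cohort
#'
#' Convenience accessor assembling the behavioral PIT measure (from the
#' phase-3 event log) and each psychophysiological measure into the common
#' `(subject, cs, value)` format consumed by [compare_measures()].
#'
#' @param cohort A [sample_cohort()] result (phase 3 must be present).
#' @return A named list of tibbles, first element `PIT`.
#' @export
measure_tables <- function(cohort) {
  stopifnot(inherits(cohort, "pit_cohort"))
  summ <- summarize_conditions(cohort$events, phase = 3)
  tabs <- list(PIT = pit_measure_table(summ))
  for (m in unique(cohort$psychophys$measure)) {
    tm <- dplyr::filter(cohort$psychophys, .data$measure == m)
    tabs[[m]] <- dplyr::arrange(
      tibble(subject = tm$subject, cs = tm$cs, value = tm$amplitude),
      .data$subject, dplyr::desc(.data$cs))
  }
  tabs
}
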