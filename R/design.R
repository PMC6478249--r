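#' Trial-count design of the two experiments
#'
#' Returns the exact within-subject trial structure of the three task
#' phases. Both experiments use a 2 (Approach/Withdraw) x 2 (Go/NoGo)
#' instrumental design with 64 trials per phase:
#'
#' * Phase 1 (instrumental training), Experiment 1: 16 trials of each of
#'   the four conditions, analyzed as two blocks of 8. Experiment 2: four
#'   balanced blocks with the Go share raised to 75% (6 Go and 2 NoGo
#'   trials per frame per block).
#' * Phase 2 (Pavlovian conditioning): 32 CS+ (16 of them reinforced with
#'   the shock) and 32 CS-.
#' * Phase 3 (transfer), Experiment 1: 8 trials of each of the eight
#'   cs x frame x go types. Experiment 2: two blocks of 6 trials per Go
#'   type and 2 per NoGo type (32 trials per block).
#'
#' @param experiment 1 or 2.
#' @return An object of class `pit_design`: a list with tibbles `phase1`,
#'   `phase2`, `phase3` (columns `block`, `frame`, `go`, `cs`/`reinforced`,
#'   `n_trials`) plus a `timing` list of experiment-specific constants.
#' @examples
#' sum(make_design(1)$phase3$n_trials)  # 64
#' @export
make_design <- function(experiment = 2) {
  if (!experiment %in% c(1, 2)) stop("`experiment` must be 1 or 2",
                                     call. = FALSE)
  frames <- c("Approach", "Withdraw")
  gos <- c("Go", "NoGo")
  css <- c("CS+", "CS-")
  if (experiment == 1) {
    phase1 <- .grid_tbl(block = 1:2, frame = frames, go = gos)
    phase1$n_trials <- 8L
    phase3 <- .grid_tbl(block = 1L, cs = css, frame = frames, go = gos)
    phase3$n_trials <- 8L
    timing <- list(iti_task = 2.5, iti_pavlovian = c(2.5, 2.5),
                   cs_duration = 3.5, us_onset = 3.0)
  } else {
    phase1 <- .grid_tbl(block = 1:4, frame = frames, go = gos)
    phase1$n_trials <- ifelse(phase1$go == "Go", 6L, 2L)
    phase3 <- .grid_tbl(block = 1:2, cs = css, frame = frames, go = gos)
    phase3$n_trials <- ifelse(phase3$go == "Go", 6L, 2L)
    timing <- list(iti_task = 1.5, iti_pavlovian = c(7, 11),
                   cs_duration = 4.0, us_onset = 3.5)
  }
  phase2 <- tibble(cs = c("CS+", "CS+", "CS-"),
                   reinforced = c(TRUE, FALSE, FALSE),
                   n_trials = c(16L, 16L, 32L))
  timing$preview <- 1
  timing$response <- 5
  timing$us_duration <- 0.5
  timing$counterbalanced <- c("CS colors", "machine colors",
                              "Pavlovian key mapping")
  structure(list(experiment = as.integer(experiment), phase1 = phase1,
                 phase2 = phase2, phase3 = phase3, timing = timing),
            class = "pit_design")
}

# expand.grid with the first column varying slowest, returned as a tibble
# (stringsAsFactors-free); local helper so the design tables read naturally.
.grid_tbl <- function(...) {
  args <- list(...)
  g <- rev(do.call(expand.grid,
                   c(rev(args), list(stringsAsFactors = FALSE,
                                     KEEP.OUT.ATTRS = FALSE))))
  as_tibble(g)
}

#' @export
print.pit_design <- function(x, ...) {
  cat(sprintf("PIT design, Experiment %d\n", x$experiment))
  cat(sprintf("  phase 1: %d trials in %d block(s)\n",
              sum(x$phase1$n_trials), max(x$phase1$block)))
  cat(sprintf("  phase 2: %d CS+ (%d reinforced), %d CS-\n",
              sum(x$phase2$n_trials[x$phase2$cs == "CS+"]),
              sum(x$phase2$n_trials[x$phase2$reinforced]),
              sum(x$phase2$n_trials[x$phase2$cs == "CS-"])))
  cat(sprintf("  phase 3: %d trials in %d block(s)\n",
              sum(x$phase3$n_trials), max(x$phase3$block)))
  invisible(x)
}
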