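test_that("design tables reproduce both experiments' trial structure", {
  d1 <- make_design(1)
  expect_equal(sum(d1$phase1$n_trials), 64)
  agg1 <- tapply(d1$phase1$n_trials, d1$phase1[c("frame", "go")], sum)
  expect_true(all(agg1 == 16))
  expect_equal(sum(d1$phase2$n_trials), 64)
  expect_equal(sum(d1$phase2$n_trials[d1$phase2$cs == "CS+"]), 32)
  expect_equal(sum(d1$phase2$n_trials[d1$phase2$reinforced]), 16)
  expect_equal(sum(d1$phase3$n_trials), 64)
  expect_true(all(d1$phase3$n_trials == 8))
  expect_equal(nrow(d1$phase3), 8)  # eight trial types

  d2 <- make_design(2)
  expect_equal(sum(d2$phase1$n_trials), 64)
  per_block1 <- tapply(d2$phase1$n_trials, d2$phase1$block, sum)
  expect_true(all(per_block1 == 16))
  expect_equal(sum(d2$phase3$n_trials), 64)
  per_block3 <- tapply(d2$phase3$n_trials, d2$phase3$block, sum)
  expect_true(all(per_block3 == 32))
  go_n <- sum(d2$phase3$n_trials[d2$phase3$go == "Go"])
  nogo_n <- sum(d2$phase3$n_trials[d2$phase3$go == "NoGo"])
  expect_equal(go_n / nogo_n, 3)  # Go:NoGo = 3:1
  expect_true(all(d2$phase3$n_trials[d2$phase3$go == "Go"] == 6))
  expect_true(all(d2$phase3$n_trials[d2$phase3$go == "NoGo"] == 2))
  expect_error(make_design(3), "1 or 2")
})

test_that("generated cohorts realize the design exactly, in permuted order", {
  for (exp_no in 1:2) {
    des <- make_design(exp_no)
    coh <- sample_cohort(des, n_subjects = 3, seed = 21, phases = c(1, 3))
    trials <- dplyr::distinct(
      dplyr::filter(coh$events, event_type == "outcome"),
      subject, phase, block, trial_index,
      frame, go, cs)
    for (sid in unique(trials$subject)) {
      p3 <- dplyr::filter(trials, subject == sid, phase == 3)
      # trial indices are a permutation of 1..64
      expect_identical(sort(p3$trial_index), 1:64)
      counts <- dplyr::count(p3, block, cs, frame, go)
      ref <- des$phase3[order(des$phase3$block, des$phase3$cs,
                              des$phase3$frame, des$phase3$go), ]
      counts <- counts[order(counts$block, counts$cs, counts$frame,
                             counts$go), ]
      expect_equal(counts$n, ref$n_trials)
    }
  }
})

test_that("a fixed seed yields byte-identical datasets on disk", {
  des <- make_design(2)
  a <- sample_cohort(des, n_subjects = 4, seed = 77, phases = 3)
  b <- sample_cohort(des, n_subjects = 4, seed = 77, phases = 3)
  expect_identical(a$events, b$events)
  expect_identical(a$psychophys, b$psychophys)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in c("events.csv", "psychophys.csv", "subjects.csv", "design.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})

test_that("shock-intensity interpolation follows the rating scale", {
  # linear ratings from 0 at 1 mA to 100 at 9 mA: 85% of scale -> 7.8 mA
  expect_equal(calibrate_us_intensity(seq(1, 9, 2), seq(0, 100, 25), 9), 7.8)
  # the full scale maps to the top of the tested range
  expect_equal(calibrate_us_intensity(seq(1, 9, 2), seq(0, 100, 25), 9,
                                      fraction = 1), 9)
  # two-segment curve against the dense-grid oracle
  cur <- c(1, 5, 9); rat <- c(0, 40, 100)
  expect_equal(calibrate_us_intensity(cur, rat, 9),
               oracle_us_current(cur, rat, 85), tolerance = 1e-3)
  # non-monotone ratings: first crossing from below (conservative current)
  cur2 <- c(1, 3, 5, 7); rat2 <- c(0, 90, 40, 95)
  got <- calibrate_us_intensity(cur2, rat2, 7)
  expect_equal(got, oracle_us_current(cur2, rat2, 85), tolerance = 1e-3)
  expect_lt(got, 3)  # crossing in the first segment, not the last
  # alternative reading: 85% of the threshold current itself
  expect_equal(calibrate_us_intensity(cur, rat, 10,
                                      interpolate_on = "current"), 8.5)
  expect_error(calibrate_us_intensity(1, 50, 9), "two")
  expect_error(calibrate_us_intensity(c(1, 2), c(-5, 50), 9), "0, 100")
  expect_error(calibrate_us_intensity(c(1, 12), c(0, 50), 9), "at most")
})

test_that("psychophysiological amplitudes match configured means and d", {
  des <- make_design(2)
  coh <- sample_cohort(des, n_subjects = 400, seed = 31, phases = NULL)
  pp <- coh$psychophys
  # exactly one amplitude per subject x measure x CS level
  expect_equal(nrow(pp), 400 * 3 * 2)
  expect_equal(max(table(pp$subject, pp$measure, pp$cs)), 1)
  scr_plus <- pp$amplitude[pp$measure == "SCR" & pp$cs == "CS+"]
  scr_minus <- pp$amplitude[pp$measure == "SCR" & pp$cs == "CS-"]
  expect_lt(abs(mean(scr_plus) - 0.39), 0.05)
  expect_lt(abs(mean(scr_minus) - 0.30), 0.05)
  targets <- c(SCR = 0.673, pupil = 0.52, heart_period = 0.78)
  for (m in names(targets)) {
    plus <- pp$amplitude[pp$measure == m & pp$cs == "CS+"]
    minus <- pp$amplitude[pp$measure == m & pp$cs == "CS-"]
    # three standard errors of a paired-d estimate at n = 400
    se_d <- sqrt(1 / 400 + targets[[m]]^2 / (2 * 400))
    expect_lt(abs(paired_t(plus, minus)$cohens_d - targets[[m]]), 3 * se_d)
  }
})

test_that("a null configuration produces no CS separation anywhere", {
  des <- make_design(2)
  null_cfg <- effect_config(
    pit_d = 0,
    psychophys = default_psychophys_effects(d = c(SCR = 0, pupil = 0,
                                                  heart_period = 0)))
  coh <- sample_cohort(des, n_subjects = 400, seed = 41, phases = NULL)
  coh0 <- sample_cohort(des, n_subjects = 400, effects = null_cfg,
                        seed = 41, phases = NULL)
  pp <- coh0$psychophys
  for (m in unique(pp$measure)) {
    dif <- pp$amplitude[pp$measure == m & pp$cs == "CS+"] -
           pp$amplitude[pp$measure == m & pp$cs == "CS-"]
    expect_lt(abs(mean(dif)) / (sd(dif) / sqrt(length(dif))), 4)
  }
  expect_equal(mean(coh0$subjects$pit_delta), 0, tolerance = 0.1)
})

test_that("the configured Withdraw-Go effect is recovered as cohorts grow", {
  des <- make_design(2)
  set.seed(500)
  dhat <- replicate(12, {
    coh <- sample_cohort(des, n_subjects = 200, phases = 3)
    tab <- pit_measure_table(summarize_conditions(coh$events, phase = 3))
    paired_t(tab$value[tab$cs == "CS+"],
             tab$value[tab$cs == "CS-"])$cohens_d
  })
  expect_lt(abs(mean(dhat) - 0.40), 0.05)
})

test_that("invalid effect configurations are rejected", {
  expect_error(default_psychophys_effects(d = c(SCR = -1, pupil = 0.5,
                                                heart_period = 0.7)),
               ">= 0")
  expect_error(default_psychophys_effects(d = c(foo = 1)), "named")
  expect_error(effect_config(pit_delta_sd = 0), "range")
  expect_error(sample_cohort(make_design(1), phases = 5), "subset")
})
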