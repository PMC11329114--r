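test_that("sleep scoring applies the 5-minute inactivity threshold", {
  # 4-minute zero run: no sleep
  s4 <- make_series(c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1))
  expect_equal(nrow(detect_sleep_bouts(s4)), 0L)

  # runs of 5 and 6 inactive minutes: two bouts, 11 sleep minutes
  s <- make_series(c(1, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 1))
  bouts <- detect_sleep_bouts(s)
  expect_equal(bouts$duration, c(5L, 6L))
  expect_equal(bouts$start_minute, c(2L, 8L))
  expect_equal(sum(bouts$duration), 11L)

  # degenerate maximal run: a fully inactive day is one 1440-min bout
  s0 <- make_series(rep(0, 1440))
  b0 <- detect_sleep_bouts(s0)
  expect_equal(b0$duration, 1440L)

  expect_error(detect_sleep_bouts(s, threshold_minutes = 0), "integer")
})

test_that("bout detection matches a run-length-encoding oracle", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(30:200, 1)
    counts <- rbinom(n, 1, runif(1, 0.2, 0.8))
    got <- detect_sleep_bouts(make_series(counts))
    want <- rle_bout_oracle(counts)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_minute, want$start)
      expect_equal(got$duration, want$duration)
    }
  }
})

test_that("raising the sleep threshold never increases sleep or bouts", {
  set.seed(7)
  for (i in 1:25) {
    counts <- rbinom(500, 1, 0.4)
    s <- make_series(counts)
    prev_sleep <- Inf
    prev_bouts <- Inf
    for (thr in c(5L, 8L, 12L, 20L)) {
      b <- detect_sleep_bouts(s, thr)
      expect_lte(sum(b$duration), prev_sleep)
      expect_lte(nrow(b), prev_bouts)
      prev_sleep <- sum(b$duration)
      prev_bouts <- nrow(b)
    }
  }
})

test_that("bouts crossing lights-off are split, conserving sleep minutes", {
  # 20-min bout spanning ZT11:50 to ZT12:10
  counts <- rep(1L, 1440)
  counts[(11 * 60 + 51):(12 * 60 + 10)] <- 0L
  cells <- attribute_bouts_to_phase(make_series(counts))
  daycell <- dplyr::filter(cells, phase == "day")
  nightcell <- dplyr::filter(cells, phase == "night")
  expect_equal(daycell$sleep_minutes, 10L)
  expect_equal(nightcell$sleep_minutes, 10L)
  expect_equal(daycell$bout_count, 1L)
  expect_equal(nightcell$bout_count, 1L)

  # onset attribution sends the whole bout to the phase where it started
  cells_on <- attribute_bouts_to_phase(make_series(counts), boundary = "onset")
  expect_equal(dplyr::filter(cells_on, phase == "day")$sleep_minutes, 20L)
  expect_equal(dplyr::filter(cells_on, phase == "night")$sleep_minutes, 0L)

  # all bouts strictly inside the night
  counts2 <- rep(1L, 1440)
  counts2[(13 * 60 + 1):(13 * 60 + 30)] <- 0L
  counts2[(20 * 60 + 1):(20 * 60 + 10)] <- 0L
  cells2 <- attribute_bouts_to_phase(make_series(counts2))
  expect_equal(dplyr::filter(cells2, phase == "day")$sleep_minutes, 0L)
  expect_equal(dplyr::filter(cells2, phase == "night")$sleep_minutes, 40L)
  expect_equal(dplyr::filter(cells2, phase == "night")$bout_count, 2L)
})

test_that("phase attribution conserves totals on random traces", {
  set.seed(11)
  for (i in 1:20) {
    counts <- rbinom(2880, 1, 0.5)
    s <- make_series(counts)
    cells <- attribute_bouts_to_phase(s)
    bouts <- detect_sleep_bouts(s)
    expect_equal(sum(cells$sleep_minutes), sum(bouts$duration))
    # brute-force per-minute phase tally of sleep-labelled minutes
    lab <- label_sleep_minutes(s)
    tally <- tapply(lab$asleep, list(lab$day, lab$phase), sum)
    for (d in unique(cells$day)) {
      for (ph in c("day", "night")) {
        got <- dplyr::filter(cells, day == d, phase == ph)$sleep_minutes
        expect_equal(got, unname(tally[as.character(d), ph]))
      }
    }
  }
})

test_that("activity totals decompose into day and night", {
  s <- make_series(rep(1L, 1440))
  tot <- phase_activity_totals(s)
  expect_equal(tot$activity_day, 720L)
  expect_equal(tot$activity_night, 720L)
  expect_equal(tot$activity_total, 1440L)

  s0 <- make_series(rep(0L, 1440))
  tot0 <- phase_activity_totals(s0)
  expect_equal(tot0$activity_total, 0L)

  set.seed(3)
  counts <- rpois(2880, 2)
  s2 <- make_series(counts)
  tot2 <- phase_activity_totals(s2)
  expect_equal(sum(tot2$activity_total), sum(counts))
  expect_equal(tot2$activity_day + tot2$activity_night, tot2$activity_total)
  # day 1 day-phase brute force
  expect_equal(tot2$activity_day[1], sum(counts[1:720]))
})

test_that("anticipation index follows its windowed ratio definition", {
  # flat profile: AI = 3/6 = 0.5 at both transitions
  s <- make_series(rep(2L, 1440))
  ai <- anticipation_index(s)
  expect_equal(ai$anticipation_morning, 0.5)
  expect_equal(ai$anticipation_evening, 0.5)

  # all pre-transition activity inside the final 3 h: AI = 1
  counts <- rep(0L, 1440)
  counts[(9 * 60 + 1):(12 * 60)] <- 5L   # ZT9-12
  counts[(21 * 60 + 1):(24 * 60)] <- 5L  # ZT21-24
  ai1 <- anticipation_index(make_series(counts))
  expect_equal(ai1$anticipation_morning, 1)
  expect_equal(ai1$anticipation_evening, 1)

  # linear ramp from 0 over the 6-h window: discrete arithmetic-series oracle
  counts2 <- rep(0L, 1440)
  ramp <- 0:359
  counts2[(6 * 60 + 1):(12 * 60)] <- ramp
  counts2[(18 * 60 + 1):(24 * 60)] <- ramp
  expected <- sum(ramp[181:360]) / sum(ramp)
  ai2 <- anticipation_index(make_series(counts2))
  expect_equal(ai2$anticipation_evening, expected)
  expect_equal(ai2$anticipation_morning, expected)
  expect_equal(round(expected, 2), 0.75)

  # zero denominator: undefined, propagated as NA
  ai0 <- anticipation_index(make_series(rep(0L, 1440)))
  expect_true(is.na(ai0$anticipation_morning))
  expect_true(is.na(ai0$anticipation_evening))

  # windows must fit the phase preceding the transition
  expect_error(
    anticipation_index(s, ai_windows(3, 14)),
    "must fit"
  )
})

test_that("the viability rule excludes flies at the stated boundary", {
  # 2 counts in the final 180 min: dead
  counts <- rep(1L, 2880)
  counts[2701:2880] <- 0L
  counts[c(2750, 2800)] <- 1L
  expect_false(viability_filter(make_series(counts))$alive)

  # exactly 3 counts: alive
  counts[2820] <- 1L
  expect_true(viability_filter(make_series(counts))$alive)

  # fully inactive trace: dead
  expect_false(viability_filter(make_series(rep(0L, 2880)))$alive)
})

test_that("per-day averaging omits undefined days", {
  expect_equal(per_day_mean(c(600, 700)), 650)
  expect_equal(per_day_mean(5), 5)
  expect_equal(per_day_mean(c(3, NA)), 3)
  expect_true(is.na(per_day_mean(c(NA_real_, NA_real_))))
  expect_error(per_day_mean(numeric(0)), "at least one")
})

test_that("binned traces have the right geometry and values", {
  # one fly, constant 2 counts/min: every 30-min activity bin is 60
  s <- make_series(rep(2L, 1440))
  expect_warning(bt <- bin_trace(s), "Single fly")
  expect_equal(nrow(bt), 48L)
  expect_true(all(bt$mean == 60))
  expect_true(all(bt$sem == 0))

  # fully asleep fly: every sleep bin is at the 30-min ceiling
  s0 <- make_series(rep(0L, 1440))
  expect_warning(bt0 <- bin_trace(s0, value = "sleep"), "Single fly")
  expect_true(all(bt0$mean == 30))

  # population SEM across two flies
  pop <- make_population(list(rep(2L, 1440), rep(4L, 1440)))
  btp <- bin_trace(pop)
  expect_equal(unique(btp$n_flies), 2L)
  expect_true(all(abs(btp$mean - 90) < 1e-12))
  expect_true(all(abs(btp$sem - sd(c(60, 120)) / sqrt(2)) < 1e-12))

  expect_error(bin_trace(s, bin_minutes = 37), "divide 1440")
})

test_that("the full metric table satisfies its conservation invariants", {
  set.seed(99)
  pop <- make_population(list(rbinom(2880, 3, 0.3), rbinom(2880, 3, 0.4)))
  m <- compute_fly_metrics(pop)
  wide <- tidyr::pivot_wider(m, names_from = "phase", values_from = "value", names_prefix = "p_")
  for (meas in c("activity", "sleep")) {
    d <- dplyr::filter(wide, measure == meas)
    expect_equal(d$p_day + d$p_night, d$p_total)
  }
  # phase bout tallies can only exceed the distinct-bout total via splits
  bn <- dplyr::filter(wide, measure == "bout_number")
  expect_true(all(bn$p_day + bn$p_night >= bn$p_total))
  ai <- dplyr::filter(m, measure == "anticipation")
  expect_true(all(is.na(ai$value) | (ai$value >= 0 & ai$value <= 1)))
  sl <- dplyr::filter(wide, measure == "sleep")
  expect_true(all(sl$p_day <= 720 & sl$p_night <= 720))

  avg <- average_days(m)
  expect_false("day" %in% names(avg))
  one <- dplyr::filter(m, tube == 1, measure == "sleep", phase == "total")
  expect_equal(
    dplyr::filter(avg, tube == 1, measure == "sleep", phase == "total")$value,
    mean(one$value)
  )
})

test_that("degenerate flies produce the expected metric limits", {
  # fully asleep: no activity, all sleep, one bout per day of 1440 min
  m0 <- compute_fly_metrics(make_series(rep(0L, 1440)))
  w0 <- tidyr::pivot_wider(m0, names_from = "phase", values_from = "value", names_prefix = "p_")
  expect_equal(dplyr::filter(w0, measure == "activity")$p_total, 0)
  expect_equal(dplyr::filter(w0, measure == "sleep")$p_total, 1440)
  expect_equal(dplyr::filter(w0, measure == "bout_number")$p_total, 1)
  expect_equal(dplyr::filter(w0, measure == "bout_length")$p_total, 1440)
  expect_true(is.na(dplyr::filter(w0, measure == "anticipation")$p_morning))

  # fully awake at constant rate: no sleep, undefined bout length, AI 0.5
  m1 <- compute_fly_metrics(make_series(rep(3L, 1440)))
  w1 <- tidyr::pivot_wider(m1, names_from = "phase", values_from = "value", names_prefix = "p_")
  expect_equal(dplyr::filter(w1, measure == "sleep")$p_total, 0)
  expect_equal(dplyr::filter(w1, measure == "bout_number")$p_total, 0)
  expect_true(is.na(dplyr::filter(w1, measure == "bout_length")$p_total))
  expect_equal(dplyr::filter(w1, measure == "anticipation")$p_morning, 0.5)
})
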