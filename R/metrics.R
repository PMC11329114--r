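#' Day, night and total activity counts per recording day
#'
#' @inheritParams detect_sleep_bouts
#' @return A tibble with the fly identifier columns plus `day`,
#'   `activity_day`, `activity_night`, `activity_total`.
#' @export
phase_activity_totals <- function(series) {
  ids <- fly_id_cols(series)
  wide <- series |>
    group_by(across(all_of(c(ids, "day", "phase")))) |>
    summarise(counts = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "phase", values_from = "counts",
      names_prefix = "activity_", values_fill = 0L
    )
  for (col in c("activity_day", "activity_night")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  mutate(wide, activity_total = .data$activity_day + .data$activity_night)
}

#' Anticipation-index window definition
#'
#' The anticipation index quantifies the clock-driven build-up of activity
#' before a light transition as the ratio of activity in the final
#' `numerator_hours` before the transition to activity in the final
#' `denominator_hours` before it (3 h over 6 h by default, following the
#' published convention). A flat activity profile therefore gives
#' `numerator_hours / denominator_hours`; values approach 1 as activity
#' concentrates just before the transition.
#'
#' @param numerator_hours Hours immediately before the transition counted in
#'   the numerator (default 3).
#' @param denominator_hours Hours immediately before the transition counted
#'   in the denominator (default 6). Must exceed `numerator_hours` and fit
#'   inside the phase preceding the transition.
#' @return An `ai_windows` object.
#' @export
ai_windows <- function(numerator_hours = 3, denominator_hours = 6) {
  assert_number(numerator_hours, "numerator_hours", lower = 1e-9)
  assert_number(denominator_hours, "denominator_hours", lower = 1e-9)
  if (numerator_hours >= denominator_hours) {
    abort("`numerator_hours` must be strictly less than `denominator_hours`.")
  }
  structure(
    list(numerator_hours = numerator_hours,
         denominator_hours = denominator_hours),
    class = "ai_windows"
  )
}

#' Morning and evening anticipation indices per recording day
#'
#' Morning (dawn) anticipation is computed over the window preceding
#' lights-on, i.e. the end of the night (ZT `24 - denominator` to 24 within
#' each recording day); evening (dusk) anticipation over the window
#' preceding lights-off (ZT `photoperiod - denominator` to `photoperiod`).
#' Each index is the activity in the final `numerator_hours` divided by the
#' activity in the final `denominator_hours`. Days whose denominator
#' activity is zero yield `NA` (undefined, never zero).
#'
#' @inheritParams detect_sleep_bouts
#' @param windows An [ai_windows()] definition.
#' @return A tibble with the fly identifier columns plus `day`,
#'   `anticipation_morning`, `anticipation_evening`.
#' @export
anticipation_index <- function(series, windows = ai_windows()) {
  if (!inherits(windows, "ai_windows")) {
    abort("`windows` must be an ai_windows object.")
  }
  schedule <- attr(series, "schedule") %||% light_schedule()
  cyc <- schedule$cycle_hours
  photo <- schedule$photoperiod_hours
  den <- windows$denominator_hours
  num <- windows$numerator_hours
  if (den > photo || den > cyc - photo) {
    abort("Denominator window must fit inside the phase preceding each transition.")
  }
  ids <- fly_id_cols(series)
  one_index <- function(transition_zt) {
    lo <- transition_zt - den
    hi_num <- transition_zt - num
    series |>
      filter(.data$zt >= lo - 1e-9, .data$zt < transition_zt - 1e-9) |>
      group_by(across(all_of(c(ids, "day")))) |>
      summarise(
        den_sum = sum(.data$count),
        num_sum = sum(.data$count[.data$zt >= hi_num - 1e-9]),
        ai = ifelse(.data$den_sum > 0, .data$num_sum / .data$den_sum, NA_real_),
        .groups = "drop"
      ) |>
      select(all_of(c(ids, "day")), "ai")
  }
  morning <- dplyr::rename(one_index(cyc), anticipation_morning = "ai")
  evening <- dplyr::rename(one_index(photo), anticipation_evening = "ai")
  left_join(morning, evening, by = c(ids, "day"))
}

#' Flag flies that died during the recording
#'
#' A fly is scored dead when it shows fewer than `min_counts` activity
#' counts over the final `tail_minutes` of the analysed window (defaults: 3
#' counts over 180 minutes). Dead flies are excluded from all metric tables.
#'
#' @inheritParams detect_sleep_bouts
#' @param min_counts Minimum tail activity for a fly to count as alive.
#' @param tail_minutes Length of the terminal window inspected.
#' @return A tibble with the fly identifier columns plus `tail_counts` and
#'   logical `alive` (`TRUE` iff `tail_counts >= min_counts`).
#' @export
viability_filter <- function(series, min_counts = 3L, tail_minutes = 180L) {
  min_counts <- assert_count(min_counts, "min_counts", lower = 0L)
  tail_minutes <- assert_count(tail_minutes, "tail_minutes")
  ids <- fly_id_cols(series)
  last_minute <- max(series$minute)
  if (last_minute < tail_minutes) {
    abort("Analysis window is shorter than `tail_minutes`.")
  }
  series |>
    group_by(across(all_of(ids))) |>
    summarise(
      tail_counts = sum(.data$count[.data$minute > last_minute - tail_minutes]),
      alive = .data$tail_counts >= min_counts,
      .groups = "drop"
    )
}

#' Average a per-day metric across recording days
#'
#' Undefined per-day values (e.g. an anticipation index with a zero
#' denominator) are omitted from the mean; a fly whose value is undefined on
#' every day gets `NA`.
#'
#' @param values Numeric vector of per-day values (may contain `NA`).
#' @return Their mean over defined days, or `NA` if none are defined.
#' @export
per_day_mean <- function(values) {
  if (!length(values)) {
    abort("`values` must contain at least one recording day.")
  }
  if (all(is.na(values))) {
    return(NA_real_)
  }
  mean(values, na.rm = TRUE)
}

#' Population mean traces in fixed-width time bins
#'
#' Bins each fly's trace into `bin_minutes` windows of the 24-h cycle (48
#' bins for the default 30), averages recording days within each fly first,
#' then reports the across-fly mean and standard error per bin. For
#' `value = "activity"` a bin holds the summed counts; for `value = "sleep"`
#' it holds the number of sleep-scored minutes, so lies in
#' `[0, bin_minutes]`.
#'
#' @inheritParams detect_sleep_bouts
#' @param value Trace to bin: `"activity"` or `"sleep"`.
#' @param bin_minutes Bin width in minutes; must divide 1440.
#' @param threshold_minutes Sleep threshold, used when `value = "sleep"`.
#' @return A `binned_trace` tibble: `bin`, `zt` (bin start, hours), `mean`,
#'   `sem`, `n_flies`. With a single fly the SEM is reported as 0 with a
#'   warning.
#' @export
bin_trace <- function(series, value = c("activity", "sleep"),
                      bin_minutes = 30L, threshold_minutes = 5L) {
  value <- match.arg(value)
  bin_minutes <- assert_count(bin_minutes, "bin_minutes")
  if (1440L %% bin_minutes != 0L) {
    abort("`bin_minutes` must divide 1440 (a whole day of minutes).")
  }
  ids <- fly_id_cols(series)
  dat <- if (value == "sleep") {
    label_sleep_minutes(series, threshold_minutes) |>
      mutate(v = as.integer(.data$asleep))
  } else {
    mutate(series, v = .data$count)
  }
  per_fly <- dat |>
    mutate(bin = floor(.data$zt * 60 / bin_minutes) + 1L) |>
    group_by(across(all_of(c(ids, "day", "bin")))) |>
    summarise(v = sum(.data$v), .groups = "drop") |>
    group_by(across(all_of(c(ids, "bin")))) |>
    summarise(v = mean(.data$v), .groups = "drop")
  out <- per_fly |>
    group_by(.data$bin) |>
    summarise(
      mean = mean(.data$v),
      sem = if (dplyr::n() > 1L) sd(.data$v) / sqrt(dplyr::n()) else 0,
      n_flies = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(zt = (.data$bin - 1L) * bin_minutes / 60) |>
    select("bin", "zt", "mean", "sem", "n_flies")
  if (all(out$n_flies == 1L)) {
    warn("Single fly: SEM reported as 0.")
  }
  structure(out, value = value, bin_minutes = bin_minutes,
            class = c("binned_trace", class(tibble())))
}

#' Compute the full per-fly behavioural metric table
#'
#' For every fly and recording day, computes day/night/total activity
#' counts, sleep minutes, sleep-bout counts and mean bout lengths, and the
#' morning and evening anticipation indices, as one tidy long table. Use
#' [average_days()] to collapse to per-fly means across recording days.
#'
#' @inheritParams detect_sleep_bouts
#' @param windows An [ai_windows()] definition for the anticipation indices.
#' @param boundary Bout attribution rule at phase boundaries; see
#'   [attribute_bouts_to_phase()].
#' @return A `fly_metrics` tibble in long form with the fly identifier
#'   columns plus `day`, `measure` (one of `activity`, `sleep`,
#'   `bout_number`, `bout_length`, `anticipation`), `phase` (`day`, `night`,
#'   `total` -- or `morning`/`evening` for anticipation) and `value`.
#'   Undefined values (bout length with no bouts, anticipation with a zero
#'   denominator) are `NA`.
#' @export
compute_fly_metrics <- function(series, threshold_minutes = 5L,
                                windows = ai_windows(),
                                boundary = c("split", "onset")) {
  boundary <- match.arg(boundary)
  ids <- fly_id_cols(series)

  act <- phase_activity_totals(series) |>
    tidyr::pivot_longer(
      dplyr::starts_with("activity_"),
      names_to = "phase", names_prefix = "activity_", values_to = "value"
    ) |>
    mutate(measure = "activity")

  cells <- attribute_bouts_to_phase(series, threshold_minutes, boundary)
  # whole-day totals count each distinct bout once (a bout crossing
  # lights-off is one bout of the day, though it tallies once per phase)
  lab <- label_sleep_minutes(series, threshold_minutes)
  if (boundary == "onset") {
    onset_day <- lab |>
      filter(!is.na(.data$bout)) |>
      group_by(across(all_of(c(ids, "bout")))) |>
      summarise(day = .data$day[1],
                minutes = dplyr::n(), .groups = "drop")
    tot_agg <- onset_day |>
      group_by(across(all_of(c(ids, "day")))) |>
      summarise(sleep_minutes = sum(.data$minutes),
                bout_count = dplyr::n(), .groups = "drop")
  } else {
    tot_agg <- lab |>
      filter(.data$asleep) |>
      group_by(across(all_of(c(ids, "day")))) |>
      summarise(sleep_minutes = dplyr::n(),
                bout_count = dplyr::n_distinct(.data$bout), .groups = "drop")
  }
  totals <- lab |>
    dplyr::distinct(across(all_of(c(ids, "day")))) |>
    left_join(tot_agg, by = c(ids, "day")) |>
    mutate(
      sleep_minutes = dplyr::coalesce(.data$sleep_minutes, 0L),
      bout_count = dplyr::coalesce(.data$bout_count, 0L),
      bout_length = ifelse(.data$bout_count > 0,
                           .data$sleep_minutes / .data$bout_count, NA_real_),
      phase = "total"
    )
  sleep_long <- bind_rows(
    mutate(cells, bout_count = as.numeric(.data$bout_count)),
    mutate(totals, bout_count = as.numeric(.data$bout_count))
  ) |>
    tidyr::pivot_longer(
      c("sleep_minutes", "bout_count", "bout_length"),
      names_to = "measure", values_to = "value"
    ) |>
    mutate(measure = dplyr::recode(.data$measure,
      sleep_minutes = "sleep", bout_count = "bout_number"
    ))

  ai <- anticipation_index(series, windows) |>
    tidyr::pivot_longer(
      dplyr::starts_with("anticipation_"),
      names_to = "phase", names_prefix = "anticipation_", values_to = "value"
    ) |>
    mutate(measure = "anticipation")

  out <- bind_rows(act, sleep_long, ai) |>
    mutate(value = as.numeric(.data$value)) |>
    select(all_of(c(ids, "day")), "measure", "phase", "value") |>
    arrange(across(all_of(c(ids, "day", "measure", "phase"))))
  structure(out, class = c("fly_metrics", class(tibble())))
}

#' Average per-day metrics across recording days
#'
#' Collapses a [compute_fly_metrics()] table to one value per fly and
#' measure, averaging over recording days with [per_day_mean()] (undefined
#' days omitted).
#'
#' @param metrics A `fly_metrics` tibble.
#' @return The same table without the `day` column, values day-averaged.
#' @export
average_days <- function(metrics) {
  ids <- setdiff(
    intersect(c("monitor", "tube", "fly_id", "strain", "sex", "age_weeks"),
              names(metrics)),
    character(0)
  )
  metrics |>
    group_by(across(all_of(c(ids, "measure", "phase")))) |>
    summarise(value = per_day_mean(.data$value), .groups = "drop")
}
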