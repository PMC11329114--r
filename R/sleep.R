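#' Score sleep bouts as runs of inactive minutes
#'
#' Sleep in activity-monitor assays is scored with the standard behavioural
#' proxy: five or more consecutive minutes with zero activity counts. A
#' sleep bout is one maximal such run; runs shorter than the threshold
#' contribute no sleep. Zero-runs truncated by the window edges count if
#' their within-window length reaches the threshold (no look-ahead outside
#' the extracted window).
#'
#' @param series A `fly_series` tibble from [extract_analysis_window()] (one
#'   or many flies).
#' @param threshold_minutes Minimum run length scored as sleep (default 5).
#'
#' @return A tibble of bouts with the fly identifier columns plus
#'   `bout` (per-fly index), `start_minute` and `duration` (minutes), in
#'   chronological order.
#' @export
detect_sleep_bouts <- function(series, threshold_minutes = 5L) {
  threshold_minutes <- assert_count(threshold_minutes, "threshold_minutes")
  ids <- fly_id_cols(series)
  series <- arrange(series, across(all_of(c(ids, "minute"))))
  lab <- label_sleep_minutes(series, threshold_minutes)
  bouts <- lab |>
    filter(!is.na(.data$bout)) |>
    group_by(across(all_of(c(ids, "bout")))) |>
    summarise(
      start_minute = .data$minute[1],
      duration = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(across(all_of(c(ids, "start_minute"))))
  bouts
}

#' Label each minute of a series as asleep or awake
#'
#' Adds an `asleep` flag and a per-fly `bout` index (NA for awake minutes)
#' to a `fly_series`, using the same maximal-zero-run rule as
#' [detect_sleep_bouts()].
#'
#' @inheritParams detect_sleep_bouts
#' @return The input tibble with `asleep` and `bout` columns appended.
#' @export
label_sleep_minutes <- function(series, threshold_minutes = 5L) {
  threshold_minutes <- assert_count(threshold_minutes, "threshold_minutes")
  ids <- fly_id_cols(series)
  series |>
    arrange(across(all_of(c(ids, "minute")))) |>
    group_by(across(all_of(ids))) |>
    mutate(
      run = with(rle(.data$count == 0L), rep(seq_along(lengths), lengths)),
      run_len = with(rle(.data$count == 0L), rep(lengths, lengths)),
      asleep = .data$count == 0L & .data$run_len >= threshold_minutes,
      bout = ifelse(.data$asleep, .data$run, NA_integer_)
    ) |>
    mutate(bout = match(.data$bout, sort(unique(.data$bout[.data$asleep])))) |>
    select(-"run", -"run_len") |>
    ungroup()
}

#' Attribute sleep bouts to day and night phases
#'
#' Splits each fly's sleep into per-(day, phase) totals: sleep minutes, bout
#' counts, and mean bout length. With `boundary = "split"` (the default) a
#' bout crossing a phase boundary is split at the boundary: each phase
#' receives its overlapped minutes and one bout tally, so day + night totals
#' conserve the overall sleep minutes. With `boundary = "onset"` the whole
#' bout is attributed to the day/phase in which it started.
#'
#' @inheritParams detect_sleep_bouts
#' @param boundary How to attribute a bout that crosses a phase boundary.
#'
#' @return A tibble with the fly identifier columns plus `day`, `phase`,
#'   `sleep_minutes`, `bout_count`, `bout_length` (mean minutes per bout;
#'   `NA` when a phase has no bouts). Every (fly, day, phase) cell of the
#'   window is present, zero-filled where there is no sleep.
#' @export
attribute_bouts_to_phase <- function(series, threshold_minutes = 5L,
                                     boundary = c("split", "onset")) {
  boundary <- match.arg(boundary)
  ids <- fly_id_cols(series)
  lab <- label_sleep_minutes(series, threshold_minutes)

  if (boundary == "onset") {
    # carry each bout's minutes to the (day, phase) cell of its first minute
    onset <- lab |>
      filter(!is.na(.data$bout)) |>
      group_by(across(all_of(c(ids, "bout")))) |>
      summarise(
        day = .data$day[1],
        phase = .data$phase[1],
        minutes = dplyr::n(),
        .groups = "drop"
      )
    agg <- onset |>
      group_by(across(all_of(c(ids, "day", "phase")))) |>
      summarise(
        sleep_minutes = sum(.data$minutes),
        bout_count = dplyr::n(),
        .groups = "drop"
      )
  } else {
    agg <- lab |>
      filter(.data$asleep) |>
      group_by(across(all_of(c(ids, "day", "phase")))) |>
      summarise(
        sleep_minutes = dplyr::n(),
        bout_count = dplyr::n_distinct(.data$bout),
        .groups = "drop"
      )
  }

  cells <- lab |>
    dplyr::distinct(across(all_of(c(ids, "day", "phase"))))
  cells |>
    left_join(agg, by = c(ids, "day", "phase")) |>
    mutate(
      sleep_minutes = dplyr::coalesce(.data$sleep_minutes, 0L),
      bout_count = dplyr::coalesce(.data$bout_count, 0L),
      bout_length = ifelse(.data$bout_count > 0,
                           .data$sleep_minutes / .data$bout_count, NA_real_)
    ) |>
    arrange(across(all_of(c(ids, "day", "phase"))))
}
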