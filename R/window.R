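#' Extract the analysis window aligned to lights-on
#'
#' Flies are given an acclimation period after loading into the monitors;
#' analysis then starts at the next lights-on event and spans a whole number
#' of 24-hour cycles (48 h in the four-age design, 24 h in the two-age
#' replicate design). The returned series carries Zeitgeber time (ZT, hours
#' since lights-on, so `zt[1] == 0`), a day/night phase label per minute
#' under the half-open `[on, off)` convention, and a recording-day index.
#'
#' @param tube_counts A `tube_counts` tibble from [sum_beams()] (all tubes of
#'   a monitor, or several monitors row-bound).
#' @param schedule A [light_schedule()].
#' @param acclimation_hours Minimum hours to discard before the window may
#'   start (default 24).
#' @param window_hours Length of the analysis window in hours; must be a
#'   positive multiple of `schedule$cycle_hours` (default 48).
#'
#' @return A `fly_series` tibble: one row per minute per tube with columns
#'   `monitor`, `tube`, `minute` (1-based index into the window), `datetime`,
#'   `zt`, `phase`, `day`, `flagged`, `count`.
#' @export
extract_analysis_window <- function(tube_counts, schedule,
                                    acclimation_hours = 24,
                                    window_hours = 48) {
  if (!all(c("datetime", "tube", "count") %in% names(tube_counts))) {
    abort("`tube_counts` must have datetime, tube and count columns.")
  }
  if (!inherits(schedule, "light_schedule")) {
    abort("`schedule` must be a light_schedule object.")
  }
  assert_number(acclimation_hours, "acclimation_hours", lower = 0)
  assert_number(window_hours, "window_hours", lower = 1e-9)
  if (abs(window_hours / schedule$cycle_hours -
          round(window_hours / schedule$cycle_hours)) > 1e-9) {
    abort("`window_hours` must be a whole number of light:dark cycles.")
  }

  stamps <- sort(unique(tube_counts$datetime))
  zt <- zeitgeber_hours(stamps, schedule)
  earliest <- stamps[1] + acclimation_hours * 3600
  on_idx <- which(abs(zt) < 1e-9 & stamps >= earliest)
  if (!length(on_idx)) {
    abort(sprintf(
      "No lights-on event after the %g h acclimation period (recording spans %.1f h).",
      acclimation_hours,
      as.numeric(difftime(stamps[length(stamps)], stamps[1], units = "hours"))
    ))
  }
  start <- stamps[on_idx[1]]
  n_min <- as.integer(round(window_hours * 60))
  end <- start + (n_min - 1L) * 60
  if (stamps[length(stamps)] < end) {
    avail <- as.numeric(difftime(stamps[length(stamps)], start, units = "hours")) + 1 / 60
    abort(sprintf(
      "Recording too short: %.1f h required from lights-on at %s, %.1f h available.",
      window_hours, format(start, tz = "UTC"), avail
    ))
  }

  out <- filter(tube_counts, .data$datetime >= start, .data$datetime <= end)
  out <- arrange(out, if ("monitor" %in% names(out)) .data$monitor else NULL,
                 .data$tube, .data$datetime)
  out <- mutate(out,
    minute = as.integer(round(as.numeric(difftime(
      .data$datetime, start, units = "mins"
    )))) + 1L,
    zt = zeitgeber_hours(.data$datetime, schedule),
    phase = phase_of(.data$zt, schedule),
    day = (.data$minute - 1L) %/% as.integer(schedule$cycle_hours * 60) + 1L
  )
  per_tube <- dplyr::count(out,
    dplyr::across(dplyr::any_of(c("monitor", "tube")))
  )
  if (any(per_tube$n != n_min)) {
    abort("Analysis window has missing minutes for some tubes.")
  }
  keep <- intersect(
    c("monitor", "tube", "minute", "datetime", "zt", "phase", "day",
      "flagged", "count"),
    names(out)
  )
  out <- select(out, all_of(keep))
  structure(out,
    schedule = schedule, window_start = start, window_minutes = n_min,
    class = c("fly_series", class(tibble()))
  )
}

# Grouping columns identifying one fly within a fly_series table.
fly_id_cols <- function(series) {
  intersect(c("monitor", "tube", "fly_id"), names(series))
}
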