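#' Describe the beam geometry of a DAM monitor file
#'
#' Trikinetics activity monitors report one column of infrared beam-break
#' counts per beam. Classic single-beam monitors (DAM2) have one beam per
#' tube; multibeam monitors (DAM5H) place several beams -- typically 15 --
#' along each tube. A `beam_layout` records how many tubes and beams a file
#' carries, where the count columns start, and which `(tube, beam)` pair each
#' count column belongs to, so that per-beam files and already-summed
#' per-tube files can both be read with the same machinery.
#'
#' @param tubes_per_monitor Number of fly tubes in the monitor.
#' @param beams_per_tube Number of beams along each tube. `15` for DAM5H
#'   multibeam monitors; use `1` for single-beam monitors or for files whose
#'   counts have already been summed per tube.
#' @param count_columns_start 1-based index of the first count column in the
#'   tab-separated file. The default dialect has columns: record index, date,
#'   time, status, six metadata columns, a light-sensor flag, then counts.
#' @param beam_order Optional integer matrix with one row per count column and
#'   columns `tube` and `beam`, mapping column offsets to `(tube, beam)`
#'   pairs. Defaults to consecutive blocks: columns `1..beams_per_tube` are
#'   tube 1, and so on.
#'
#' @return A `beam_layout` object (a list with the fields above).
#' @examples
#' beam_layout(8, 15) # a DAM5H monitor: 120 count columns
#' beam_layout(32, 1) # a single-beam monitor or summed per-tube file
#' @export
beam_layout <- function(tubes_per_monitor,
                        beams_per_tube = 15L,
                        count_columns_start = 12L,
                        beam_order = NULL) {
  tubes_per_monitor <- assert_count(tubes_per_monitor, "tubes_per_monitor")
  beams_per_tube <- assert_count(beams_per_tube, "beams_per_tube")
  count_columns_start <- assert_count(count_columns_start, "count_columns_start")
  n_cols <- tubes_per_monitor * beams_per_tube
  if (is.null(beam_order)) {
    beam_order <- cbind(
      tube = rep(seq_len(tubes_per_monitor), each = beams_per_tube),
      beam = rep(seq_len(beams_per_tube), times = tubes_per_monitor)
    )
  } else {
    beam_order <- as.matrix(beam_order)
    if (nrow(beam_order) != n_cols || ncol(beam_order) != 2L) {
      abort(sprintf(
        "`beam_order` must be a %d x 2 (tube, beam) matrix.", n_cols
      ))
    }
    colnames(beam_order) <- c("tube", "beam")
    keys <- paste(beam_order[, 1], beam_order[, 2])
    want <- paste(
      rep(seq_len(tubes_per_monitor), each = beams_per_tube),
      rep(seq_len(beams_per_tube), times = tubes_per_monitor)
    )
    if (anyDuplicated(keys) || !setequal(keys, want)) {
      abort("`beam_order` must be a bijection onto all (tube, beam) pairs.")
    }
  }
  structure(
    list(
      tubes_per_monitor = tubes_per_monitor,
      beams_per_tube = beams_per_tube,
      count_columns_start = count_columns_start,
      beam_order = beam_order,
      n_count_columns = n_cols
    ),
    class = "beam_layout"
  )
}

#' @export
print.beam_layout <- function(x, ...) {
  cat(sprintf(
    "<beam_layout> %d tubes x %d beams (%d count columns from column %d)\n",
    x$tubes_per_monitor, x$beams_per_tube, x$n_count_columns,
    x$count_columns_start
  ))
  invisible(x)
}

#' Define the light:dark schedule of an experiment
#'
#' @param lights_on Clock time of lights-on, as `"HH:MM:SS"` or `"HH:MM"`.
#' @param photoperiod_hours Hours of light per cycle (default 12, the
#'   standard 12h:12h light:dark regime).
#' @param cycle_hours Full cycle length in hours (default 24).
#'
#' @details Phase labelling uses half-open intervals: a minute is "day" iff
#' its Zeitgeber time lies in `[0, photoperiod_hours)`, where ZT0 is
#' lights-on. The lights-on minute itself therefore belongs to the day and
#' the lights-off minute to the night, so no minute is counted twice.
#'
#' @return A `light_schedule` object.
#' @examples
#' light_schedule("08:00")
#' @export
light_schedule <- function(lights_on = "08:00:00",
                           photoperiod_hours = 12,
                           cycle_hours = 24) {
  assert_number(photoperiod_hours, "photoperiod_hours", lower = 1e-9)
  assert_number(cycle_hours, "cycle_hours", lower = 1e-9)
  if (photoperiod_hours >= cycle_hours) {
    abort("`photoperiod_hours` must be strictly less than `cycle_hours`.")
  }
  parts <- strsplit(lights_on, ":", fixed = TRUE)[[1]]
  if (!length(parts) %in% c(2L, 3L) || anyNA(suppressWarnings(as.numeric(parts)))) {
    abort("`lights_on` must be a clock time like \"08:00\" or \"08:00:00\".")
  }
  parts <- as.numeric(parts)
  secs <- parts[1] * 3600 + parts[2] * 60 + if (length(parts) == 3L) parts[3] else 0
  if (secs < 0 || secs >= 86400) {
    abort("`lights_on` must lie within a single day.")
  }
  structure(
    list(
      lights_on = sprintf(
        "%02d:%02d:%02d", secs %/% 3600, (secs %% 3600) %/% 60, secs %% 60
      ),
      lights_on_seconds = secs,
      photoperiod_hours = photoperiod_hours,
      cycle_hours = cycle_hours
    ),
    class = "light_schedule"
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf(
    "<light_schedule> lights on %s, %gh:%gh light:dark\n",
    x$lights_on, x$photoperiod_hours, x$cycle_hours - x$photoperiod_hours
  ))
  invisible(x)
}

# Zeitgeber time (hours since lights-on, in [0, cycle)) of POSIXct stamps.
zeitgeber_hours <- function(datetime, schedule) {
  secs_of_day <- as.numeric(datetime) %% 86400
  zt <- (secs_of_day - schedule$lights_on_seconds) / 3600
  zt %% schedule$cycle_hours
}

# "day"/"night" phase labels under the half-open [on, off) convention.
phase_of <- function(zt, schedule) {
  ifelse(zt < schedule$photoperiod_hours, "day", "night")
}
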