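MONTH_ABBREV <- c(
  "Jan", "Feb", "Mar", "Apr", "May", "Jun",
  "Jul", "Aug", "Sep", "Oct", "Nov", "Dec"
)

# Locale-independent parser for the DAM date/time stamp ("1 Jan 24",
# "08:00:00"). Returns POSIXct in UTC; NA for unparseable stamps.
parse_dam_datetime <- function(date_str, time_str) {
  parts <- strsplit(trimws(date_str), " +")
  day <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  mon <- match(vapply(parts, `[`, "", 2L), MONTH_ABBREV)
  yr <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  yr <- ifelse(!is.na(yr) & yr < 100L, 2000L + yr, yr)
  iso <- sprintf("%04d-%02d-%02d %s", yr, mon, day, time_str)
  iso[is.na(day) | is.na(mon) | is.na(yr)] <- NA
  as.POSIXct(iso, tz = "UTC")
}

format_dam_datetime <- function(datetime) {
  lt <- as.POSIXlt(datetime, tz = "UTC")
  list(
    date = sprintf("%d %s %02d", lt$mday, MONTH_ABBREV[lt$mon + 1L],
                   lt$year %% 100L),
    time = sprintf("%02d:%02d:%02d", lt$hour, lt$min, lt$sec)
  )
}

#' Read a DAM-style activity monitor file
#'
#' Reads a tab-separated Trikinetics-style monitor file: one row per minute
#' with a record index, date, time, status code, metadata columns, an
#' optional light-sensor flag, and one count column per beam as described by
#' `layout`. Rows whose status code is not in `valid_status` are retained but
#' flagged (`flagged = TRUE`), never silently dropped; downstream analysis
#' excludes flies whose analysis window contains flagged rows. Short clock
#' gaps (missing minutes) are repaired by inserting zero-count rows, up to
#' `max_gap_minutes`; longer gaps or non-monotone timestamps raise an error.
#'
#' @param path Path to the monitor file.
#' @param layout A [beam_layout()] describing the count-column geometry.
#' @param monitor_id Identifier for the monitor; defaults to the file name.
#' @param valid_status Integer status codes treated as valid (default `1`).
#' @param max_gap_minutes Longest repairable gap, in missing minutes.
#'
#' @return A `dam_recording`: a tibble with columns `datetime`, `status`,
#'   `light`, `flagged`, and one integer column per beam (`cnt_001`, ...),
#'   with the layout and monitor id stored as attributes.
#' @seealso [sum_beams()], [extract_analysis_window()]
#' @export
read_monitor_file <- function(path, layout,
                              monitor_id = NULL,
                              valid_status = 1L,
                              max_gap_minutes = 5L) {
  if (!inherits(layout, "beam_layout")) {
    abort("`layout` must be a beam_layout object.")
  }
  if (!file.exists(path)) {
    abort(sprintf("Monitor file not found: %s", path))
  }
  monitor_id <- monitor_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    abort(sprintf("Monitor file is empty: %s", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_expected <- layout$count_columns_start - 1L + layout$n_count_columns
  n_found <- lengths(fields)
  bad <- which(n_found != n_expected)
  if (length(bad)) {
    abort(sprintf(
      "Malformed row in %s at line %d: expected %d tab-separated columns, found %d.",
      path, bad[1], n_expected, n_found[bad[1]]
    ))
  }
  mat <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  datetime <- parse_dam_datetime(mat[, 2], mat[, 3])
  if (anyNA(datetime)) {
    abort(sprintf(
      "Unparseable date/time in %s at line %d.", path, which(is.na(datetime))[1]
    ))
  }
  status <- suppressWarnings(as.integer(mat[, 4]))
  light_col <- layout$count_columns_start - 1L
  light <- if (light_col >= 5L) {
    suppressWarnings(as.integer(mat[, light_col]))
  } else {
    rep(NA_integer_, nrow(mat))
  }
  counts <- suppressWarnings(
    matrix(as.integer(mat[, layout$count_columns_start - 1L +
                            seq_len(layout$n_count_columns), drop = FALSE]),
           nrow = nrow(mat))
  )
  if (anyNA(counts)) {
    abort(sprintf(
      "Non-integer count value in %s at line %d.",
      path, which(rowSums(is.na(counts)) > 0)[1]
    ))
  }
  if (any(counts < 0L)) {
    abort(sprintf(
      "Negative count value in %s at line %d.",
      path, which(rowSums(counts < 0L) > 0)[1]
    ))
  }
  rec <- new_dam_recording(datetime, status, light, counts, layout, monitor_id,
                           valid_status = valid_status)
  repair_minute_gaps(rec, max_gap_minutes = max_gap_minutes, path = path)
}

new_dam_recording <- function(datetime, status, light, counts, layout,
                              monitor_id, valid_status = 1L,
                              n_repaired = 0L) {
  colnames(counts) <- sprintf("cnt_%03d", seq_len(ncol(counts)))
  out <- tibble(
    datetime = datetime,
    status = status,
    light = light,
    flagged = !(status %in% as.integer(valid_status))
  )
  out <- dplyr::bind_cols(out, as_tibble(counts))
  structure(
    out,
    layout = layout,
    monitor_id = monitor_id,
    valid_status = as.integer(valid_status),
    n_repaired = n_repaired,
    class = c("dam_recording", class(out))
  )
}

# Insert zero-count rows for missing minutes (clock skips) up to
# `max_gap_minutes`; abort on longer gaps or non-increasing stamps.
repair_minute_gaps <- function(rec, max_gap_minutes = 5L, path = "<recording>") {
  layout <- attr(rec, "layout")
  dmin <- as.numeric(diff(rec$datetime), units = "mins")
  if (any(dmin <= 0)) {
    abort(sprintf(
      "Non-monotone timestamps in %s near row %d.", path, which(dmin <= 0)[1] + 1L
    ))
  }
  if (any(abs(dmin - round(dmin)) > 1e-6)) {
    abort(sprintf("Timestamps in %s are not minute-aligned.", path))
  }
  dmin <- as.integer(round(dmin))
  if (all(dmin == 1L)) {
    return(rec)
  }
  gaps <- which(dmin > 1L)
  too_long <- gaps[dmin[gaps] - 1L > max_gap_minutes]
  if (length(too_long)) {
    abort(sprintf(
      "Clock gap of %d missing minutes in %s after %s exceeds the repairable limit of %d.",
      dmin[too_long[1]] - 1L, path,
      format(rec$datetime[too_long[1]], tz = "UTC"), max_gap_minutes
    ))
  }
  full <- seq(rec$datetime[1], rec$datetime[nrow(rec)], by = "1 min")
  idx <- match(full, rec$datetime)
  present <- !is.na(idx)
  counts <- matrix(0L, nrow = length(full), ncol = layout$n_count_columns)
  cnt_cols <- grep("^cnt_", names(rec))
  counts[present, ] <- as.matrix(rec[idx[present], cnt_cols])
  status <- rep(attr(rec, "valid_status")[1], length(full))
  status[present] <- rec$status[idx[present]]
  light <- rep(NA_integer_, length(full))
  light[present] <- rec$light[idx[present]]
  new_dam_recording(full, status, light, counts, layout,
                    attr(rec, "monitor_id"),
                    valid_status = attr(rec, "valid_status"),
                    n_repaired = sum(!present))
}

#' Sum per-beam counts into per-tube activity
#'
#' Multibeam monitors report each beam separately; per-fly analysis uses the
#' total beam breaks per tube per minute. This collapses the beam columns of
#' a recording into one count per tube, conserving the grand total.
#'
#' @param rec A `dam_recording` from [read_monitor_file()].
#'
#' @return A `tube_counts` tibble in long form: one row per minute per tube
#'   with columns `monitor`, `datetime`, `status`, `flagged`, `tube`,
#'   `count`.
#' @export
sum_beams <- function(rec) {
  if (!inherits(rec, "dam_recording")) {
    abort("`rec` must be a dam_recording from read_monitor_file().")
  }
  layout <- attr(rec, "layout")
  cnt_cols <- grep("^cnt_", names(rec))
  if (length(cnt_cols) != layout$n_count_columns) {
    abort("Recording count columns do not match its layout.")
  }
  counts <- as.matrix(rec[, cnt_cols])
  tube_of_col <- layout$beam_order[, "tube"]
  per_tube <- vapply(
    seq_len(layout$tubes_per_monitor),
    function(tb) {
      cols <- which(tube_of_col == tb)
      if (length(cols) == 1L) counts[, cols] else rowSums(counts[, cols, drop = FALSE])
    },
    numeric(nrow(counts))
  )
  if (nrow(rec) == 1L) per_tube <- matrix(per_tube, nrow = 1L)
  out <- tibble(
    monitor = attr(rec, "monitor_id"),
    datetime = rep(rec$datetime, times = layout$tubes_per_monitor),
    status = rep(rec$status, times = layout$tubes_per_monitor),
    flagged = rep(rec$flagged, times = layout$tubes_per_monitor),
    tube = rep(seq_len(layout$tubes_per_monitor), each = nrow(rec)),
    count = as.integer(per_tube)
  )
  out <- arrange(out, .data$datetime, .data$tube)
  structure(out, monitor_id = attr(rec, "monitor_id"),
            class = c("tube_counts", class(tibble())))
}

#' Write and re-read per-tube summed count files
#'
#' `write_summed_file()` persists a `tube_counts` table in the same
#' tab-separated row structure as a monitor file, with one count column per
#' tube; `read_summed_file()` reads such a file (or any single-beam monitor
#' file) back. Writing then reading is the identity on the count matrix.
#'
#' @param table A `tube_counts` tibble from [sum_beams()].
#' @param path Output file path.
#' @return `write_summed_file()` returns `path` invisibly;
#'   `read_summed_file()` returns a `tube_counts` tibble.
#' @export
write_summed_file <- function(table, path) {
  if (!all(c("datetime", "tube", "count") %in% names(table))) {
    abort("`table` must have datetime, tube and count columns.")
  }
  wide <- tidyr::pivot_wider(
    as_tibble(table),
    id_cols = dplyr::any_of(c("datetime", "status")),
    names_from = "tube", values_from = "count", names_prefix = "tube_"
  )
  wide <- arrange(wide, .data$datetime)
  if (!nrow(wide)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stamp <- format_dam_datetime(wide$datetime)
  status <- if ("status" %in% names(wide)) wide$status else rep(1L, nrow(wide))
  counts <- as.matrix(wide[, grep("^tube_", names(wide)), drop = FALSE])
  body <- cbind(
    seq_len(nrow(wide)), stamp$date, stamp$time, status,
    matrix(0L, nrow(wide), 6L), 0L, counts
  )
  writeLines(apply(body, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' @rdname write_summed_file
#' @param n_tubes Number of tube count columns in the file.
#' @param ... Passed on to [read_monitor_file()].
#' @export
read_summed_file <- function(path, n_tubes, ...) {
  layout <- beam_layout(n_tubes, beams_per_tube = 1L)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) {
    out <- tibble(
      monitor = character(), datetime = as.POSIXct(character(), tz = "UTC"),
      status = integer(), flagged = logical(), tube = integer(),
      count = integer()
    )
    return(structure(out, class = c("tube_counts", class(tibble()))))
  }
  rec <- read_monitor_file(path, layout, ...)
  sum_beams(rec)
}
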