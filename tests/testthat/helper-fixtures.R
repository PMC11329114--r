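# Shared fixture builders. Everything is generated in code; no stored data.

# Build a single-fly fly_series directly from a per-minute count vector,
# starting at lights-on (ZT0) under a 12:12 schedule by default.
make_series <- function(counts, schedule = light_schedule("08:00:00"),
                        tube = 1L, monitor = "m1", start_zt = 0) {
  n <- length(counts)
  start <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC") + start_zt * 3600
  datetime <- start + (seq_len(n) - 1L) * 60
  zt <- (start_zt + (seq_len(n) - 1L) / 60) %% schedule$cycle_hours
  out <- tibble::tibble(
    monitor = monitor, tube = tube, minute = seq_len(n), datetime = datetime,
    zt = zt,
    phase = ifelse(zt < schedule$photoperiod_hours, "day", "night"),
    day = (seq_len(n) - 1L) %/% (schedule$cycle_hours * 60) + 1L,
    flagged = FALSE,
    count = as.integer(counts)
  )
  structure(out,
    schedule = schedule, window_start = start, window_minutes = n,
    class = c("fly_series", class(tibble::tibble()))
  )
}

# Stack several count vectors as one multi-fly series (one tube per fly).
make_population <- function(count_list, ...) {
  out <- dplyr::bind_rows(lapply(seq_along(count_list), function(i) {
    make_series(count_list[[i]], tube = i, ...)
  }))
  one <- make_series(count_list[[1]], ...)
  for (a in c("schedule", "window_start", "window_minutes")) {
    attr(out, a) <- attr(one, a)
  }
  class(out) <- class(one)
  out
}

# Independent run-length-encoding oracle for sleep bouts: scans the binary
# inactivity vector directly, no shared code with detect_sleep_bouts().
rle_bout_oracle <- function(counts, threshold = 5L) {
  bouts <- list()
  run_start <- NA_integer_
  for (i in seq_along(counts)) {
    if (counts[i] == 0L) {
      if (is.na(run_start)) run_start <- i
    }
    if (counts[i] != 0L || i == length(counts)) {
      if (!is.na(run_start)) {
        run_end <- if (counts[i] != 0L) i - 1L else i
        len <- run_end - run_start + 1L
        if (len >= threshold) {
          bouts[[length(bouts) + 1L]] <- c(start = run_start, duration = len)
        }
        run_start <- NA_integer_
      }
    }
  }
  if (!length(bouts)) {
    return(data.frame(start = integer(0), duration = integer(0)))
  }
  as.data.frame(do.call(rbind, bouts))
}

# Write a per-beam count matrix as a DAM-dialect monitor file.
write_dam_fixture <- function(counts, path,
                              start = as.POSIXct("2024-01-01 08:00:00",
                                                 tz = "UTC")) {
  damsleep:::write_dam_file(counts, start, path)
}
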