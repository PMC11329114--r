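#' Configuration for the synthetic activity / lifespan generator
#'
#' Defines a complete synthetic cohort: the light schedule, the sleep-wake
#' process, the wake activity intensity profile, group effect multipliers,
#' monitor geometry, and the lifespan model. The generator is the testing
#' stand-in for a real recorded cohort; every parameter has a known ground
#' truth that the pipeline can be checked against.
#'
#' @details
#' Sleep and wake alternate as a discrete-time renewal process: wake runs
#' (in minutes) are geometric with a per-phase mean and sleep runs are
#' shifted geometrics with a `min_sleep_run` floor, matching the 1-minute
#' sampling of the monitors and giving analytic expected bout lengths.
#' Every sleeping minute emits zero counts; every waking minute emits a
#' Poisson count with intensity (counts/min)
#' `baseline + startle + anticipation ramp`, where the startle decays
#' exponentially after each light transition and the ramp rises linearly
#' over the `ramp_window_hours` preceding each transition (slope in
#' counts/min per hour). With a flat profile the expected anticipation
#' index is exactly the numerator/denominator window ratio (0.5 for the
#' 3 h / 6 h default); the ramp shifts it upward in closed form.
#'
#' Lifespans follow a Gompertz hazard `a * exp(b * t)` (exponential when
#' `b = 0`), sampled by inverse transform, with independent uniform
#' censoring applied at rate `censor_rate`.
#'
#' @param seed Integer master seed. Each fly and the lifespan table get
#'   their own derived substream, so adding flies never perturbs existing
#'   traces.
#' @param n_flies Flies per group.
#' @param groups Data frame with one row per group: columns `strain`,
#'   `sex`, `age_weeks`, and optional effect multipliers `activity_mult`
#'   (scales wake intensity), `ramp_mult` (scales the anticipation ramp),
#'   `sleep_mult` (scales sleep-run means), `hazard_mult` (scales the
#'   Gompertz baseline hazard).
#' @param schedule A [light_schedule()].
#' @param start_datetime Clock time of the first recorded minute; defaults
#'   to the lights-on event of 2024-01-01.
#' @param wake_run_mean,sleep_run_mean Named vectors `c(day = , night = )`
#'   of mean run lengths in minutes (>= 1).
#' @param min_sleep_run Minimum sleep-run length in minutes (default 5, the
#'   scoring threshold). Sleep runs are drawn as
#'   `min_sleep_run - 1 + Geometric` with the configured mean, so every
#'   generated sleep episode is long enough to be scored and the configured
#'   mean equals the expected scored bout length; sub-threshold quiescence
#'   still arises naturally from zero Poisson counts during wake. Set to 1
#'   for a plain geometric run law.
#' @param baseline_rate Baseline wake intensity, counts/min.
#' @param ramp_slope Anticipation ramp slope, counts/min per hour over the
#'   pre-transition window.
#' @param ramp_window_hours Length of the pre-transition ramp window.
#' @param startle_amp,startle_decay_minutes Post-transition startle burst:
#'   amplitude (counts/min at the transition) and exponential decay time.
#' @param tubes_per_monitor,beams_per_tube Monitor geometry used when
#'   writing DAM files (defaults: 8 tubes x 15 beams, the multibeam
#'   layout).
#' @param recording_hours Total recorded span per fly.
#' @param dead_fly_fraction Fraction of tubes whose fly dies mid-recording
#'   (counts cease at a drawn death minute).
#' @param empty_tube_fraction Fraction of tubes left empty (all-zero).
#' @param gompertz_a,gompertz_b Gompertz hazard scale (per day) and shape
#'   (per day).
#' @param censor_rate Probability that an individual is censored before
#'   death.
#' @param n_lifespan Individuals per group in the lifespan table.
#' @param scoring_interval_days If set, death/censor times are rounded up
#'   to the next multiple (emulating discrete vial-transfer scoring).
#'
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_flies = 32L,
                       groups = default_sim_groups(),
                       schedule = light_schedule("08:00:00"),
                       start_datetime = NULL,
                       wake_run_mean = c(day = 40, night = 10),
                       sleep_run_mean = c(day = 15, night = 30),
                       min_sleep_run = 5L,
                       baseline_rate = 2,
                       ramp_slope = 0.5,
                       ramp_window_hours = 6,
                       startle_amp = 4,
                       startle_decay_minutes = 20,
                       tubes_per_monitor = 8L,
                       beams_per_tube = 15L,
                       recording_hours = 96,
                       dead_fly_fraction = 0,
                       empty_tube_fraction = 0,
                       gompertz_a = 5e-4,
                       gompertz_b = 0.15,
                       censor_rate = 0.02,
                       n_lifespan = 150L,
                       scoring_interval_days = NULL) {
  seed <- assert_count(seed, "seed", lower = 0L)
  n_flies <- assert_count(n_flies, "n_flies")
  groups <- as_tibble(groups)
  for (v in c("strain", "sex", "age_weeks")) {
    if (!v %in% names(groups)) {
      abort(sprintf("`groups` must have a `%s` column.", v))
    }
  }
  for (v in c("activity_mult", "ramp_mult", "sleep_mult", "hazard_mult")) {
    if (!v %in% names(groups)) groups[[v]] <- 1
    if (any(groups[[v]] < 0)) abort(sprintf("`groups$%s` must be >= 0.", v))
  }
  if (!inherits(schedule, "light_schedule")) {
    abort("`schedule` must be a light_schedule object.")
  }
  for (v in c("wake_run_mean", "sleep_run_mean")) {
    x <- get(v)
    if (!all(c("day", "night") %in% names(x)) || any(x < 1)) {
      abort(sprintf("`%s` must be c(day =, night =) with means >= 1 minute.", v))
    }
  }
  min_sleep_run <- assert_count(min_sleep_run, "min_sleep_run")
  if (any(sleep_run_mean < min_sleep_run)) {
    abort("`sleep_run_mean` must be >= `min_sleep_run` in both phases.")
  }
  assert_number(baseline_rate, "baseline_rate", lower = 0)
  assert_number(ramp_slope, "ramp_slope", lower = 0)
  assert_number(ramp_window_hours, "ramp_window_hours", lower = 1e-9)
  assert_number(startle_amp, "startle_amp", lower = 0)
  assert_number(startle_decay_minutes, "startle_decay_minutes", lower = 1e-9)
  assert_number(recording_hours, "recording_hours", lower = 1)
  assert_number(dead_fly_fraction, "dead_fly_fraction", lower = 0)
  assert_number(empty_tube_fraction, "empty_tube_fraction", lower = 0)
  if (dead_fly_fraction > 1 || empty_tube_fraction > 1) {
    abort("Fractions must lie in [0, 1].")
  }
  assert_number(gompertz_a, "gompertz_a", lower = 1e-12)
  assert_number(gompertz_b, "gompertz_b", lower = 0)
  assert_number(censor_rate, "censor_rate", lower = 0)
  if (censor_rate > 1) abort("`censor_rate` must lie in [0, 1].")
  if (is.null(start_datetime)) {
    start_datetime <- as.POSIXct(paste("2024-01-01", schedule$lights_on),
                                 tz = "UTC")
  }
  structure(
    list(
      seed = seed, n_flies = n_flies, groups = groups, schedule = schedule,
      start_datetime = start_datetime,
      wake_run_mean = wake_run_mean, sleep_run_mean = sleep_run_mean,
      min_sleep_run = min_sleep_run,
      baseline_rate = baseline_rate, ramp_slope = ramp_slope,
      ramp_window_hours = ramp_window_hours,
      startle_amp = startle_amp,
      startle_decay_minutes = startle_decay_minutes,
      tubes_per_monitor = assert_count(tubes_per_monitor, "tubes_per_monitor"),
      beams_per_tube = assert_count(beams_per_tube, "beams_per_tube"),
      recording_hours = recording_hours,
      dead_fly_fraction = dead_fly_fraction,
      empty_tube_fraction = empty_tube_fraction,
      gompertz_a = gompertz_a, gompertz_b = gompertz_b,
      censor_rate = censor_rate,
      n_lifespan = assert_count(n_lifespan, "n_lifespan"),
      scoring_interval_days = scoring_interval_days
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_sim_groups <- function() {
  tibble(
    strain = "CS", sex = c("F", "M"), age_weeks = 2L,
    activity_mult = 1, ramp_mult = 1, sleep_mult = 1, hazard_mult = c(1, 2)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> seed %d: %d groups x %d flies, %g h recording, %d x %d beams\n",
    x$seed, nrow(x$groups), x$n_flies, x$recording_hours,
    x$tubes_per_monitor, x$beams_per_tube
  ))
  invisible(x)
}

# Wake intensity (counts/min) at each Zeitgeber time for a group.
wake_intensity <- function(zt, config, activity_mult = 1, ramp_mult = 1) {
  sch <- config$schedule
  photo <- sch$photoperiod_hours
  cyc <- sch$cycle_hours
  win <- config$ramp_window_hours
  lambda <- rep(config$baseline_rate, length(zt))
  # anticipation ramps before lights-off and before lights-on
  for (transition in c(photo, cyc)) {
    inside <- zt >= transition - win & zt < transition
    lambda[inside] <- lambda[inside] +
      config$ramp_slope * ramp_mult * (zt[inside] - (transition - win))
  }
  # startle bursts after lights-on (zt 0) and lights-off (zt photo)
  for (transition in c(0, photo)) {
    since <- (zt - transition) %% cyc
    lambda <- lambda + config$startle_amp *
      exp(-(since * 60) / config$startle_decay_minutes) * (since < cyc / 2)
  }
  lambda * activity_mult
}

#' Simulate one fly's per-minute activity trace
#'
#' Draws the alternating sleep/wake renewal process and Poisson wake counts
#' for a single fly, returning the trace together with its ground truth
#' (state sequence and per-minute intensity).
#'
#' @param config A [sim_config()].
#' @param group A single row of `config$groups` (defaults to the first).
#' @param seed Substream seed for this fly; derive it with the master seed
#'   plus a fly label for reproducible cohorts.
#'
#' @return A list: `series` (tibble `minute`, `datetime`, `zt`, `phase`,
#'   `count`, `asleep_truth`) and `truth` (list with the state run lengths
#'   and intensity vector).
#' @export
simulate_fly_minutes <- function(config, group = NULL, seed = NULL) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config object.")
  }
  group <- group %||% config$groups[1, ]
  n_min <- as.integer(round(config$recording_hours * 60))
  datetime <- config$start_datetime + (seq_len(n_min) - 1L) * 60
  zt <- zeitgeber_hours(datetime, config$schedule)
  phase <- phase_of(zt, config$schedule)
  lambda <- wake_intensity(zt, config,
                           activity_mult = group$activity_mult %||% 1,
                           ramp_mult = group$ramp_mult %||% 1)
  sleep_mult <- group$sleep_mult %||% 1

  with_seed(seed, {
    state <- integer(n_min) # 1 = wake, 0 = sleep
    runs <- integer(0)
    pos <- 1L
    awake <- TRUE # flies are handled/startled at loading: start awake
    while (pos <= n_min) {
      if (awake) {
        len <- rgeom(1L, 1 / config$wake_run_mean[[phase[pos]]]) + 1L
      } else {
        # shifted geometric: min_sleep_run floor, configured mean overall
        shift <- config$min_sleep_run - 1L
        m_eff <- max(config$min_sleep_run,
                     config$sleep_run_mean[[phase[pos]]] * sleep_mult)
        len <- shift + rgeom(1L, 1 / (m_eff - shift)) + 1L
      }
      end <- min(pos + len - 1L, n_min)
      state[pos:end] <- as.integer(awake)
      runs <- c(runs, end - pos + 1L)
      pos <- end + 1L
      awake <- !awake
    }
    count <- integer(n_min)
    wake_idx <- state == 1L
    count[wake_idx] <- rpois(sum(wake_idx), lambda[wake_idx])
    list(
      series = tibble(
        minute = seq_len(n_min), datetime = datetime, zt = zt, phase = phase,
        count = count, asleep_truth = state == 0L
      ),
      truth = list(run_lengths = runs, intensity = lambda, state = state)
    )
  })
}

#' Simulate a whole cohort as an in-memory fly series table
#'
#' Convenience wrapper over [simulate_fly_minutes()]: simulates `n_flies`
#' per group, trims the acclimation period, and returns an analysis-ready
#' `fly_series` table (as produced by [extract_analysis_window()]) plus the
#' per-fly ground truth.
#'
#' @inheritParams simulate_fly_minutes
#' @param acclimation_hours,window_hours Window passed to
#'   [extract_analysis_window()].
#' @return A list: `series` (a `fly_series` tibble with `fly_id`, `strain`,
#'   `sex`, `age_weeks` columns) and `truth` (per-fly tibble of group
#'   parameters).
#' @export
simulate_cohort <- function(config, acclimation_hours = 24,
                            window_hours = 48) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config object.")
  }
  all_series <- list()
  truth <- list()
  for (g in seq_len(nrow(config$groups))) {
    grp <- config$groups[g, ]
    glab <- paste(grp$strain, grp$sex, grp$age_weeks, sep = "_")
    for (i in seq_len(config$n_flies)) {
      fly_id <- sprintf("%s_f%02d", glab, i)
      sim <- simulate_fly_minutes(
        config, grp, seed = substream_seed(config$seed, fly_id)
      )
      tc <- structure(
        tibble(
          monitor = glab,
          datetime = sim$series$datetime,
          status = 1L, flagged = FALSE,
          tube = i, count = sim$series$count
        ),
        class = c("tube_counts", class(tibble()))
      )
      win <- extract_analysis_window(tc, config$schedule,
                                     acclimation_hours, window_hours)
      win$fly_id <- fly_id
      win$strain <- grp$strain
      win$sex <- grp$sex
      win$age_weeks <- grp$age_weeks
      all_series[[fly_id]] <- win
      truth[[fly_id]] <- dplyr::bind_cols(tibble(fly_id = fly_id), grp)
    }
  }
  series <- bind_rows(all_series)
  structure_attrs <- attributes(all_series[[1]])
  attr(series, "schedule") <- structure_attrs$schedule
  attr(series, "window_start") <- structure_attrs$window_start
  attr(series, "window_minutes") <- structure_attrs$window_minutes
  class(series) <- c("fly_series", class(tibble()))
  list(series = series, truth = bind_rows(truth))
}

#' Write a simulated cohort as DAM monitor files
#'
#' Simulates every tube of every monitor and writes per-beam DAM-dialect
#' files (each minute's per-tube count split multinomially over the beams,
#' conserving the total), together with a ground-truth CSV and the
#' configuration as a YAML file. The configured fractions of dead flies
#' (counts cease at a drawn death minute) and empty tubes (all-zero) are
#' included, assigned deterministically from the master seed.
#'
#' @inheritParams simulate_fly_minutes
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `files` (monitor file paths), `assignments`
#'   (tibble mapping monitor/tube to group and fate), `truth_file`,
#'   `config_file`.
#' @export
simulate_cohort_to_dam_files <- function(config, out_dir) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config object.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_min <- as.integer(round(config$recording_hours * 60))
  total_flies <- nrow(config$groups) * config$n_flies
  n_monitors <- ceiling(total_flies / config$tubes_per_monitor)

  assignments <- tidyr::expand_grid(
    g = seq_len(nrow(config$groups)), i = seq_len(config$n_flies)
  ) |>
    mutate(
      slot = dplyr::row_number(),
      monitor = sprintf("monitor_%02d", (.data$slot - 1L) %/%
                          config$tubes_per_monitor + 1L),
      tube = (.data$slot - 1L) %% config$tubes_per_monitor + 1L
    )
  assignments <- dplyr::bind_cols(
    assignments,
    config$groups[assignments$g,
                  c("strain", "sex", "age_weeks",
                    "activity_mult", "ramp_mult", "sleep_mult")]
  )
  fate <- with_seed(substream_seed(config$seed, "tube_fates"), {
    u <- runif(nrow(assignments))
    death_frac <- runif(nrow(assignments), 0.3, 0.6)
    tibble(
      empty = u < config$empty_tube_fraction,
      dead = !(u < config$empty_tube_fraction) &
        u < config$empty_tube_fraction + config$dead_fly_fraction,
      death_minute = as.integer(round(death_frac * n_min))
    )
  })
  assignments <- dplyr::bind_cols(assignments, fate)
  assignments$fly_id <- sprintf("%s_t%02d", assignments$monitor,
                                assignments$tube)

  files <- character(0)
  for (m in unique(assignments$monitor)) {
    rows <- filter(assignments, .data$monitor == m)
    counts <- matrix(
      0L, nrow = n_min,
      ncol = config$tubes_per_monitor * config$beams_per_tube
    )
    for (r in seq_len(nrow(rows))) {
      tube <- rows$tube[r]
      if (rows$empty[r]) next
      sim <- simulate_fly_minutes(
        config, rows[r, ], seed = substream_seed(config$seed, rows$fly_id[r])
      )
      tube_counts <- sim$series$count
      if (rows$dead[r]) {
        tube_counts[seq_len(n_min) > rows$death_minute[r]] <- 0L
      }
      beams <- with_seed(
        substream_seed(config$seed, paste0(rows$fly_id[r], "_beams")),
        split_counts_over_beams(tube_counts, config$beams_per_tube)
      )
      cols <- (tube - 1L) * config$beams_per_tube + seq_len(config$beams_per_tube)
      counts[, cols] <- beams
    }
    path <- file.path(out_dir, paste0(m, ".txt"))
    write_dam_file(counts, config$start_datetime, path)
    files <- c(files, path)
  }

  truth_file <- file.path(out_dir, "ground_truth.csv")
  readr::write_csv(assignments, truth_file)
  config_file <- file.path(out_dir, "sim_config.yaml")
  yaml::write_yaml(config_as_list(config), config_file)
  invisible(list(files = files, assignments = assignments,
                 truth_file = truth_file, config_file = config_file))
}

# Multinomial split of each minute's tube count over the beams.
split_counts_over_beams <- function(tube_counts, beams_per_tube) {
  out <- matrix(0L, nrow = length(tube_counts), ncol = beams_per_tube)
  nz <- which(tube_counts > 0L)
  if (length(nz)) {
    # rmultinom sizes differ per minute, so loop over active minutes
    for (j in seq_along(nz)) {
      out[nz[j], ] <- as.integer(
        rmultinom(1L, size = tube_counts[nz[j]],
                  prob = rep(1 / beams_per_tube, beams_per_tube))
      )
    }
  }
  out
}

# Serialise a sim_config into plain lists for YAML output.
config_as_list <- function(config) {
  out <- unclass(config)
  out$groups <- lapply(seq_len(nrow(config$groups)), function(i) {
    as.list(config$groups[i, ])
  })
  out$schedule <- unclass(config$schedule)
  out$start_datetime <- format(config$start_datetime, tz = "UTC")
  out$wake_run_mean <- as.list(config$wake_run_mean)
  out$sleep_run_mean <- as.list(config$sleep_run_mean)
  out
}

# Write a raw per-beam count matrix as a DAM-dialect monitor file.
write_dam_file <- function(counts, start_datetime, path) {
  n <- nrow(counts)
  stamp <- format_dam_datetime(start_datetime + (seq_len(n) - 1L) * 60)
  body <- cbind(
    seq_len(n), stamp$date, stamp$time, 1L,
    matrix(0L, n, 6L), 0L, counts
  )
  writeLines(apply(body, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Simulate a Gompertz lifespan table
#'
#' Inverse-transform samples from the Gompertz hazard `a * exp(b * t)`
#' (exponential when `b = 0`), one individual per row, with independent
#' censoring: each individual is censored with probability `censor_rate` at
#' a uniform fraction of its drawn death time. The closed-form median of
#' the death-time distribution is `log(1 + b * log(2) / a) / b`
#' (`log(2) / a` when `b = 0`), scaled per group by `hazard_mult`.
#'
#' @inheritParams simulate_fly_minutes
#' @return A tibble of survival records: `id`, `strain`, `sex`,
#'   `age_weeks`, `time` (days), `event` (1 death / 0 censor).
#' @export
simulate_lifespans <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config object.")
  }
  with_seed(substream_seed(config$seed, "lifespans"), {
    rows <- list()
    for (g in seq_len(nrow(config$groups))) {
      grp <- config$groups[g, ]
      a <- config$gompertz_a * (grp$hazard_mult %||% 1)
      b <- config$gompertz_b
      u <- runif(config$n_lifespan)
      t_death <- if (b > 0) log(1 - (b / a) * log(u)) / b else -log(u) / a
      censored <- runif(config$n_lifespan) < config$censor_rate
      time <- ifelse(censored, runif(config$n_lifespan) * t_death, t_death)
      if (!is.null(config$scoring_interval_days)) {
        time <- ceiling(time / config$scoring_interval_days) *
          config$scoring_interval_days
      }
      rows[[g]] <- tibble(
        id = sprintf("%s_%s_%dw_%03d", grp$strain, grp$sex, grp$age_weeks,
                     seq_len(config$n_lifespan)),
        strain = grp$strain, sex = grp$sex, age_weeks = grp$age_weeks,
        time = time, event = as.integer(!censored)
      )
    }
    bind_rows(rows)
  })
}

#' Closed-form Gompertz median death time
#'
#' @param a,b Gompertz hazard scale and shape (per day).
#' @return The median of the death-time distribution.
#' @export
gompertz_median <- function(a, b) {
  assert_number(a, "a", lower = 1e-12)
  assert_number(b, "b", lower = 0)
  if (b > 0) log(1 + b * log(2) / a) / b else log(2) / a
}
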