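#' Describe a full activity-monitor experiment
#'
#' A manifest bundles everything one analysis run needs: the monitor files,
#' the per-tube group assignments, the light schedule, the analysis window,
#' and every scoring threshold (surfaced with the standard defaults: 5-min
#' sleep threshold, 3 counts / 180 min viability rule, 30-min bins,
#' 3 h / 6 h anticipation windows, 48-h window after 24-h acclimation).
#' Inconsistencies are reported here, before any computation.
#'
#' @param monitor_files Character vector of monitor file paths.
#' @param assignments Data frame mapping tubes to groups: columns `monitor`
#'   (file base name without extension), `tube`, `strain`, `sex`,
#'   `age_weeks`. Tubes without an assignment (e.g. empty tubes) are
#'   ignored and logged.
#' @param layout A [beam_layout()] for the monitor files.
#' @param schedule A [light_schedule()].
#' @param acclimation_hours,window_hours Analysis window; see
#'   [extract_analysis_window()].
#' @param sleep_threshold Sleep-run threshold in minutes.
#' @param windows An [ai_windows()] definition.
#' @param viability_min_counts,viability_tail_minutes Death-exclusion rule;
#'   see [viability_filter()].
#' @param bin_minutes Bin width for population traces.
#' @param boundary Bout attribution rule; see [attribute_bouts_to_phase()].
#' @param control_age Control age cohort for Dunnett comparisons.
#' @param seed Seed for the Dunnett Monte-Carlo adjustment.
#' @param out_dir Output directory for compiled tables.
#'
#' @return An `experiment_manifest` object.
#' @export
experiment_manifest <- function(monitor_files, assignments, layout,
                                schedule = light_schedule(),
                                acclimation_hours = 24, window_hours = 48,
                                sleep_threshold = 5L,
                                windows = ai_windows(),
                                viability_min_counts = 3L,
                                viability_tail_minutes = 180L,
                                bin_minutes = 30L,
                                boundary = "split",
                                control_age = 2L,
                                seed = 1L,
                                out_dir = NULL) {
  missing_files <- monitor_files[!file.exists(monitor_files)]
  if (length(missing_files)) {
    abort(paste0("Manifest references missing monitor files: ",
                 paste(missing_files, collapse = ", ")))
  }
  assignments <- as_tibble(assignments)
  need <- c("monitor", "tube", "strain", "sex", "age_weeks")
  if (!all(need %in% names(assignments))) {
    abort(paste0("`assignments` must have columns: ",
                 paste(need, collapse = ", ")))
  }
  known_monitors <- sub("\\.[^.]*$", "", basename(monitor_files))
  unknown <- setdiff(unique(assignments$monitor), known_monitors)
  if (length(unknown)) {
    abort(paste0("Assignments reference monitors with no file: ",
                 paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(assignments[, c("monitor", "tube")])) {
    abort("Duplicate (monitor, tube) rows in `assignments`.")
  }
  structure(
    list(
      monitor_files = monitor_files, assignments = assignments,
      layout = layout, schedule = schedule,
      acclimation_hours = acclimation_hours, window_hours = window_hours,
      sleep_threshold = sleep_threshold, windows = windows,
      viability_min_counts = viability_min_counts,
      viability_tail_minutes = viability_tail_minutes,
      bin_minutes = bin_minutes, boundary = boundary,
      control_age = control_age, seed = seed, out_dir = out_dir
    ),
    class = "experiment_manifest"
  )
}

#' Run the full behavioural analysis pipeline
#'
#' End-to-end flow over a manifest: parse every monitor file, sum beams,
#' extract the lights-on-aligned window, exclude flies with flagged status
#' rows or failing the viability rule (all exclusions logged with reasons),
#' compute the per-fly metric tables, and -- where the design supports it --
#' two-way (age x sex) ANOVA per strain and Dunnett comparisons versus the
#' control age cohort per (strain, sex, measure, phase) family. Results are
#' deterministic given the manifest (including its seed).
#'
#' @param manifest An [experiment_manifest()].
#' @param write Write compiled CSV tables and a JSON run summary to
#'   `manifest$out_dir`? Requires `out_dir` to be set.
#'
#' @return A list: `metrics` (per-day long table), `metrics_avg`
#'   (day-averaged), `exclusions`, `anova`, `dunnett`, `summary`.
#' @export
run_behaviour_pipeline <- function(manifest, write = !is.null(manifest$out_dir)) {
  if (!inherits(manifest, "experiment_manifest")) {
    abort("`manifest` must come from experiment_manifest().")
  }
  missing_files <- manifest$monitor_files[!file.exists(manifest$monitor_files)]
  if (length(missing_files)) {
    abort(paste0("Missing monitor files: ",
                 paste(missing_files, collapse = ", ")))
  }

  series_list <- lapply(manifest$monitor_files, function(path) {
    rec <- read_monitor_file(path, manifest$layout)
    extract_analysis_window(
      sum_beams(rec), manifest$schedule,
      manifest$acclimation_hours, manifest$window_hours
    )
  })
  series <- bind_rows(series_list)
  for (a in c("schedule", "window_start", "window_minutes")) {
    attr(series, a) <- attr(series_list[[1]], a)
  }
  class(series) <- c("fly_series", class(tibble()))

  assigned <- dplyr::semi_join(series, manifest$assignments,
                               by = c("monitor", "tube"))
  unassigned <- dplyr::anti_join(
    dplyr::distinct(series, .data$monitor, .data$tube),
    manifest$assignments, by = c("monitor", "tube")
  ) |> mutate(reason = "no group assignment")
  attrs <- attributes(series)
  for (a in c("schedule", "window_start", "window_minutes")) {
    attr(assigned, a) <- attrs[[a]]
  }
  class(assigned) <- c("fly_series", class(tibble()))

  flagged <- assigned |>
    group_by(.data$monitor, .data$tube) |>
    summarise(has_flagged = any(.data$flagged), .groups = "drop") |>
    filter(.data$has_flagged) |>
    mutate(reason = "flagged status rows in analysis window") |>
    select("monitor", "tube", "reason")
  viability <- viability_filter(
    assigned, manifest$viability_min_counts, manifest$viability_tail_minutes
  )
  dead <- viability |>
    filter(!.data$alive) |>
    mutate(reason = sprintf(
      "dead: %d counts in final %d min (< %d)",
      .data$tail_counts, manifest$viability_tail_minutes,
      manifest$viability_min_counts
    )) |>
    select("monitor", "tube", "reason")
  exclusions <- bind_rows(
    select(unassigned, "monitor", "tube", "reason"), flagged, dead
  )

  kept <- dplyr::anti_join(assigned, exclusions, by = c("monitor", "tube"))
  for (a in c("schedule", "window_start", "window_minutes")) {
    attr(kept, a) <- attrs[[a]]
  }
  class(kept) <- c("fly_series", class(tibble()))
  if (!nrow(kept)) {
    abort("No flies survive the exclusion rules; nothing to analyse.")
  }

  metrics <- compute_fly_metrics(
    kept, manifest$sleep_threshold, manifest$windows,
    boundary = manifest$boundary
  ) |>
    left_join(manifest$assignments, by = c("monitor", "tube")) |>
    mutate(fly_id = paste0(.data$monitor, "_t", sprintf("%02d", .data$tube))) |>
    select("fly_id", "monitor", "tube", "strain", "sex", "age_weeks",
           "day", "measure", "phase", "value")
  metrics_avg <- metrics |>
    group_by(.data$fly_id, .data$monitor, .data$tube, .data$strain,
             .data$sex, .data$age_weeks, .data$measure, .data$phase) |>
    summarise(value = per_day_mean(.data$value), .groups = "drop")

  anova_tbl <- behaviour_anova_tables(metrics_avg)
  dunnett_tbl <- behaviour_dunnett_tables(metrics_avg, manifest$control_age,
                                          seed = manifest$seed)

  # hash the run inputs by content, not location, so identical data in a
  # different directory hashes identically
  hash_input <- manifest[setdiff(names(manifest), c("out_dir", "monitor_files"))]
  hash_input$monitor_files <- basename(manifest$monitor_files)
  hash_input$monitor_contents <- unname(vapply(
    manifest$monitor_files, function(f) rlang::hash(readLines(f)), ""
  ))
  summary <- list(
    package_version = as.character(utils::packageVersion("damsleep")),
    manifest_hash = rlang::hash(hash_input),
    seed = manifest$seed,
    n_monitors = length(manifest$monitor_files),
    n_tubes_assigned = nrow(manifest$assignments),
    n_excluded = nrow(exclusions),
    n_flies_analysed = nrow(dplyr::distinct(metrics, .data$fly_id)),
    measures = sort(unique(metrics$measure))
  )

  out <- list(
    metrics = metrics, metrics_avg = metrics_avg, exclusions = exclusions,
    anova = anova_tbl, dunnett = dunnett_tbl, summary = summary
  )
  if (write) {
    if (is.null(manifest$out_dir)) {
      abort("Set `out_dir` in the manifest to write outputs.")
    }
    write_pipeline_outputs(out, manifest$out_dir)
  }
  invisible(out)
}

# One two-way (age x sex) ANOVA per strain, measure and phase, where the
# design has >= 2 ages and sexes and a replicated full grid.
behaviour_anova_tables <- function(metrics_avg) {
  combos <- metrics_avg |>
    dplyr::distinct(.data$strain, .data$measure, .data$phase)
  res <- purrr::pmap(combos, function(strain, measure, phase) {
    d <- filter(metrics_avg, .data$strain == !!strain,
                .data$measure == !!measure, .data$phase == !!phase,
                !is.na(.data$value))
    if (length(unique(d$age_weeks)) < 2L || length(unique(d$sex)) < 2L) {
      return(NULL)
    }
    cells <- table(d$age_weeks, d$sex)
    if (any(cells < 2L)) {
      return(NULL)
    }
    two_way_anova(d, "value", "age_weeks", "sex") |>
      mutate(strain = strain, measure = measure, phase = phase,
             .before = 1L)
  })
  bind_rows(res)
}

# Dunnett many-to-one age comparisons versus the control age, one family
# per (strain, sex, measure, phase) panel.
behaviour_dunnett_tables <- function(metrics_avg, control_age, seed = 1L,
                                     n_mc = 1e5) {
  combos <- metrics_avg |>
    dplyr::distinct(.data$strain, .data$sex, .data$measure, .data$phase)
  res <- purrr::pmap(combos, function(strain, sex, measure, phase) {
    d <- filter(metrics_avg, .data$strain == !!strain, .data$sex == !!sex,
                .data$measure == !!measure, .data$phase == !!phase,
                !is.na(.data$value))
    ages <- unique(d$age_weeks)
    if (!control_age %in% ages || length(ages) < 2L ||
        any(table(d$age_weeks) < 2L)) {
      return(NULL)
    }
    dunnett_test(d, "value", "age_weeks", control = control_age,
                 n_mc = n_mc,
                 seed = substream_seed(seed, paste(strain, sex, measure,
                                                   phase))) |>
      mutate(strain = strain, sex = sex, measure = measure, phase = phase,
             stars = significance_stars(.data$p.adjusted), .before = 1L)
  })
  bind_rows(res)
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in unique(out$metrics$measure)) {
    readr::write_csv(
      filter(out$metrics, .data$measure == m),
      file.path(out_dir, paste0("measure_", m, ".csv"))
    )
  }
  readr::write_csv(out$metrics_avg, file.path(out_dir, "metrics_day_averaged.csv"))
  readr::write_csv(out$exclusions, file.path(out_dir, "excluded_flies.csv"))
  if (nrow(out$anova %||% tibble())) {
    readr::write_csv(out$anova, file.path(out_dir, "anova_results.csv"))
  }
  if (nrow(out$dunnett %||% tibble())) {
    readr::write_csv(out$dunnett, file.path(out_dir, "dunnett_results.csv"))
  }
  jsonlite::write_json(out$summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Run the lifespan analysis pipeline
#'
#' Produces the full survival results bundle for a strain-by-sex cohort:
#' Kaplan-Meier curves and median lifespans per (strain, sex), percent
#' decreases in median lifespan of males versus females within each strain,
#' all pairwise log-rank tests between sexes within strain and between
#' strains within sex, and the Cox proportional-hazards likelihood-ratio
#' test for the sex-by-strain interaction.
#'
#' @param records A data frame of survival records (or a CSV path) with
#'   columns `time` (days), `event` (1 death / 0 censor), `strain`, `sex`.
#' @param out_dir Optional output directory for CSV results.
#' @param reference_sex Sex used as the reference for percent decreases
#'   (default `"F"`).
#' @return A list: `curves`, `medians` (with percent decreases), `logrank`
#'   (pairwise tests), `cox` (the interaction test tibble), `cox_fit`.
#' @export
run_survival_pipeline <- function(records, out_dir = NULL,
                                  reference_sex = "F") {
  if (is.character(records) && length(records) == 1L) {
    if (!file.exists(records)) {
      abort(sprintf("Survival records file not found: %s", records))
    }
    records <- readr::read_csv(records, show_col_types = FALSE)
  }
  records <- as_tibble(records)
  for (v in c("time", "event", "strain", "sex")) {
    if (!v %in% names(records)) {
      abort(sprintf("Survival records must have a `%s` column.", v))
    }
  }
  n_strain <- length(unique(records$strain))
  n_sex <- length(unique(records$sex))
  if (n_strain < 2L || n_sex < 2L) {
    abort("The interaction model needs >= 2 strains and >= 2 sexes.")
  }

  curves <- km_fit(records, by = c("strain", "sex"))
  medians <- median_lifespan(curves)
  med_wide <- medians |>
    tidyr::pivot_wider(names_from = "sex", values_from = "median")
  other_sexes <- setdiff(unique(records$sex), reference_sex)
  pct <- med_wide |>
    tidyr::pivot_longer(all_of(other_sexes), names_to = "sex",
                        values_to = "median") |>
    mutate(pct_decrease_vs_reference = percent_median_decrease(
      .data[[reference_sex]], .data$median
    )) |>
    select("strain", "sex", "median", "pct_decrease_vs_reference")
  medians <- left_join(medians, select(pct, -"median"),
                       by = c("strain", "sex"))

  pairwise <- list()
  for (st in unique(records$strain)) {
    d <- filter(records, .data$strain == st)
    sexes <- sort(unique(d$sex))
    for (pair in utils::combn(sexes, 2L, simplify = FALSE)) {
      lr <- log_rank_test(filter(d, .data$sex %in% pair), group = "sex")
      pairwise[[length(pairwise) + 1L]] <- tibble(
        comparison = "sexes within strain", stratum = st,
        group1 = pair[1], group2 = pair[2],
        statistic = lr$statistic, df = lr$df, p.value = lr$p.value
      )
    }
  }
  for (sx in unique(records$sex)) {
    d <- filter(records, .data$sex == sx)
    strains <- sort(unique(d$strain))
    for (pair in utils::combn(strains, 2L, simplify = FALSE)) {
      lr <- log_rank_test(filter(d, .data$strain %in% pair), group = "strain")
      pairwise[[length(pairwise) + 1L]] <- tibble(
        comparison = "strains within sex", stratum = sx,
        group1 = pair[1], group2 = pair[2],
        statistic = lr$statistic, df = lr$df, p.value = lr$p.value
      )
    }
  }
  logrank <- bind_rows(pairwise)

  cox <- cox_interaction_test(records, a = "sex", b = "strain")

  out <- list(
    curves = curves, medians = medians, logrank = logrank,
    cox = cox$test, cox_fit = cox$full
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(curves, file.path(out_dir, "km_curves.csv"))
    readr::write_csv(medians, file.path(out_dir, "median_lifespans.csv"))
    readr::write_csv(logrank, file.path(out_dir, "logrank_tests.csv"))
    readr::write_csv(
      dplyr::bind_cols(tibble(test = "sex:strain interaction LR"), cox$test),
      file.path(out_dir, "cox_interaction.csv")
    )
  }
  out
}
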