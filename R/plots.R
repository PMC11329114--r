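#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_ribbon
#'   geom_rect labs theme_minimal annotate scale_x_continuous
NULL

#' Plot a population trace in time bins
#'
#' Mean +/- SEM trace across flies over the 24-h cycle, with the dark phase
#' shaded.
#'
#' @param object A `binned_trace` from [bin_trace()].
#' @param photoperiod_hours Hours of light, for the night shading.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binned_trace <- function(object, photoperiod_hours = 12, ...) {
  value <- attr(object, "value") %||% "activity"
  bin_minutes <- attr(object, "bin_minutes") %||% 30
  ylab <- if (value == "sleep") {
    sprintf("Sleep (min / %d-min bin)", bin_minutes)
  } else {
    sprintf("Activity (counts / %d-min bin)", bin_minutes)
  }
  ggplot(object, aes(x = .data$zt, y = .data$mean)) +
    annotate("rect",
      xmin = photoperiod_hours, xmax = 24, ymin = -Inf, ymax = Inf,
      alpha = 0.12
    ) +
    geom_ribbon(aes(ymin = .data$mean - .data$sem,
                    ymax = .data$mean + .data$sem), alpha = 0.3) +
    geom_line() +
    scale_x_continuous(breaks = seq(0, 24, 6)) +
    labs(x = "Zeitgeber time (h)", y = ylab) +
    theme_minimal()
}

#' Plot Kaplan-Meier survival curves
#'
#' @param object A `km_curve` from [km_fit()].
#' @param ... Unused.
#' @return A ggplot object (one step curve per group, if grouped).
#' @export
autoplot.km_curve <- function(object, ...) {
  by <- attr(object, "by")
  d <- as_tibble(object)
  if (!is.null(by)) {
    d$group <- interaction(d[by], sep = " / ")
    p <- ggplot(d, aes(x = .data$time, y = .data$surv,
                       colour = .data$group)) +
      labs(colour = paste(by, collapse = " / "))
  } else {
    p <- ggplot(d, aes(x = .data$time, y = .data$surv))
  }
  p +
    geom_step() +
    labs(x = "Time (days)", y = "Survival proportion") +
    ggplot2::ylim(0, 1) +
    theme_minimal()
}

#' Plot one fly's activity trace
#'
#' Thin per-minute activity trace with the dark phases shaded; mainly a
#' diagnostic view of a single tube.
#'
#' @param object A `fly_series` (filtered to one fly).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fly_series <- function(object, ...) {
  ids <- fly_id_cols(object)
  if (nrow(dplyr::distinct(object[ids])) > 1L) {
    warn("Multiple flies in series; plotting the binned population trace instead.")
    return(autoplot(bin_trace(object)))
  }
  sched <- attr(object, "schedule") %||% light_schedule()
  nights <- filter(object, .data$phase == "night")
  ggplot(object, aes(x = .data$minute / 60, y = .data$count)) +
    annotate("rect",
      xmin = nights$minute[which(diff(c(-10, nights$minute)) > 1)] / 60,
      xmax = nights$minute[which(diff(c(nights$minute, max(object$minute) + 10)) > 1)] / 60,
      ymin = -Inf, ymax = Inf, alpha = 0.12
    ) +
    geom_line(linewidth = 0.2) +
    labs(x = "Hours from window start", y = "Counts / min") +
    theme_minimal()
}
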