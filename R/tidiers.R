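#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Cox proportional-hazards fit
#'
#' @param x A `cox_ph` fit.
#' @param exponentiate Report hazard ratios instead of log-hazard
#'   coefficients?
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic` (Wald z), `p.value`.
#' @export
tidy.cox_ph <- function(x, exponentiate = FALSE, ...) {
  z <- x$coefficients / x$se
  est <- if (exponentiate) exp(x$coefficients) else x$coefficients
  tibble(
    term = names(x$coefficients),
    estimate = unname(est),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' Model-level summary of a Cox fit
#'
#' @param x A `cox_ph` fit.
#' @param ... Unused.
#' @return A one-row tibble: sample sizes, log-likelihoods, the
#'   likelihood-ratio test against the null model, and the score test.
#' @export
glance.cox_ph <- function(x, ...) {
  lr <- 2 * (x$loglik[["model"]] - x$loglik[["null"]])
  df <- length(x$coefficients)
  tibble(
    n = x$n, n_events = x$n_events,
    loglik_null = x$loglik[["null"]], loglik = x$loglik[["model"]],
    statistic_lr = lr, df = df,
    p.value_lr = pchisq(lr, df, lower.tail = FALSE),
    statistic_score = x$score,
    iter = x$iter
  )
}

#' @export
tidy.km_curve <- function(x, ...) {
  as_tibble(x)
}

#' Group-level summary of Kaplan-Meier curves
#'
#' @param x A `km_curve`.
#' @param ... Unused.
#' @return One row per group: subjects, events, and median lifespan.
#' @export
glance.km_curve <- function(x, ...) {
  by <- attr(x, "by")
  med <- suppressWarnings(median_lifespan(x))
  counts <- if (is.null(by)) {
    summarise(as_tibble(x),
      n = max(.data$n_risk),
      n_events = sum(.data$n_event)
    )
  } else {
    as_tibble(x) |>
      group_by(across(all_of(by))) |>
      summarise(n = max(.data$n_risk), n_events = sum(.data$n_event),
                .groups = "drop")
  }
  if (is.null(by)) dplyr::bind_cols(counts, med) else left_join(counts, med, by = by)
}

#' @export
glance.log_rank_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p.value = x$p.value,
    n = x$n, n_events = x$n_events
  )
}

#' @export
tidy.log_rank_test <- function(x, ...) {
  tibble(
    group = names(x$observed),
    observed = unname(x$observed),
    expected = unname(x$expected)
  )
}
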