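#' Two-way fixed-effects ANOVA with Type II sums of squares
#'
#' Tests the two main effects and their interaction for a fully crossed
#' two-factor design. Sums of squares are Type II (each main effect adjusted
#' for the other, the interaction adjusted for both), computed as residual
#' sum-of-squares differences between nested [stats::lm()] fits; F
#' statistics use the full-model residual mean square. For balanced designs
#' Type II coincides with the sequential and marginal decompositions.
#'
#' @param data Data frame with one row per fly.
#' @param response Name of the numeric response column.
#' @param factor_a,factor_b Names of the two factor columns (e.g. age cohort
#'   and sex).
#'
#' @return A tidy tibble with one row per term (`factor_a`, `factor_b`,
#'   `interaction`, `residuals`): `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  for (v in c(response, factor_a, factor_b)) {
    if (!v %in% names(data)) abort(sprintf("`data` must have a `%s` column.", v))
  }
  d <- tibble(
    y = as.numeric(data[[response]]),
    a = factor(data[[factor_a]]),
    b = factor(data[[factor_b]])
  )
  d <- filter(d, !is.na(.data$y))
  if (nlevels(droplevels(d$a)) < 2L || nlevels(droplevels(d$b)) < 2L) {
    abort("Both factors need at least two observed levels.")
  }
  d$a <- droplevels(d$a)
  d$b <- droplevels(d$b)
  cell_n <- table(d$a, d$b)
  if (any(cell_n == 0)) {
    empty <- which(cell_n == 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Empty design cell: %s = %s, %s = %s.",
      factor_a, rownames(cell_n)[empty[1]], factor_b, colnames(cell_n)[empty[2]]
    ))
  }

  rss <- function(f) sum(stats::resid(lm(f, data = d))^2)
  rss_full <- rss(y ~ a * b)
  rss_ab <- rss(y ~ a + b)
  ss_a <- rss(y ~ b) - rss_ab
  ss_b <- rss(y ~ a) - rss_ab
  ss_int <- rss_ab - rss_full

  df_a <- nlevels(d$a) - 1L
  df_b <- nlevels(d$b) - 1L
  df_int <- df_a * df_b
  df_res <- nrow(d) - nlevels(d$a) * nlevels(d$b)
  if (df_res < 1L) {
    abort("No residual degrees of freedom: need replicate observations per cell.")
  }
  ms_res <- rss_full / df_res
  degenerate <- ms_res <= 1e-12 * max(1, mean(d$y^2))
  term_tbl <- tibble(
    term = c(factor_a, factor_b, "interaction", "residuals"),
    df = c(df_a, df_b, df_int, df_res),
    sumsq = c(ss_a, ss_b, ss_int, rss_full)
  ) |>
    mutate(
      meansq = .data$sumsq / .data$df,
      statistic = dplyr::if_else(.data$term == "residuals" | degenerate,
                                 NA_real_, .data$meansq / ms_res),
      p.value = pf(.data$statistic, .data$df, df_res, lower.tail = FALSE)
    )
  if (degenerate) {
    warn("Zero residual variance: F statistics undefined (NA).")
  }
  term_tbl
}

# Dunnett contrast correlation matrix for comparisons of each treatment
# level i against the common control c: rho_ij = sqrt(n_i n_j /
# ((n_i + n_c)(n_j + n_c))).
dunnett_correlation <- function(n_treat, n_control) {
  lam <- sqrt(n_treat / (n_treat + n_control))
  R <- tcrossprod(lam)
  diag(R) <- 1
  R
}

# Monte-Carlo draws of max_j |T_j| for the Dunnett many-to-one statistic:
# T = Z / S with Z ~ N(0, R) and S^2 ~ chi^2_df / df shared across
# comparisons (the pooled-variance estimate).
dunnett_max_t_draws <- function(R, df, n_mc, seed = NULL) {
  k <- nrow(R)
  with_seed(seed, {
    L <- chol(R)
    Z <- matrix(rnorm(n_mc * k), n_mc, k) %*% L
    S <- sqrt(rchisq(n_mc, df) / df)
    apply(abs(Z) / S, 1L, max)
  })
}

#' Dunnett many-to-one comparisons against a control group
#'
#' Compares each treatment level of a one-way layout against a designated
#' control (here typically the youngest age cohort), using pooled-variance t
#' statistics and family-wise adjusted p-values from the multivariate t
#' distribution of the contrast vector. The multivariate-t tail probability
#' is evaluated by seed-controlled Monte Carlo (default 10^5 draws), which
#' handles unbalanced correlation structures exactly in distribution; the
#' Monte-Carlo standard error of each adjusted p-value is reported.
#'
#' @param data Data frame with one row per observation.
#' @param response Name of the numeric response column.
#' @param group Name of the grouping column.
#' @param control Control level of `group` that all others are compared to.
#' @param n_mc Number of Monte-Carlo draws for the adjustment.
#' @param seed Seed for the Monte-Carlo draws (local to this call).
#'
#' @return A tibble with one row per non-control level: `level`, `estimate`
#'   (mean difference vs control), `std_error`, `statistic` (t), `df`,
#'   `p.unadjusted` (two-sided pooled t), `p.adjusted` (family-wise),
#'   `mc_se` (Monte-Carlo error of `p.adjusted`).
#' @export
dunnett_test <- function(data, response, group, control,
                         n_mc = 1e5, seed = 1L) {
  for (v in c(response, group)) {
    if (!v %in% names(data)) abort(sprintf("`data` must have a `%s` column.", v))
  }
  d <- tibble(y = as.numeric(data[[response]]),
              g = as.character(data[[group]]))
  d <- filter(d, !is.na(.data$y))
  levels_all <- unique(d$g)
  if (!as.character(control) %in% levels_all) {
    abort(sprintf("Control level \"%s\" not present in `%s`.", control, group))
  }
  control <- as.character(control)
  treat <- setdiff(levels_all, control)
  if (!length(treat)) {
    abort("At least one non-control level is required.")
  }
  stats_by <- d |>
    group_by(.data$g) |>
    summarise(n = dplyr::n(), m = mean(.data$y),
              ss = sum((.data$y - mean(.data$y))^2), .groups = "drop")
  df <- sum(stats_by$n) - nrow(stats_by)
  if (df < 1L) {
    abort("Pooled residual variance needs replicate observations.")
  }
  s2 <- sum(stats_by$ss) / df
  if (s2 <= 0) {
    abort("Zero pooled variance: t statistics undefined.")
  }
  ctrl <- filter(stats_by, .data$g == control)
  trt <- stats_by[match(treat, stats_by$g), ]
  est <- trt$m - ctrl$m
  se <- sqrt(s2 * (1 / trt$n + 1 / ctrl$n))
  tstat <- est / se
  p_unadj <- 2 * pt(-abs(tstat), df)
  if (length(treat) == 1L) {
    # a single comparison needs no multiplicity adjustment: the
    # multivariate-t family collapses to the ordinary two-sided t
    p_adj <- p_unadj
    mc_se <- 0
  } else {
    R <- dunnett_correlation(trt$n, ctrl$n)
    maxt <- dunnett_max_t_draws(R, df, n_mc = as.integer(n_mc), seed = seed)
    p_adj <- vapply(abs(tstat), function(t0) mean(maxt >= t0), 0)
    # multiplicity can only increase p; guard the MC estimate against
    # undershooting the single-comparison p at small |t|
    p_adj <- pmax(p_adj, p_unadj)
    mc_se <- sqrt(p_adj * (1 - p_adj) / length(maxt))
  }
  tibble(
    level = treat,
    estimate = est,
    std_error = se,
    statistic = tstat,
    df = df,
    p.unadjusted = p_unadj,
    p.adjusted = p_adj,
    mc_se = mc_se
  )
}

#' Dunnett family-wise critical value
#'
#' Two-sided critical value `c` with `P(max_j |T_j| >= c) = alpha` under the
#' global null, estimated from the same Monte-Carlo scheme as
#' [dunnett_test()]. Useful for simulation studies of family-wise error.
#'
#' @param n_treat Integer vector of treatment-group sizes.
#' @param n_control Control-group size.
#' @param df Residual degrees of freedom of the pooled variance.
#' @param alpha Family-wise error rate.
#' @inheritParams dunnett_test
#' @return The critical value (a single number).
#' @export
dunnett_critical <- function(n_treat, n_control, df, alpha = 0.05,
                             n_mc = 1e5, seed = 1L) {
  R <- dunnett_correlation(n_treat, n_control)
  maxt <- dunnett_max_t_draws(R, df, n_mc = as.integer(n_mc), seed = seed)
  unname(stats::quantile(maxt, 1 - alpha, type = 8))
}

#' Bonferroni adjustment of p-values
#'
#' `min(1, m * p)` for each of the `m` p-values.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues < 0 | pvalues > 1)) {
    abort("`pvalues` must be numbers in [0, 1].")
  }
  p.adjust(pvalues, method = "bonferroni")
}

#' Significance stars at conventional thresholds
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `****` below 1e-4, `***` below 1e-3, `**`
#'   below 0.01, `*` below 0.05, `""` otherwise.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}
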