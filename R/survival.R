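normalise_event <- function(event) {
  if (is.character(event) || is.factor(event)) {
    ev <- as.character(event)
    if (!all(ev %in% c("death", "censor"))) {
      abort("`event` strings must be \"death\" or \"censor\".")
    }
    return(as.integer(ev == "death"))
  }
  if (!all(event %in% c(0, 1))) {
    abort("`event` must be 0/1 (censor/death) or \"death\"/\"censor\".")
  }
  as.integer(event)
}

check_survival_records <- function(data, time, event) {
  if (!all(c(time, event) %in% names(data))) {
    abort(sprintf("`data` must have columns `%s` and `%s`.", time, event))
  }
  if (!nrow(data)) {
    abort("No survival records supplied.")
  }
  if (any(data[[time]] <= 0 | is.na(data[[time]]))) {
    abort("All event times must be positive.")
  }
  invisible(data)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate of the survivor function: at each distinct death
#' time the curve steps down by the factor `1 - d/n`; censored subjects
#' leave the risk set without a step.
#'
#' @param data Data frame of survival records, one row per individual.
#' @param time Name of the column of event times (days).
#' @param event Name of the event column: 1/`"death"` for deaths,
#'   0/`"censor"` for censored exits.
#' @param by Optional character vector of grouping columns (e.g.
#'   `c("strain", "sex")`), giving one curve per group.
#'
#' @return A `km_curve` tibble with (per group) one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_fit <- function(data, time = "time", event = "event", by = NULL) {
  check_survival_records(data, time, event)
  dat <- tibble(
    .time = data[[time]],
    .event = normalise_event(data[[event]])
  )
  if (!is.null(by)) {
    dat <- dplyr::bind_cols(data[by], dat)
  }
  one_curve <- function(d) {
    # with no deaths the product-limit curve is flat at 1 (censor marks only)
    tt <- sort(unique(d$.time))
    n_risk <- vapply(tt, function(t) sum(d$.time >= t), 0L)
    n_event <- vapply(tt, function(t) sum(d$.time == t & d$.event == 1L), 0L)
    n_censor <- vapply(tt, function(t) sum(d$.time == t & d$.event == 0L), 0L)
    tibble(
      time = tt, n_risk = n_risk, n_event = n_event, n_censor = n_censor,
      surv = cumprod(1 - n_event / n_risk)
    )
  }
  out <- if (is.null(by)) {
    one_curve(dat)
  } else {
    dat |>
      group_by(across(all_of(by))) |>
      dplyr::group_modify(~ one_curve(.x)) |>
      ungroup()
  }
  structure(out, by = by, class = c("km_curve", class(tibble())))
}

#' Median lifespan from a Kaplan-Meier curve
#'
#' The median is the smallest observed event time at which the survivor
#' function reaches 0.5 or below (the usual product-limit convention). If
#' the curve never falls to 0.5 the median is undefined (`NA`) and a
#' warning is issued.
#'
#' @param curve A `km_curve` tibble from [km_fit()].
#' @return A tibble with the grouping columns (if any) and `median` (days).
#' @export
median_lifespan <- function(curve) {
  if (!inherits(curve, "km_curve")) {
    abort("`curve` must come from km_fit().")
  }
  by <- attr(curve, "by")
  one <- function(d) {
    hit <- which(d$surv <= 0.5 + 1e-12 & d$n_event > 0)
    tibble(median = if (length(hit)) d$time[hit[1]] else NA_real_)
  }
  out <- if (is.null(by)) {
    one(curve)
  } else {
    curve |>
      group_by(across(all_of(by))) |>
      dplyr::group_modify(~ one(.x)) |>
      ungroup()
  }
  if (anyNA(out$median)) {
    warn("Survival never reaches 0.5 for some groups; median undefined (NA).")
  }
  out
}

#' Percent decrease in median lifespan
#'
#' `100 * (reference - comparison) / reference`; negative values indicate a
#' longer-lived comparison group and are preserved with their sign.
#'
#' @param reference_median Reference group median lifespan (days), > 0.
#' @param comparison_median Comparison group median lifespan (days).
#' @return Percent decrease (may be negative).
#' @export
percent_median_decrease <- function(reference_median, comparison_median) {
  if (!is.numeric(reference_median) || any(reference_median <= 0)) {
    abort("`reference_median` must be positive.")
  }
  100 * (reference_median - comparison_median) / reference_median
}

#' K-group log-rank test
#'
#' Observed-minus-expected test over the pooled distinct death times: at
#' each death time the expected deaths in group j are `d * n_j / n`, and the
#' chi-square statistic is formed from the observed-minus-expected vector
#' and its hypergeometric variance-covariance, with `k - 1` degrees of
#' freedom.
#'
#' @inheritParams km_fit
#' @param group Name of the grouping column (>= 2 levels).
#' @return A `log_rank_test` object with elements `statistic`, `df`,
#'   `p.value`, `observed`, `expected`, `n`.
#' @export
log_rank_test <- function(data, time = "time", event = "event",
                          group = "group") {
  check_survival_records(data, time, event)
  if (!group %in% names(data)) {
    abort(sprintf("`data` must have a `%s` column.", group))
  }
  g <- factor(data[[group]])
  if (any(table(g) == 0) || nlevels(g) < 2L) {
    abort("Every group must contain at least one subject, and >= 2 groups are required.")
  }
  tt <- data[[time]]
  ev <- normalise_event(data[[event]])
  if (!sum(ev)) {
    abort("Log-rank test requires at least one death.")
  }
  k <- nlevels(g)
  death_times <- sort(unique(tt[ev == 1L]))
  O <- E <- rep(0, k)
  V <- matrix(0, k, k)
  for (t in death_times) {
    at_risk <- tt >= t
    n_t <- sum(at_risk)
    n_tj <- tabulate(g[at_risk], nbins = k)
    dead <- ev == 1L & tt == t
    d_t <- sum(dead)
    d_tj <- tabulate(g[dead], nbins = k)
    O <- O + d_tj
    E <- E + d_t * n_tj / n_t
    if (n_t > 1) {
      p <- n_tj / n_t
      vfac <- d_t * (n_t - d_t) / (n_t - 1)
      V <- V + vfac * (diag(p, k) - tcrossprod(p))
    }
  }
  u <- (O - E)[-k]
  Vs <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(
    drop(t(u) %*% solve(Vs, u)),
    error = function(e) {
      sv <- svd(Vs)
      pos <- sv$d > max(sv$d) * 1e-10
      drop(t(u) %*% sv$v[, pos, drop = FALSE] %*%
             ((t(sv$u[, pos, drop = FALSE]) %*% u) / sv$d[pos]))
    }
  )
  structure(
    list(
      statistic = stat, df = k - 1L,
      p.value = pchisq(stat, df = k - 1L, lower.tail = FALSE),
      observed = setNames(O, levels(g)), expected = setNames(E, levels(g)),
      n = length(tt), n_events = sum(ev)
    ),
    class = "log_rank_test"
  )
}

#' @export
print.log_rank_test <- function(x, ...) {
  cat(sprintf(
    "Log-rank test: chi-square = %.4g on %d df, p = %.4g (n = %d, %d deaths)\n",
    x$statistic, x$df, x$p.value, x$n, x$n_events
  ))
  invisible(x)
}

# ---- Cox proportional hazards ------------------------------------------

# Efron (or Breslow) partial log-likelihood with gradient and Hessian.
# X: centred model matrix; times sorted handled internally.
cox_loglik <- function(beta, tt, ev, X, ties = "efron") {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  p <- ncol(X)
  ll <- 0
  grad <- rep(0, p)
  hess <- matrix(0, p, p)
  death_times <- sort(unique(tt[ev == 1L]))
  for (t in death_times) {
    risk <- tt >= t
    dead <- ev == 1L & tt == t
    d <- sum(dead)
    s_r <- sum(w[risk])
    z_r <- drop(crossprod(X[risk, , drop = FALSE], w[risk]))
    q_r <- crossprod(X[risk, , drop = FALSE] * w[risk], X[risk, , drop = FALSE])
    s_d <- sum(w[dead])
    z_d <- drop(crossprod(X[dead, , drop = FALSE], w[dead]))
    q_d <- crossprod(X[dead, , drop = FALSE] * w[dead], X[dead, , drop = FALSE])
    ll <- ll + sum(eta[dead])
    grad <- grad + colSums(X[dead, , drop = FALSE])
    frac <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
    for (f in frac) {
      phi <- s_r - f * s_d
      zeta <- z_r - f * z_d
      qq <- q_r - f * q_d
      ll <- ll - log(phi)
      grad <- grad - zeta / phi
      hess <- hess - (qq / phi - tcrossprod(zeta) / phi^2)
    }
  }
  list(loglik = ll, gradient = grad, hessian = hess)
}

#' Cox proportional-hazards regression
#'
#' Maximises the Cox partial likelihood by Newton-Raphson with step-halving,
#' using the Efron correction for tied death times by default (Breslow
#' available). Standard errors come from the inverse observed information;
#' the likelihood-ratio statistic compares the fitted model to the null.
#'
#' @inheritParams km_fit
#' @param formula One-sided formula of covariate terms, e.g.
#'   `~ sex * strain` for main effects plus interaction.
#' @param ties Tie correction: `"efron"` (default) or `"breslow"`.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the partial log-likelihood change.
#'
#' @return A `cox_ph` object: coefficients, `var` (covariance matrix),
#'   log-likelihoods, the score test at zero, and bookkeeping. Use
#'   [generics::tidy()] / [generics::glance()] for tabular summaries and
#'   [cox_lr_test()] to compare nested fits.
#' @export
cox_ph <- function(data, formula, time = "time", event = "event",
                   ties = c("efron", "breslow"), max_iter = 25L,
                   tol = 1e-9) {
  ties <- match.arg(ties)
  check_survival_records(data, time, event)
  tt <- data[[time]]
  ev <- normalise_event(data[[event]])
  if (!sum(ev)) {
    abort("Cox regression requires at least one death.")
  }
  X <- model.matrix(formula, data = data)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (!ncol(X)) {
    abort("`formula` must contain at least one covariate term.")
  }
  centers <- colMeans(X)
  Xc <- sweep(X, 2L, centers)
  p <- ncol(Xc)

  beta <- rep(0, p)
  at0 <- cox_loglik(beta, tt, ev, Xc, ties)
  ll0 <- at0$loglik
  score_stat <- tryCatch(
    drop(t(at0$gradient) %*% solve(-at0$hessian, at0$gradient)),
    error = function(e) NA_real_
  )
  ll <- ll0
  cur <- at0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(
      solve(-cur$hessian, cur$gradient),
      error = function(e) abort(
        "Cox fit failed: singular information matrix (possible complete separation)."
      )
    )
    step_scale <- 1
    repeat {
      cand <- beta + step_scale * step
      cand_fit <- cox_loglik(cand, tt, ev, Xc, ties)
      if (is.finite(cand_fit$loglik) && cand_fit$loglik >= ll - 1e-12) break
      step_scale <- step_scale / 2
      if (step_scale < 1e-8) {
        abort("Cox fit failed to find an ascent step; fit diagnostics: loglik plateaued.")
      }
    }
    beta <- cand
    improve <- cand_fit$loglik - ll
    ll <- cand_fit$loglik
    cur <- cand_fit
    if (abs(improve) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf(
      "Cox fit did not converge in %d iterations (last loglik change %.3g).",
      max_iter, ll - ll0
    ))
  }
  if (any(abs(beta) > 15)) {
    warn("Very large coefficient magnitude: possible complete separation.")
  }
  vcov <- solve(-cur$hessian)
  se <- sqrt(diag(vcov))
  structure(
    list(
      coefficients = setNames(drop(beta), colnames(X)),
      se = setNames(se, colnames(X)),
      var = vcov,
      loglik = c(null = ll0, model = ll),
      score = score_stat,
      n = length(tt), n_events = sum(ev),
      iter = iter, ties = ties, formula = formula
    ),
    class = "cox_ph"
  )
}

#' @export
print.cox_ph <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties), n = %d, %d deaths\n",
              x$ties, x$n, x$n_events))
  z <- x$coefficients / x$se
  tab <- data.frame(
    coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
    se = x$se, z = z, p = 2 * stats::pnorm(-abs(z)), check.names = FALSE
  )
  print(round(tab, 4))
  invisible(x)
}

#' Likelihood-ratio test between nested Cox fits
#'
#' @param full,reduced `cox_ph` fits of nested models on the same records.
#' @return A tibble: `statistic` (2 * log-likelihood difference), `df`
#'   (difference in parameters), `p.value`.
#' @export
cox_lr_test <- function(full, reduced) {
  if (!inherits(full, "cox_ph") || !inherits(reduced, "cox_ph")) {
    abort("Both arguments must be cox_ph fits.")
  }
  if (full$n != reduced$n || full$n_events != reduced$n_events) {
    abort("The two fits must use the same records.")
  }
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df <= 0) {
    abort("`full` must have more parameters than `reduced`.")
  }
  stat <- 2 * (full$loglik[["model"]] - reduced$loglik[["model"]])
  tibble(
    statistic = stat, df = df,
    p.value = pchisq(stat, df = df, lower.tail = FALSE)
  )
}

#' Test a sex-by-strain (or any two-factor) interaction on survival
#'
#' Fits the full Cox model `~ a * b` and the main-effects model `~ a + b`
#' and reports the likelihood-ratio test of the interaction terms.
#'
#' @inheritParams km_fit
#' @param a,b Names of the two factor columns.
#' @return A list with elements `full`, `reduced` (the `cox_ph` fits) and
#'   `test` (the [cox_lr_test()] tibble).
#' @export
cox_interaction_test <- function(data, a = "sex", b = "strain",
                                 time = "time", event = "event") {
  for (v in c(a, b)) {
    if (!v %in% names(data)) abort(sprintf("`data` must have a `%s` column.", v))
    if (length(unique(data[[v]])) < 2L) {
      abort(sprintf("Factor `%s` must have at least two observed levels.", v))
    }
  }
  f_full <- stats::as.formula(paste("~", a, "*", b))
  f_red <- stats::as.formula(paste("~", a, "+", b))
  full <- cox_ph(data, f_full, time = time, event = event)
  reduced <- cox_ph(data, f_red, time = time, event = event)
  list(full = full, reduced = reduced, test = cox_lr_test(full, reduced))
}
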