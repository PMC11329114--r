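surv_df <- function(time, event, ...) {
  tibble::tibble(time = time, event = event, ...)
}

test_that("Kaplan-Meier curves take uniform steps without censoring", {
  d <- surv_df(1:10, rep(1L, 10))
  km <- km_fit(d)
  expect_equal(km$surv, seq(0.9, 0, by = -0.1))
  expect_equal(km$surv[km$time == 5], 0.5)
  expect_equal(km$n_risk, 10:1)
  # no censoring: equals the empirical survival function
  expect_equal(km$surv, 1 - ecdf(d$time)(km$time))
})

test_that("all-censored data give a flat curve with undefined median", {
  d <- surv_df(c(3, 5, 8), c(0L, 0L, 0L))
  km <- km_fit(d)
  expect_true(all(km$surv == 1))
  expect_warning(med <- median_lifespan(km), "undefined")
  expect_true(is.na(med$median))
})

test_that("KM matches the brute-force product-limit oracle under censoring", {
  set.seed(5)
  for (i in 1:10) {
    n <- 40
    d <- surv_df(sample(1:15, n, replace = TRUE), rbinom(n, 1, 0.7))
    km <- km_fit(d)
    # direct product of (1 - d_i/n_i) over death times <= t
    oracle_surv <- function(t) {
      dt <- sort(unique(d$time[d$event == 1 & d$time <= t]))
      prod(vapply(dt, function(s) {
        1 - sum(d$time == s & d$event == 1) / sum(d$time >= s)
      }, 0))
    }
    expect_equal(km$surv, vapply(km$time, oracle_surv, 0))
  }
})

test_that("KM agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(8)
  d <- surv_df(sample(1:20, 60, replace = TRUE), rbinom(60, 1, 0.6))
  km <- km_fit(d)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  expect_equal(km$surv[km$n_event > 0 | km$n_censor > 0],
               sf$surv, tolerance = 1e-12)
  med <- suppressWarnings(median_lifespan(km))
  expect_equal(med$median, unname(stats::quantile(sf, 0.5)$quantile))
})

test_that("median lifespan follows the first-crossing convention", {
  expect_equal(median_lifespan(km_fit(surv_df(1:10, rep(1L, 10))))$median, 5)
  expect_equal(median_lifespan(km_fit(surv_df(7, 1L)))$median, 7)

  # tie-heavy fixture against a step-function scan oracle
  set.seed(2)
  d <- surv_df(sample(c(2, 2, 2, 5, 5, 9), 30, replace = TRUE), rep(1L, 30))
  km <- km_fit(d)
  scan <- km$time[km$surv <= 0.5][1]
  expect_equal(median_lifespan(km)$median, scan)
})

test_that("percent decrease in median preserves magnitude and sign", {
  expect_equal(percent_median_decrease(100, 50), 50)
  expect_equal(percent_median_decrease(60, 60), 0)
  expect_equal(percent_median_decrease(50, 60), -20)
  expect_error(percent_median_decrease(0, 10), "positive")
})

test_that("log-rank statistic is zero for identical groups", {
  d <- dplyr::bind_rows(
    surv_df(1:10, rep(1L, 10), group = "a"),
    surv_df(1:10, rep(1L, 10), group = "b")
  )
  lr <- log_rank_test(d)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p.value, 1)
})

test_that("log-rank matches the hand-computed 4-subject fixture", {
  # group a: deaths at 1 and 3; group b: death at 2, censor at 4.
  # Pooled death times 1, 2, 3 give O_a = 2, E_a = 0.5 + 1/3 + 0.5 = 4/3,
  # V = 1/4 + 2/9 + 1/4 = 13/18, so chi-square = (2/3)^2 / (13/18) = 8/13.
  d <- dplyr::bind_rows(
    surv_df(c(1, 3), c(1L, 1L), group = "a"),
    surv_df(c(2, 4), c(1L, 0L), group = "b")
  )
  lr <- log_rank_test(d)
  expect_equal(unname(lr$observed["a"]), 2)
  expect_equal(unname(lr$expected["a"]), 4 / 3)
  expect_equal(lr$statistic, (2 / 3)^2 / (13 / 18))
  expect_equal(lr$df, 1L)
})

test_that("log-rank agrees with survdiff and is invariant to rescaling", {
  skip_if_not_installed("survival")
  set.seed(13)
  for (k in 2:3) {
    d <- dplyr::bind_rows(lapply(seq_len(k), function(g) {
      surv_df(rexp(30, rate = 0.1 * g) + 0.01, rbinom(30, 1, 0.8),
              group = letters[g])
    }))
    lr <- log_rank_test(d)
    sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    expect_equal(lr$statistic, sd_fit$chisq, tolerance = 1e-10)
    expect_equal(lr$df, k - 1L)

    # time rescaling leaves the statistic unchanged
    d2 <- dplyr::mutate(d, time = time * 3.7)
    expect_equal(log_rank_test(d2)$statistic, lr$statistic)

    # group relabelling leaves the statistic unchanged
    d3 <- dplyr::mutate(d, group = factor(group, levels = rev(sort(unique(group)))))
    expect_equal(log_rank_test(d3)$statistic, lr$statistic)
  }
})

test_that("log-rank error paths match their contracts", {
  expect_error(log_rank_test(surv_df(numeric(0), integer(0), group = character(0))),
               "No survival records")
  d <- surv_df(1:4, rep(1L, 4), group = rep("a", 4))
  expect_error(log_rank_test(d), ">= 2 groups")
  d0 <- surv_df(1:4, rep(0L, 4), group = rep(c("a", "b"), 2))
  expect_error(log_rank_test(d0), "at least one death")
})

test_that("Cox fit recovers a known hazard ratio and matches coxph", {
  set.seed(21)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t_death <- rexp(n, rate = 0.05 * 2^x)
  cens <- rexp(n, rate = 0.01)
  d <- tibble::tibble(
    time = pmin(t_death, cens) + 1e-9,
    event = as.integer(t_death <= cens),
    x = x
  )
  fit <- cox_ph(d, ~x)
  expect_lt(abs(fit$coefficients[["x"]] - log(2)), 3 * fit$se[["x"]])

  skip_if_not_installed("survival")
  ref <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "efron")
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(stats::vcov(ref)))),
               tolerance = 1e-6)
  expect_equal(fit$loglik[["model"]], ref$loglik[2], tolerance = 1e-8)
})

test_that("Cox and coxph agree with Efron ties on tied data", {
  skip_if_not_installed("survival")
  set.seed(33)
  d <- tibble::tibble(
    time = sample(1:8, 80, replace = TRUE),
    event = rbinom(80, 1, 0.7),
    x = rnorm(80), z = rbinom(80, 1, 0.4)
  )
  fit <- cox_ph(d, ~ x + z)
  ref <- survival::coxph(survival::Surv(time, event) ~ x + z, data = d,
                         ties = "efron")
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-6)
})

test_that("a null covariate is not flagged as significant", {
  set.seed(55)
  n_sig <- 0
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    d <- tibble::tibble(
      time = rexp(100, 0.1) + 1e-9, event = 1L, x = rnorm(100)
    )
    fit <- cox_ph(d, ~x)
    z <- fit$coefficients[["x"]] / fit$se[["x"]]
    if (abs(z) >= 3) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / n_rep, 0.05)
})

test_that("the Cox score test equals the log-rank statistic without ties", {
  set.seed(71)
  d <- tibble::tibble(
    time = rexp(60, 0.1) + runif(60) * 1e-6, # continuous: no ties
    event = rbinom(60, 1, 0.8),
    group = rep(c("a", "b"), 30)
  )
  fit <- cox_ph(d, ~group)
  lr <- log_rank_test(d)
  expect_equal(fit$score, lr$statistic, tolerance = 1e-8)

  # Efron and Breslow coincide on tie-free data
  fit_b <- cox_ph(d, ~group, ties = "breslow")
  expect_equal(fit$coefficients, fit_b$coefficients, tolerance = 1e-9)
})

test_that("nested Cox fits give a likelihood-ratio interaction test", {
  set.seed(91)
  d <- tibble::tibble(
    time = rexp(240, 0.1) + 1e-9, event = 1L,
    sex = rep(c("F", "M"), each = 120),
    strain = rep(rep(c("CS", "Dah", "w1118"), each = 40), 2)
  )
  res <- cox_interaction_test(d)
  expect_equal(res$test$df, 2L)
  expect_gte(res$test$p.value, 0)
  expect_lte(res$test$p.value, 1)
  expect_equal(
    res$test$statistic,
    2 * (res$full$loglik[["model"]] - res$reduced$loglik[["model"]])
  )
  expect_error(
    cox_interaction_test(dplyr::mutate(d, sex = "F")),
    "two observed levels"
  )
})

test_that("tidy and glance methods summarise survival fits", {
  d <- surv_df(c(1:9, 9), c(rep(1L, 9), 0L), group = rep(c("a", "b"), 5))
  km <- km_fit(d, by = "group")
  g <- glance(km)
  expect_equal(nrow(g), 2L)
  expect_true(all(c("n", "n_events", "median") %in% names(g)))

  fit <- cox_ph(d, ~group)
  td <- tidy(fit)
  expect_equal(names(td), c("term", "estimate", "std.error", "statistic",
                            "p.value"))
  gl <- glance(fit)
  expect_equal(gl$n, 10L)
  expect_true(gl$p.value_lr >= 0 && gl$p.value_lr <= 1)

  lr <- log_rank_test(d)
  expect_equal(glance(lr)$statistic, lr$statistic)
})
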