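test_that("risk marker is the linear predictor over selected components", {
  sim <- simulated_integrated(50, c(1, -0.5), seed = 3, censoring = 0.2)
  fit <- fit_cox(sim$data, sim$survival)
  marker <- risk_marker(fit, sim$data)
  expect_equal(unname(marker),
               as.vector(sim$data$scores %*% fit$coefficients))
  # single covariate with b = 1 gives back that column
  fit1 <- fit_cox(sim$data, sim$survival, labels = "C1")
  fit1$coefficients[] <- 1
  expect_equal(unname(risk_marker(fit1, sim$data)),
               unname(sim$data$scores[, "C1"]))
  # empty model: constant zero marker
  fit0 <- fit_cox(sim$data, sim$survival, labels = character(0))
  expect_equal(unname(risk_marker(fit0, sim$data)), rep(0, 50))
})

test_that("without censoring the CD-ROC AUC is the Mann-Whitney statistic", {
  for (s in 1:5) {
    set.seed(900 + s)
    n <- 60
    marker <- rnorm(n)
    time <- rexp(n, exp(0.8 * marker))
    surv <- tiny_survival(time, rep(1, n))
    t_eval <- median(time)
    roc <- cd_roc(marker, surv, t_eval)
    expect_equal(roc$auc,
                 mw_auc(marker[time <= t_eval], marker[time > t_eval]),
                 tolerance = 1e-10)
  }
})

test_that("a perfectly separating marker reaches AUC 1 and a null one stays near 0.5", {
  time <- c(1, 2, 3, 10, 11, 12)
  surv <- tiny_survival(time, rep(1, 6))
  marker <- c(9, 8, 7, 1, 2, 3)   # high risk for the early events
  expect_equal(cd_roc(marker, surv, 5)$auc, 1)

  set.seed(99)
  n <- 1000
  time2 <- rexp(n)
  surv2 <- tiny_survival(time2, rep(1, n))
  auc <- cd_roc(rnorm(n), surv2, median(time2))$auc
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("CD-ROC is invariant to monotone marker transforms and flips with sign", {
  set.seed(7)
  n <- 80
  marker <- rnorm(n)
  time <- rexp(n, exp(marker))
  cens <- rexp(n, 0.3)
  surv <- tiny_survival(pmin(time, cens), as.numeric(time <= cens))
  t_eval <- median(surv$time)
  base <- cd_roc(marker, surv, t_eval)
  trans <- cd_roc(exp(2 * marker) + 5, surv, t_eval)
  expect_equal(trans$auc, base$auc, tolerance = 1e-10)
  flipped <- cd_roc(-marker, surv, t_eval)
  expect_equal(flipped$auc, 1 - base$auc, tolerance = 1e-10)
})

test_that("CD-ROC errors without cases or controls at the horizon", {
  surv <- tiny_survival(c(5, 6, 7), c(1, 1, 1))
  expect_error(cd_roc(c(1, 2, 3), surv, 1), "no observed events")
  expect_error(cd_roc(c(1, 2, 3), surv, 10), "at risk beyond")
})

test_that("sensitivities and specificities are proper monotone curves", {
  set.seed(13)
  n <- 100
  marker <- rnorm(n)
  time <- rexp(n, exp(0.5 * marker))
  cens <- rexp(n, 0.25)
  surv <- tiny_survival(pmin(time, cens), as.numeric(time <= cens))
  roc <- cd_roc(marker, surv, median(surv$time))
  expect_true(all(roc$sensitivity >= 0 & roc$sensitivity <= 1))
  expect_true(all(roc$specificity >= 0 & roc$specificity <= 1))
  # thresholds ascend, so sensitivity falls and specificity rises
  expect_true(all(diff(roc$sensitivity) <= 1e-12))
  expect_true(all(diff(roc$specificity) >= -1e-12))
  expect_gte(roc$auc, 0); expect_lte(roc$auc, 1)
})

test_that("the concordance index reproduces hand-enumerated pairs", {
  # denominator: pairs with T_i > T_j and subject j an event
  surv <- tiny_survival(c(1, 2, 3), c(1, 0, 1))
  expect_equal(harrell_c(c(2, 1, 3), surv), 0.5)
  # perfectly anti-ordered marker (higher risk, shorter survival)
  surv2 <- tiny_survival(1:5, rep(1, 5))
  expect_equal(harrell_c(5:1, surv2), 1)
  expect_equal(harrell_c(1:5, surv2), 0)
  # all censored: no comparable pairs
  expect_error(harrell_c(1:3, tiny_survival(1:3, rep(0, 3))), "comparable")
})

test_that("concordance matches an O(n^2) oracle over many small datasets", {
  oracle_c <- function(marker, time, event, half = TRUE) {
    num <- 0; den <- 0
    for (i in seq_along(time)) for (j in seq_along(time)) {
      if (i != j && event[j] == 1 && time[i] > time[j]) {
        den <- den + 1
        if (marker[i] < marker[j]) num <- num + 1
        else if (half && marker[i] == marker[j]) num <- num + 0.5
      }
    }
    if (den == 0) return(NA_real_)
    num / den
  }
  checked <- 0
  for (s in 1:200) {
    set.seed(3000 + s)
    n <- sample(3:12, 1)
    time <- sample(1:8, n, replace = TRUE) + 0.5
    event <- rbinom(n, 1, 0.7)
    marker <- sample(1:5, n, replace = TRUE) + 0   # ties likely
    expected <- oracle_c(marker, time, event)
    if (is.na(expected)) next
    surv <- tiny_survival(time, event)
    expect_equal(harrell_c(marker, surv), expected, info = paste("seed", s))
    expect_equal(harrell_c(marker, surv, ties = "strict"),
                 oracle_c(marker, time, event, half = FALSE),
                 info = paste("seed", s))
    checked <- checked + 1
  }
  expect_gte(checked, 150)
})

test_that("zero-censoring concordance equals the pairwise Mann-Whitney probability", {
  set.seed(17)
  n <- 40
  marker <- rnorm(n)
  time <- rexp(n, exp(marker))
  surv <- tiny_survival(time, rep(1, n))
  # brute force over all ordered pairs
  num <- 0; den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i != j && time[i] > time[j]) {
      den <- den + 1
      num <- num + (marker[i] < marker[j]) + 0.5 * (marker[i] == marker[j])
    }
  }
  expect_equal(harrell_c(marker, surv), num / den, tolerance = 1e-12)
  # agrees with the survival package's concordance on tie-free data
  cref <- survival::concordance(survival::Surv(time, rep(1, n)) ~ marker,
                                reverse = TRUE)$concordance
  expect_equal(harrell_c(marker, surv), cref, tolerance = 1e-10)
})

test_that("the KM median is the first event time with survival at or below one half", {
  expect_equal(median_survival_time(tiny_survival(1:5, rep(1, 5))), 3)
  # a single subject: the curve drops to zero at the event
  expect_equal(median_survival_time(tiny_survival(4.2, 1)), 4.2)
  # heavy censoring: curve floors above 0.5
  surv <- tiny_survival(c(1, 2, 3, 4, 5), c(1, 0, 0, 0, 0))
  expect_error(median_survival_time(surv), "never reaches")
  # censoring shifts the KM median above the naive sample median
  surv2 <- tiny_survival(c(1, 2, 3, 4, 5, 6), c(1, 0, 0, 1, 1, 1))
  expect_equal(median_survival_time(surv2), 5)
})

test_that("evaluate_model bundles AUC, concordance and the horizon", {
  sim <- simulated_integrated(150, c(0.9), seed = 23, censoring = 0.2)
  fit <- fit_cox(sim$data, sim$survival)
  ev <- evaluate_model(fit, sim$data, sim$survival)
  expect_equal(ev$t_eval, median_survival_time(sim$survival))
  expect_equal(ev$auc, ev$roc$auc)
  expect_gt(ev$auc, 0.5)
  expect_gt(ev$c_index, 0.5)
  ev2 <- evaluate_model(fit, sim$data, sim$survival, t = 1)
  expect_equal(ev2$t_eval, 1)
})
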