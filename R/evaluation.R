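# Evaluation of a fitted risk score on censored survival data:
# cumulative/dynamic time-dependent ROC with IPCW, Harrell's concordance
# index by exact pair enumeration, and the Kaplan-Meier median used as the
# default evaluation horizon.

#' Linear risk marker of a fitted component model
#'
#' The Cox linear predictor `eta = scores %*% coefficients` (no baseline
#' term); higher values mean higher hazard.
#'
#' @param fit a `cox_fit`.
#' @param data the `integrated_dataset` it was fitted on.
#' @return named numeric n-vector.
#' @export
risk_marker <- function(fit, data) {
  stopifnot(inherits(fit, "cox_fit"), inherits(data, "integrated_dataset"))
  if (!all(fit$labels %in% data$labels))
    stop("fit covariates not all present in the dataset: ",
         paste(setdiff(fit$labels, data$labels), collapse = ", "))
  if (length(fit$labels) == 0)
    return(stats::setNames(rep(0, nrow(data$scores)), data$sample_ids))
  eta <- as.vector(data$scores[, fit$labels, drop = FALSE] %*% fit$coefficients)
  stats::setNames(eta, data$sample_ids)
}

# Kaplan-Meier estimate of the censoring survival function G(t) = P(C > t),
# evaluated as a left-continuous step lookup
censoring_km <- function(survival) {
  sf <- survival::survfit(survival::Surv(survival$time, 1 - survival$event) ~ 1)
  list(time = sf$time, surv = sf$surv)
}

km_eval <- function(km, t, left = FALSE) {
  # survival probability at t (left = TRUE gives the left limit G(t-))
  vapply(t, function(tt) {
    idx <- if (left) which(km$time < tt) else which(km$time <= tt)
    if (length(idx) == 0) 1 else km$surv[max(idx)]
  }, numeric(1))
}

#' Cumulative/dynamic time-dependent ROC at a horizon
#'
#' Cases at horizon `t` are subjects with an observed event by `t`
#' (cumulative sensitivity `P(Q > q | T <= t)`); controls are subjects
#' still event-free beyond `t` (dynamic specificity `P(Q <= q | T > t)`).
#' Censoring before `t` is handled by inverse-probability-of-censoring
#' weights from the Kaplan-Meier estimate of the censoring distribution;
#' with no censoring the estimator reduces to the empirical ROC, whose
#' trapezoidal AUC equals the Mann-Whitney statistic between the two
#' groups.
#'
#' @param marker numeric risk marker (higher = higher risk).
#' @param survival a [survival_outcome()].
#' @param t evaluation horizon within the observed time range.
#' @return an object of class `cdroc`: `t`, `thresholds`, `sensitivity`,
#'   `specificity` (aligned to thresholds), `auc`, `n_cases`,
#'   `n_controls`.
#' @export
cd_roc <- function(marker, survival, t) {
  stopifnot(inherits(survival, "survival_outcome"),
            length(marker) == length(survival$time))
  time <- survival$time; event <- survival$event
  is_case <- time <= t & event == 1
  is_control <- time > t
  if (!any(is_case)) stop("no observed events by t = ", t)
  if (!any(is_control)) stop("no subjects still at risk beyond t = ", t)

  G <- censoring_km(survival)
  w <- numeric(length(time))
  gi <- km_eval(G, time[is_case], left = TRUE)   # G(T_i-)
  if (any(gi <= 0)) stop("zero censoring-survival weight at an event time")
  w[is_case] <- 1 / gi
  # control weights 1/G(t) are constant and cancel in the proportions

  qs <- sort(unique(marker))
  thresholds <- c(-Inf, qs)
  sens <- vapply(thresholds, function(q)
    sum(w[is_case & marker > q]) / sum(w[is_case]), numeric(1))
  spec <- vapply(thresholds, function(q)
    sum(is_control & marker <= q) / sum(is_control), numeric(1))

  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  structure(list(t = t, thresholds = thresholds,
                 sensitivity = sens, specificity = spec, auc = auc,
                 n_cases = sum(is_case), n_controls = sum(is_control)),
            class = "cdroc")
}

#' @export
print.cdroc <- function(x, ...) {
  cat(sprintf("cumulative/dynamic ROC at t = %g: AUC %.4f (%d cases, %d controls)\n",
              x$t, x$auc, x$n_cases, x$n_controls))
  invisible(x)
}

#' Export ROC curve points as TSV
#' @param roc a `cdroc`.
#' @param path output TSV path (`threshold`, `sensitivity`,
#'   `one_minus_specificity`).
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "cdroc"))
  df <- data.frame(threshold = roc$thresholds,
                   sensitivity = roc$sensitivity,
                   one_minus_specificity = 1 - roc$specificity)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harrell's concordance index by exact pair enumeration
#'
#' A pair (i, j) is comparable when subject j experienced an event and
#' subject i survived longer (`T_i > T_j`, `d_j = 1`); it is concordant
#' when the longer survivor carries the lower risk (`eta_i < eta_j`).
#' By default marker ties in comparable pairs count one half (the usual
#' Harrell convention); `ties = "strict"` scores them zero, reproducing
#' the bare indicator-function formula.
#'
#' @param marker numeric risk marker (higher = higher risk).
#' @param survival a [survival_outcome()].
#' @param ties `"half"` (default) or `"strict"`.
#' @return concordance index in `[0, 1]`.
#' @export
harrell_c <- function(marker, survival, ties = c("half", "strict")) {
  stopifnot(inherits(survival, "survival_outcome"),
            length(marker) == length(survival$time))
  ties <- match.arg(ties)
  time <- survival$time; event <- survival$event
  num <- 0; den <- 0
  for (j in which(event == 1)) {
    longer <- which(time > time[j])
    den <- den + length(longer)
    num <- num + sum(marker[longer] < marker[j])
    if (ties == "half") num <- num + 0.5 * sum(marker[longer] == marker[j])
  }
  if (den == 0) stop("no comparable pairs (all subjects censored or tied)")
  num / den
}

#' Kaplan-Meier median survival time
#'
#' The smallest observed event time at which the Kaplan-Meier survival
#' estimate drops to 0.5 or below. Used as the default horizon for the
#' cumulative/dynamic ROC because the raw sample median of observed times
#' is biased downward under censoring.
#'
#' @param survival a [survival_outcome()].
#' @return the median survival time.
#' @export
median_survival_time <- function(survival) {
  stopifnot(inherits(survival, "survival_outcome"))
  sf <- survival::survfit(survival::Surv(survival$time, survival$event) ~ 1)
  ok <- which(sf$surv <= 0.5 & sf$n.event > 0)
  if (length(ok) == 0)
    stop("Kaplan-Meier curve never reaches 0.5; supply an explicit evaluation time")
  sf$time[min(ok)]
}

#' Evaluate a fitted model: CD-ROC AUC and concordance
#'
#' @param fit a `cox_fit`.
#' @param data the `integrated_dataset` it was fitted on.
#' @param survival a [survival_outcome()].
#' @param t evaluation horizon; default the Kaplan-Meier median.
#' @return list with `auc`, `c_index`, `t_eval`, `roc` (the `cdroc`
#'   object) and `marker`.
#' @export
evaluate_model <- function(fit, data, survival, t = NULL) {
  marker <- risk_marker(fit, data)
  if (is.null(t)) t <- median_survival_time(survival)
  roc <- cd_roc(marker, survival, t)
  list(auc = roc$auc, c_index = harrell_c(marker, survival),
       t_eval = t, roc = roc, marker = marker)
}
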