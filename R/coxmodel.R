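# Cox proportional-hazards modelling on integrated components.
#
# The hazard model is h(t) = h0(t) exp(b1 c1 + ... + bK cK) over component
# scores; partial-likelihood maximization is delegated to survival::coxph
# (Efron tie correction by default). The stepwise AIC driver, the reporting
# table and the AIC bookkeeping are implemented here.

#' Fit a Cox model on a subset of integrated components
#'
#' @param data an `integrated_dataset`.
#' @param survival a [survival_outcome()] (same samples, same order).
#' @param labels component labels to include; default all. An empty
#'   selection fits the null (intercept-only) model.
#' @param ties tie correction, `"efron"` (default) or `"breslow"`.
#' @return an object of class `cox_fit`: `labels`, `coefficients`, `se`,
#'   `hazard_ratios`, `p_values` (Wald), `loglik` (maximized log partial
#'   likelihood), `aic` (`-2 loglik + 2 * #covariates`), `n`, `n_events`,
#'   `ties`, and the underlying `coxph` object (`fit`, `NULL` for the null
#'   model).
#' @export
fit_cox <- function(data, survival, labels = NULL, ties = c("efron", "breslow")) {
  stopifnot(inherits(data, "integrated_dataset"),
            inherits(survival, "survival_outcome"))
  ties <- match.arg(ties)
  if (!identical(data$sample_ids, survival$sample_ids))
    stop("integrated dataset and survival table have different samples; align first")
  if (is.null(labels)) labels <- data$labels
  if (length(labels) && !all(labels %in% data$labels))
    stop("unknown component label(s): ",
         paste(setdiff(labels, data$labels), collapse = ", "))
  if (sum(survival$event) < 2) stop("need at least 2 observed events")
  y <- survival::Surv(survival$time, survival$event)

  if (length(labels) == 0) {
    null_fit <- survival::coxph(y ~ 1)
    return(structure(list(labels = character(0),
                          coefficients = numeric(0), se = numeric(0),
                          hazard_ratios = numeric(0), p_values = numeric(0),
                          loglik = null_fit$loglik[1],
                          aic = -2 * null_fit$loglik[1],
                          n = length(survival$time),
                          n_events = sum(survival$event),
                          ties = ties, fit = NULL),
                     class = "cox_fit"))
  }

  x <- data$scores[, labels, drop = FALSE]
  fit <- survival::coxph(y ~ x, ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("singular information matrix (collinear covariates): ",
         paste(labels[is.na(co)], collapse = ", "))
  se <- sqrt(diag(fit$var))
  if (any(abs(co) > 50))
    stop("monotone partial likelihood (coefficient diverging) for: ",
         paste(labels[abs(co) > 50], collapse = ", "))
  names(co) <- names(se) <- labels
  structure(list(labels = labels,
                 coefficients = co, se = se,
                 hazard_ratios = exp(co),
                 p_values = stats::setNames(
                   2 * stats::pnorm(-abs(co / se)), labels),
                 loglik = fit$loglik[2],
                 aic = -2 * fit$loglik[2] + 2 * length(labels),
                 n = length(survival$time),
                 n_events = sum(survival$event),
                 ties = ties, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: %d covariates, %d/%d events, logPL %.3f, AIC %.3f\n",
              length(x$labels), x$n_events, x$n, x$loglik, x$aic))
  if (length(x$labels)) {
    print(data.frame(coef = x$coefficients, se = x$se, HR = x$hazard_ratios,
                     p = signif(x$p_values, 3)))
  }
  invisible(x)
}

#' Hazard ratio of a Cox coefficient
#'
#' @param coefficient finite numeric coefficient(s).
#' @return `exp(coefficient)`.
#' @export
hazard_ratio <- function(coefficient) {
  stopifnot(all(is.finite(coefficient)))
  exp(coefficient)
}

#' Bidirectional stepwise selection by AIC
#'
#' Starts from the full model; at each step every single-component removal
#' and addition is scored by AIC and the best move is taken; stops when no
#' move lowers the AIC. Ties are broken deterministically by move order
#' (drops before adds, each in label order). Candidate moves whose fit
#' fails (collinearity, monotone likelihood) are skipped with a note.
#'
#' @inheritParams fit_cox
#' @param trace if `TRUE`, prints each accepted move.
#' @return list with `labels` (selected components, in original order) and
#'   `fit` (the final `cox_fit`); attribute `"path"` records the accepted
#'   moves.
#' @export
stepwise_aic <- function(data, survival, ties = "efron", trace = FALSE) {
  stopifnot(inherits(data, "integrated_dataset"))
  if (ncol(data$scores) < 1) stop("need at least one component")
  all_labels <- data$labels
  current <- all_labels
  fit <- fit_cox(data, survival, current, ties = ties)
  path <- character(0)

  try_fit <- function(labels) {
    tryCatch(fit_cox(data, survival, labels, ties = ties),
             error = function(e) NULL)
  }

  repeat {
    moves <- list()
    for (lab in current)                       # drops, label order
      moves[[paste0("- ", lab)]] <- setdiff(current, lab)
    for (lab in setdiff(all_labels, current))  # adds, label order
      moves[[paste0("+ ", lab)]] <- all_labels[all_labels %in% c(current, lab)]
    if (length(moves) == 0) break
    fits <- lapply(moves, try_fit)
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) break
    aics <- vapply(fits[ok], `[[`, numeric(1), "aic")
    best <- which.min(aics)    # first minimum wins: deterministic tie-break
    if (aics[best] < fit$aic - 1e-8) {
      mv <- names(moves)[ok][best]
      current <- moves[ok][[best]]
      fit <- fits[ok][[best]]
      path <- c(path, sprintf("%s (AIC %.4f)", mv, fit$aic))
      if (trace) message(sprintf("step: %s -> AIC %.4f", mv, fit$aic))
    } else break
  }
  structure(list(labels = current, fit = fit), path = path)
}

#' Report table for a fitted component model
#'
#' One row per selected component: layer, block, block size, number of
#' nonzero loadings, coefficient (SE), hazard ratio, Wald p-value.
#'
#' @param fit a `cox_fit`.
#' @param provenance provenance map from an `integrated_dataset`
#'   (`$provenance`), covering every fitted label.
#' @return a `data.frame`.
#' @export
report_table <- function(fit, provenance) {
  stopifnot(inherits(fit, "cox_fit"))
  missing <- setdiff(fit$labels, names(provenance))
  if (length(missing))
    stop("provenance missing for label(s): ", paste(missing, collapse = ", "))
  do.call(rbind, lapply(fit$labels, function(lab) {
    pv <- provenance[[lab]]
    data.frame(layer = pv$layer_id, component = lab,
               n_variables = pv$block_size,
               n_variables_remained = length(pv$support),
               coefficient = unname(fit$coefficients[lab]),
               se = unname(fit$se[lab]),
               hazard_ratio = unname(fit$hazard_ratios[lab]),
               p_value = unname(fit$p_values[lab]))
  }))
}
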