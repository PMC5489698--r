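#' Administrative right-censoring at a horizon
#'
#' Subjects followed beyond the horizon are censored there (10 years by
#' default, so that sparse very-late follow-up does not dominate tail
#' estimates).
#'
#' @param data Data frame with numeric `time` (years) and logical `event`.
#' @param horizon Censoring horizon in years (> 0); `Inf` is the identity.
#' @return `data` with `time` and `event` updated.
#' @export
censor_at <- function(data, horizon = 10) {
  if (horizon <= 0) stop("horizon must be positive")
  over <- !is.na(data$time) & data$time > horizon
  data$time[over] <- horizon
  data$event[over] <- FALSE
  data
}

check_survival_data <- function(data) {
  if (!all(c("time", "event") %in% names(data))) {
    stop("data needs `time` and `event` columns")
  }
  if (any(data$time < 0, na.rm = TRUE)) stop("negative survival time")
  invisible(data)
}

#' Kaplan-Meier estimate
#'
#' Product-limit survival estimate with Greenwood variance and log-log 95%
#' confidence intervals.
#'
#' @param data Data frame with `time` and `event`.
#' @return Object of class `km_estimate`: data frame with `time`, `n_risk`,
#'   `n_event`, `surv`, `lower`, `upper`; the underlying
#'   [survival::survfit()] object is kept in attribute `fit`.
#' @export
km_estimate <- function(data) {
  check_survival_data(data)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data,
                           conf.type = "log-log")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv,
                    lower = fit$lower, upper = fit$upper)
  structure(out, fit = fit, class = c("km_estimate", "data.frame"))
}

#' Survival probability at given times from a Kaplan-Meier estimate
#'
#' @param km A `km_estimate`.
#' @param t Time(s) in years.
#' @return S(t), right-continuous, with S(0) = 1.
#' @export
km_surv_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1]
}

#' Log-rank test
#'
#' @param data Data frame with `time` and `event`.
#' @param groups Group labels (>= 2 groups).
#' @return List with `statistic` (chi-squared), `df`, `p`.
#' @export
logrank_test <- function(data, groups) {
  check_survival_data(data)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  sd <- survival::survdiff(survival::Surv(data$time, data$event) ~ g)
  df <- nlevels(g) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Interval hazard ratio between two groups
#'
#' Hazard ratio over a restricted interval (0-5 years by default):
#' administratively censors at the interval end, fits a univariate Cox model
#' on the group indicator and reports the Wald 95% CI.
#'
#' @param data Data frame with `time` and `event`.
#' @param groups Two-level group labels; the hazard ratio is second level vs
#'   first (reference) level.
#' @param interval Numeric length-2, default `c(0, 5)` years.
#' @return List with `hr`, `ci_lower`, `ci_upper`, `p`, `n`, `events`.
#' @export
interval_hazard_ratio <- function(data, groups, interval = c(0, 5)) {
  check_survival_data(data)
  g <- factor(groups)
  if (nlevels(g) != 2) stop("exactly two groups required")
  d <- censor_at(data[, c("time", "event")], horizon = interval[2])
  keep <- d$time >= interval[1]
  d <- d[keep, ]
  g <- g[keep]
  if (sum(d$event) == 0) stop("no events in the interval")
  fit <- survival::coxph(survival::Surv(time, event) ~ g, data = d)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  list(hr = exp(beta), ci_lower = exp(beta - 1.96 * se),
       ci_upper = exp(beta + 1.96 * se),
       p = unname(summary(fit)$coefficients[1, "Pr(>|z|)"]),
       n = nrow(d), events = sum(d$event))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Cox regression on the named covariates, complete cases
#' only (missing covariate data are assumed missing completely at random and
#' dropped). Reports hazard ratios with Wald 95% CIs and p-values.
#'
#' @param data Data frame with `time`, `event` and the covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param ties Tie handling: "efron" (default) or "breslow".
#' @return Object of class `cox_fit`: `table` (term, coef, se, hr, ci_lower,
#'   ci_upper, p), `n`, `events`, `ties` and the underlying `coxph` fit in
#'   `$model`.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_survival_data(data)
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, c("time", "event", covariates)]),
            c("time", "event", covariates), drop = FALSE]
  if (!nrow(d)) stop("no complete cases")
  if (sum(d$event) < length(covariates)) {
    warning("fewer events (", sum(d$event), ") than covariates (",
            length(covariates), ")")
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w))) {
        stop("monotone likelihood (complete separation): ",
             conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), coef = sm[, "coef"],
                    se = sm[, "se(coef)"], hr = exp(sm[, "coef"]),
                    ci_lower = exp(sm[, "coef"] - 1.96 * sm[, "se(coef)"]),
                    ci_upper = exp(sm[, "coef"] + 1.96 * sm[, "se(coef)"]),
                    p = sm[, "Pr(>|z|)"], row.names = NULL)
  structure(list(table = tab, n = nrow(d), events = sum(d$event),
                 ties = ties, model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$events))
  print(x$table, digits = 3)
  invisible(x)
}

#' Proportional-hazards test via scaled Schoenfeld residuals
#'
#' Correlation test of the scaled Schoenfeld residuals against time (identity
#' transform by default), per covariate and globally; covariates with
#' p < 0.05 violate proportionality.
#'
#' @param fit A [cox_fit()] object.
#' @param transform Time transform for [survival::cox.zph()] (default
#'   "identity").
#' @return Data frame with `term`, `chisq`, `df`, `p` (last row "GLOBAL")
#'   and a logical `flagged` column (p < 0.05).
#' @export
schoenfeld_ph_test <- function(fit, transform = "identity") {
  if (!inherits(fit, "cox_fit")) stop("fit must be a cox_fit")
  if (fit$events < 3) stop("needs at least 3 events")
  z <- survival::cox.zph(fit$model, transform = transform)
  out <- data.frame(term = rownames(z$table), chisq = z$table[, "chisq"],
                    df = z$table[, "df"], p = z$table[, "p"],
                    row.names = NULL)
  out$flagged <- out$p < 0.05
  out
}

# left-continuous KM value G(t-) of a survfit object
surv_left <- function(fit, t) {
  idx <- findInterval(t - 1e-12, fit$time)
  c(1, fit$surv)[idx + 1]
}

#' Time-dependent ROC AUC (cumulative cases / dynamic controls, IPCW)
#'
#' Discrimination of a marker for events occurring by time `t`:
#' cases are subjects with an event by `t`, controls are subjects still
#' event-free beyond `t`. Censoring is handled by inverse-probability-of-
#' censoring weights from the Kaplan-Meier estimate of the censoring
#' distribution (cases weighted by `1/G(T-)`, controls by `1/G(t)`). The AUC
#' is the weighted probability that a random case has a higher marker value
#' than a random control (ties count one half), and is invariant to strictly
#' monotone marker transforms.
#'
#' @param marker Numeric marker (higher = higher risk).
#' @param data Data frame with `time` and `event` aligned with `marker`.
#' @param t Evaluation time in years (default 5).
#' @return The AUC estimate in \[0, 1\].
#' @export
time_dependent_auc <- function(marker, data, t = 5) {
  check_survival_data(data)
  if (length(marker) != nrow(data)) stop("marker length mismatch")
  keep <- !is.na(marker) & !is.na(data$time) & !is.na(data$event)
  marker <- marker[keep]
  time <- data$time[keep]
  event <- data$event[keep]
  is_case <- time <= t & event
  is_ctrl <- time > t
  if (!any(is_case)) stop("no cases by t = ", t)
  if (!any(is_ctrl)) stop("no controls beyond t = ", t)
  cens_fit <- survival::survfit(
    survival::Surv(time, !event) ~ 1,
    data = data.frame(time = time, event = event))
  w_case <- 1 / pmax(surv_left(cens_fit, time[is_case]), 1e-12)
  w_ctrl <- rep(1 / pmax(surv_left(cens_fit, t), 1e-12), sum(is_ctrl))
  mc <- marker[is_case]
  mk <- marker[is_ctrl]
  cmp <- outer(mc, mk, ">") + 0.5 * outer(mc, mk, "==")
  sum((w_case %o% w_ctrl) * cmp) / (sum(w_case) * sum(w_ctrl))
}

#' Cross-validated forward covariate selection by 5-year AUC
#'
#' Greedy forward selection of prognostic covariates for a Cox model,
#' scored by cross-validated time-dependent AUC: over `rounds` rounds of
#' `folds`-fold cross-validation (folds stratified by event status so every
#' fold contains events), each candidate model is fitted on the training
#' folds and its linear predictor scored on the left-out fold with
#' [time_dependent_auc()] at time `t`. The candidate with the highest mean
#' AUC is added if it improves on the current model's mean AUC by more than
#' `min_gain`; otherwise selection stops. Complete cases on all candidates
#' are used throughout.
#'
#' @param data Data frame with `time`, `event` and numeric/logical candidate
#'   columns.
#' @param candidates Character vector of candidate covariate names.
#' @param rounds Cross-validation rounds (default 100).
#' @param folds Folds per round (default 10).
#' @param t AUC evaluation time in years (default 5).
#' @param min_gain Minimum mean-AUC improvement to accept a covariate
#'   (default 0.005; use 0 for any strict increase).
#' @param seed Optional integer seed controlling all fold shuffles.
#' @return Object of class `cv_selection`: `selected` (ordered character),
#'   `trajectory` (data frame: step, candidate, mean_auc, selected),
#'   `auc_path` (mean AUC after each accepted step), `rounds`, `folds`,
#'   `t`, `n`, `baseline_auc` (0.5).
#' @export
cv_forward_select <- function(data, candidates, rounds = 100, folds = 10,
                              t = 5, min_gain = 0.005, seed = NULL) {
  check_survival_data(data)
  d <- data[stats::complete.cases(data[, c("time", "event", candidates)]),
            c("time", "event", candidates), drop = FALSE]
  if (!nrow(d)) stop("no complete cases")
  if (sum(d$event) < folds) stop("fewer events than folds")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(d)

  fold_sets <- replicate(rounds, stratified_folds(d$event, folds),
                         simplify = FALSE)

  cv_auc <- function(vars) {
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~",
      paste(sprintf("`%s`", vars), collapse = " + ")))
    aucs <- numeric(0)
    for (r in seq_len(rounds)) {
      fold <- fold_sets[[r]]
      for (f in seq_len(folds)) {
        test <- fold == f
        fit <- tryCatch(
          suppressWarnings(survival::coxph(fml, data = d[!test, ])),
          error = function(e) NULL)
        if (is.null(fit)) next
        lp <- stats::predict(fit, newdata = d[test, ], type = "lp")
        a <- tryCatch(time_dependent_auc(lp, d[test, ], t = t),
                      error = function(e) NA_real_)
        aucs <- c(aucs, a)
      }
    }
    mean(aucs, na.rm = TRUE)
  }

  selected <- character(0)
  current_auc <- 0.5
  remaining <- candidates
  trajectory <- data.frame(step = integer(0), candidate = character(0),
                           mean_auc = numeric(0), selected = logical(0))
  auc_path <- numeric(0)
  step <- 0L
  while (length(remaining)) {
    step <- step + 1L
    scores <- vapply(remaining, function(v) cv_auc(c(selected, v)),
                     numeric(1))
    best <- which.max(scores)
    accept <- is.finite(scores[best]) && scores[best] - current_auc > min_gain
    trajectory <- rbind(trajectory, data.frame(
      step = step, candidate = remaining, mean_auc = unname(scores),
      selected = accept & seq_along(remaining) == best))
    if (!accept) break
    selected <- c(selected, remaining[best])
    current_auc <- scores[best]
    auc_path <- c(auc_path, current_auc)
    remaining <- remaining[-best]
  }
  structure(list(selected = selected, trajectory = trajectory,
                 auc_path = auc_path, rounds = rounds, folds = folds,
                 t = t, n = n, baseline_auc = 0.5),
            class = "cv_selection")
}

#' @export
print.cv_selection <- function(x, ...) {
  cat(sprintf("cv_selection (%d x %d-fold, AUC at %g y): ",
              x$rounds, x$folds, x$t))
  if (length(x$selected)) {
    cat(paste(x$selected, collapse = " + "),
        sprintf(" (mean AUC %.3f)\n", x$auc_path[length(x$auc_path)]))
  } else {
    cat("no covariate selected\n")
  }
  invisible(x)
}

# folds stratified by event indicator; every fold gets events when possible
stratified_folds <- function(event, folds) {
  fold <- integer(length(event))
  for (lev in unique(event)) {
    idx <- which(event == lev)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}
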