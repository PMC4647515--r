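#' Derive time-to-deterioration records from longitudinal scores
#'
#' Deterioration is the first post-baseline visit at which the score has
#' worsened from baseline by at least `threshold` points: a decrease for
#' function and global domains (where high is good), an increase for symptom
#' domains and FI (where high is bad). Patients who never cross the
#' threshold are censored at their last assessment; patients with no
#' post-baseline visit are censored at time 0 with a warning. Because
#' domain scores live on a coarse grid, thresholds between two achievable
#' step sizes are equivalent (no trajectory can change by an amount strictly
#' inside the gap).
#'
#' @param data One-domain trial dataset.
#' @param threshold Deterioration threshold in points (> 0, default 5).
#' @param direction `"decrease"`, `"increase"`, or `NULL` to infer from the
#'   domain kind (see [qlq_domains()]).
#' @return Data.frame of records: `patient_id`, `arm`, `td_time`, `event`.
#' @export
derive_td <- function(data, threshold = 5, direction = NULL) {
  validate_trial(data)
  if (threshold <= 0) stop("threshold must be > 0")
  if (is.null(direction)) {
    kind <- domain_def(data$domain[1])$kind
    direction <- if (kind == "symptom") "increase" else "decrease"
  }
  direction <- match.arg(direction, c("decrease", "increase"))
  data <- data[!is.na(data$score), , drop = FALSE]
  data <- data[order(data$patient_id, data$visit_time), , drop = FALSE]
  ids <- unique(data$patient_id)
  rec <- lapply(ids, function(id) {
    d <- data[data$patient_id == id, , drop = FALSE]
    if (nrow(d) == 1L) {
      warning("patient ", id, " has no post-baseline visit; censored at 0")
      return(data.frame(patient_id = id, arm = d$arm[1], td_time = 0,
                        event = FALSE))
    }
    base <- d$score[1]
    delta <- if (direction == "decrease") base - d$score[-1] else d$score[-1] - base
    hit <- which(delta >= threshold)
    if (length(hit))
      data.frame(patient_id = id, arm = d$arm[1],
                 td_time = d$visit_time[-1][hit[1]], event = TRUE)
    else
      data.frame(patient_id = id, arm = d$arm[1],
                 td_time = max(d$visit_time), event = FALSE)
  })
  out <- do.call(rbind, rec)
  if (!any(out$event))
    stop("no deterioration events in either arm; time-to-deterioration is ",
         "not estimable for this domain/threshold")
  out
}

#' Kaplan-Meier median time to deterioration per arm
#'
#' Product-limit estimate per arm; the median is the first time at which the
#' survival curve reaches 0.5 or below, and is `NA` (undefined) when the
#' curve never crosses 0.5 — which happens routinely for domains with few
#' deterioration events.
#'
#' @param records Output of [derive_td()].
#' @return Named numeric vector `c(control = ..., experimental = ...)` (or a
#'   single value if one arm present), `NA` where undefined.
#' @export
km_median <- function(records) {
  if (!nrow(records)) stop("no records")
  arms <- sort(unique(records$arm))
  out <- vapply(arms, function(a) {
    r <- records[records$arm == a, ]
    sf <- survival::survfit(survival::Surv(td_time, event) ~ 1, data = r)
    # first time at which the product-limit curve reaches 0.5 or below
    hit <- which(sf$surv <= 0.5 + 1e-12)
    if (length(hit)) sf$time[hit[1]] else NA_real_
  }, 0)
  names(out) <- c("control", "experimental")[arms + 1L]
  out
}

#' Cox proportional-hazards ratio for deterioration
#'
#' Partial-likelihood hazard ratio (experimental vs control) with Efron tie
#' handling, 95% CI and Wald p-value.
#'
#' @param records Output of [derive_td()].
#' @return List: `hr`, `lcl`, `ucl`, `p`, `n_events`, and the underlying
#'   `coxph` fit (element `fit`).
#' @export
cox_hr <- function(records) {
  if (!any(records$event)) stop("no events; hazard ratio not estimable")
  if (length(unique(records$arm)) < 2L) stop("both arms must be present")
  fit <- survival::coxph(survival::Surv(td_time, event) ~ arm,
                         data = records, ties = "efron")
  s <- summary(fit)
  list(hr = unname(s$coefficients[1, "exp(coef)"]),
       lcl = unname(s$conf.int[1, "lower .95"]),
       ucl = unname(s$conf.int[1, "upper .95"]),
       p = unname(s$coefficients[1, "Pr(>|z|)"]),
       n_events = sum(records$event), fit = fit)
}

#' Proportional-hazards diagnostic for the deterioration model
#'
#' Scaled Schoenfeld-residual trend test of the treatment effect against
#' time; `ph_ok` when `p >= 0.05`. Crossing deterioration hazards (an early
#' benefit that reverses late) violate the assumption and invalidate a
#' single hazard ratio — a complication the odds-ratio analysis avoids.
#' Withheld (all-`NA` result) with fewer than 3 events.
#'
#' @param records Output of [derive_td()].
#' @param fit Optional result of [cox_hr()] (refit if omitted).
#' @return List: `statistic`, `p`, `ph_ok`, `withheld`.
#' @export
ph_diagnostic <- function(records, fit = NULL) {
  if (sum(records$event) < 3L)
    return(list(statistic = NA_real_, p = NA_real_, ph_ok = NA,
                withheld = TRUE))
  if (is.null(fit)) fit <- cox_hr(records)
  zp <- survival::cox.zph(fit$fit)
  list(statistic = unname(zp$table["arm", "chisq"]),
       p = unname(zp$table["arm", "p"]),
       ph_ok = unname(zp$table["arm", "p"] >= 0.05),
       withheld = FALSE)
}

#' Full time-to-deterioration analysis for one domain
#'
#' Convenience wrapper chaining [derive_td()], [km_median()], [cox_hr()] and
#' [ph_diagnostic()].
#'
#' @inheritParams derive_td
#' @return List of class `td_result`: `records`, `median`, `hr`, `ph`.
#' @export
ttd_analysis <- function(data, threshold = 5, direction = NULL) {
  records <- derive_td(data, threshold, direction)
  hr <- cox_hr(records)
  structure(list(records = records, median = km_median(records),
                 hr = hr[c("hr", "lcl", "ucl", "p", "n_events")],
                 ph = ph_diagnostic(records, hr)),
            class = "td_result")
}

#' @export
print.td_result <- function(x, ...) {
  cat("Time to deterioration\n")
  med <- vapply(x$median, function(m) if (is.na(m)) "not reached" else format(m), "")
  cat("  median:", paste(names(x$median), med, collapse = ", "), "\n")
  cat(sprintf("  HR %.3f (95%% CI %.3f-%.3f), p = %.3g, %d events\n",
              x$hr$hr, x$hr$lcl, x$hr$ucl, x$hr$p, x$hr$n_events))
  if (isTRUE(x$ph$withheld)) cat("  PH diagnostic withheld (<3 events)\n")
  else cat(sprintf("  PH diagnostic p = %.3g (%s)\n", x$ph$p,
                   if (isTRUE(x$ph$ph_ok)) "no violation detected"
                   else "assumption violated"))
  invisible(x)
}
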