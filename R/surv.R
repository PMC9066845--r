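# Survival analysis for median-split signature stratification. Estimation
# and testing are delegated to the survival package (product-limit survfit,
# Mantel-Haenszel survdiff, coxph with Breslow tie handling) behind this
# module's interface.

surv_object <- function(time, event) {
  if (any(time <= 0)) stop_ctx("survival times must be > 0")
  if (!all(event %in% c(0, 1))) stop_ctx("event status must be 0 or 1")
  survival::Surv(time, event)
}

#' Kaplan-Meier product-limit estimate
#'
#' Censored observations leave the risk set after their time; a censoring
#' tied with an event at the same time counts the event first.
#'
#' @param time Positive event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @return A `km_curve` data.frame: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (survival probability just after `time`).
#' @export
km_estimate <- function(time, event) {
  fit <- survival::survfit(surv_object(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' @param time,event Survival data.
#' @param group Two-level group labels.
#' @return List with `chisq`, `df` (1) and `p`.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop_ctx("logrank_test: exactly two groups required")
  if (sum(event) == 0) stop_ctx("logrank_test: no events observed")
  sd <- survival::survdiff(surv_object(time, event) ~ g)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, df = 1L, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial likelihood with Breslow tie handling; the hazard ratio is per
#' unit of the covariate, with a 95% Wald confidence interval.
#'
#' @param covariate Per-sample numeric covariate.
#' @param time,event Survival data.
#' @return A `cox_result`: list with `beta`, `se`, `hr`, `ci` (length 2),
#'   `p`, `n`, `n_event`.
#' @export
cox_fit <- function(covariate, time, event) {
  if (sd(covariate) == 0) stop_ctx("cox_fit: constant covariate")
  if (sum(event) < 10)
    log_msg("cox_fit: fewer than 10 events; estimates may be unstable")
  fit <- withCallingHandlers(
    survival::coxph(surv_object(time, event) ~ covariate, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        stop_ctx("cox_fit: monotone likelihood / non-convergence: ",
                 conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  res <- list(beta = beta, se = se, hr = exp(beta),
              ci = exp(beta + c(-1.96, 1.96) * se),
              p = 2 * pnorm(-abs(beta / se)),
              n = fit$n, n_event = fit$nevent)
  class(res) <- "cox_result"
  res
}

#' @export
print.cox_result <- function(x, ...) {
  cat("cox_result: HR =", fmt_num(x$hr), "(95% CI", fmt_num(x$ci[1]), "-",
      fmt_num(x$ci[2]), "), p =", fmt_num(x$p), "\n")
  invisible(x)
}

#' Median split of a score vector into high/low strata
#'
#' Scores strictly above the median go to `high`; ties at the median go to
#' `low`.
#'
#' @param scores Named numeric vector.
#' @return Named character vector of labels `"high"`/`"low"`.
#' @export
median_stratify <- function(scores) {
  if (length(scores) < 2L) stop_ctx("median_stratify: need >= 2 samples")
  if (max(scores) == min(scores))
    stop_ctx("median_stratify: all scores identical (degenerate split)")
  m <- median(scores)
  setNames(ifelse(scores > m, "high", "low"), names(scores))
}

#' Median-split survival analysis of a gene signature
#'
#' Composes cohort z-scoring, weighted-sum signature scoring, median
#' stratification, per-stratum Kaplan-Meier estimation, the log-rank test
#' between strata, and a Cox fit on the continuous standardized score.
#'
#' @param expr Genes x samples expression matrix (unnormalized; z-scoring is
#'   applied internally).
#' @param sig A `signature`.
#' @param clinical Clinical data.frame with `sample`, `time`, `event`.
#' @return List: `scores`, `strata`, `km_high`, `km_low`, `logrank`, `cox`,
#'   `n_high`, `n_low`.
#' @export
signature_survival <- function(expr, sig, clinical) {
  ids <- intersect(colnames(expr), clinical$sample)
  if (length(ids) < length(clinical$sample) / 2)
    stop_ctx("signature_survival: > 50% of clinical samples lack expression")
  cl <- clinical[match(ids, clinical$sample), , drop = FALSE]
  z <- zscore_normalize(expr[, ids, drop = FALSE])
  sc <- signature_score(z, sig)
  strata <- median_stratify(sc)
  if (min(table(strata)) < 2L)
    stop_ctx("signature_survival: a stratum has < 2 samples")
  hi <- strata == "high"
  list(scores = sc, strata = strata,
       km_high = km_estimate(cl$time[hi], cl$event[hi]),
       km_low = km_estimate(cl$time[!hi], cl$event[!hi]),
       logrank = logrank_test(cl$time, cl$event, strata),
       cox = cox_fit(as.numeric(scale(sc)), cl$time, cl$event),
       n_high = sum(hi), n_low = sum(!hi))
}
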