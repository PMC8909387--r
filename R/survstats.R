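#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator via the survival package. The median is the
#' smallest observed time with S(t) <= 0.5, reported as `NA` ("not
#' reached") when the curve never drops that far.
#'
#' @param time follow-up times (> 0), months.
#' @param event event indicators (1/TRUE = event, 0/FALSE = censored).
#' @return List with `time`, `surv`, `n_risk`, `n_event` (step-function
#'   support), `median`, and `median_reached`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event), all(time > 0))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  med <- fit$time[fit$surv <= 0.5 + 1e-12]
  med <- if (length(med)) min(med) else NA_real_
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, median = med, median_reached = !is.na(med))
}

#' Log-rank test between two groups
#'
#' Standard one-degree-of-freedom log-rank comparison.
#'
#' @param time_a,event_a first group.
#' @param time_b,event_b second group.
#' @return List with `statistic` (chi-square, 1 df) and `p`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  stopifnot(length(time_a) >= 1L, length(time_b) >= 1L)
  if (sum(event_a) + sum(event_b) == 0) {
    stop("log-rank undefined: no events in either group")
  }
  time <- c(time_a, time_b)
  event <- as.integer(c(event_a, event_b))
  grp <- rep(c(0L, 1L), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = sd$chisq, p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with the Efron tie approximation; Wald confidence
#' interval and p-value. Degenerate fits (constant covariate,
#' non-convergence, separation driving the coefficient to infinity) raise
#' errors rather than returning nonsense.
#'
#' @param time,event survival endpoint.
#' @param covariate numeric covariate (non-constant).
#' @param conf_level confidence level for the Wald interval.
#' @return List with `hr`, `ci` (length 2), `p`, `coef`, `se`, `n`,
#'   `n_event`.
#' @export
cox_univariate <- function(time, event, covariate, conf_level = 0.95) {
  keep <- stats::complete.cases(time, event, covariate)
  time <- time[keep]; event <- as.integer(event[keep]); covariate <- as.numeric(covariate[keep])
  if (length(unique(covariate)) < 2L) stop("constant covariate")
  fit <- survival::coxph(survival::Surv(time, event) ~ covariate, ties = "efron")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 20) {
    stop("Cox fit did not converge (possible complete separation)")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(beta), ci = exp(beta + c(-1, 1) * z * se),
       p = 2 * stats::pnorm(-abs(beta / se)),
       coef = beta, se = se, n = length(time), n_event = sum(event))
}

# log-rank scores a_i = event_i - Nelson-Aalen cumulative hazard at time_i
logrank_scores <- function(time, event) {
  e_all <- as.integer(event)
  ut <- sort(unique(time[e_all == 1L]))
  if (!length(ut)) return(rep(0, length(time)))
  haz_at <- stats::stepfun(ut, c(0, cumsum(vapply(ut, function(tt) {
    sum(e_all[time == tt]) / sum(time >= tt)
  }, 0))))
  e_all - haz_at(time)
}

#' Maximally selected rank statistic cutpoint
#'
#' Scans every candidate cutoff (midpoints between consecutive distinct
#' covariate values whose induced low-group proportion lies within
#' `q_range`) and computes the standardized log-rank statistic of the
#' induced dichotomy, built from Nelson-Aalen log-rank scores with the
#' permutation variance. Returns the maximizing cutoff (ties to the
#' smaller value) and a permutation p-value obtained by permuting the
#' covariate against the survival records and re-maximizing each time.
#'
#' @param values continuous covariate.
#' @param time,event survival endpoint.
#' @param q_range quantile range of admissible low-group proportions.
#' @param n_perm number of permutations for the p-value.
#' @return A `maxstat_result` list: `best_cutoff`, `max_statistic`,
#'   `permutation_p`, `n_candidates`, `cutoffs`, `statistics`.
#' @export
maxstat_cutpoint <- function(values, time, event, q_range = c(0.1, 0.9),
                             n_perm = 1000L) {
  keep <- stats::complete.cases(values, time, event)
  values <- as.numeric(values[keep]); time <- time[keep]; event <- event[keep]
  n <- length(values)
  if (length(unique(values)) < 2L) stop("constant covariate: no cutpoint exists")
  a <- logrank_scores(time, event)
  ssq <- sum((a - mean(a))^2)
  if (ssq <= 0) stop("degenerate survival data: all log-rank scores equal")
  ord <- order(values)
  v_s <- values[ord]
  distinct_hi <- which(diff(v_s) > 0) # last index of each distinct value but the top
  cuts <- (v_s[distinct_hi] + v_s[distinct_hi + 1L]) / 2
  m <- distinct_hi # low-group size at each cut
  prop <- m / n
  in_range <- prop >= q_range[1L] & prop <= q_range[2L]
  if (!any(in_range)) in_range <- rep(TRUE, length(cuts)) # fall back to all cuts
  cuts <- cuts[in_range]; m <- m[in_range]
  stat_for <- function(a_ord) {
    S <- cumsum(a_ord)[m]
    abs(S - m * mean(a_ord)) / sqrt(m * (n - m) / (n * (n - 1)) * ssq)
  }
  stats_obs <- stat_for(a[ord])
  best <- which.max(stats_obs) # leftmost max = smaller cutoff on ties
  obs <- stats_obs[best]
  perm_max <- vapply(seq_len(n_perm), function(b) max(stat_for(sample(a))), 0)
  structure(list(best_cutoff = cuts[best], max_statistic = obs,
                 permutation_p = (1 + sum(perm_max >= obs - 1e-12)) / (n_perm + 1),
                 n_candidates = length(cuts),
                 cutoffs = cuts, statistics = stats_obs),
            class = "maxstat_result")
}

#' @export
print.maxstat_result <- function(x, ...) {
  cat(sprintf("maximally selected rank statistic: best cutoff %.4g (T = %.3f, permutation p = %.4g, %d candidates)\n",
              x$best_cutoff, x$max_statistic, x$permutation_p, x$n_candidates))
  invisible(x)
}
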