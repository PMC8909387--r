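#' Bootstrap lasso-Cox stability selection
#'
#' For each of `B` bootstrap resamples of patients, fits an L1-penalized
#' Cox model with the penalty chosen by internal K-fold cross-validated
#' partial likelihood (the 1-SE rule by default — the sparser choice is
#' what keeps all-noise designs from retaining spurious variables — with
#' the CV optimum as an option) and records which variables carry nonzero
#' coefficients.
#' Variables selected in more than `threshold` of the resamples are
#' retained. For each retained variable the hazard ratio is summarized as
#' the exponentiated median of its bootstrap coefficients over the
#' resamples where it was selected, with a 2.5/97.5 percentile interval —
#' a bootstrap-percentile convention, not a Wald interval.
#'
#' Callers are expected to pre-filter candidates by univariate Cox p < 0.1
#' (see [report_tables()], which does this).
#'
#' @param time,event survival endpoint (n >= 20).
#' @param x numeric covariate matrix (columns named).
#' @param B number of bootstrap resamples (default 500).
#' @param threshold selection-frequency retention threshold (default 2/3,
#'   strict inequality).
#' @param nfolds folds for the internal cross-validation.
#' @param lambda `"1se"` (sparser, default) or `"min"` (CV optimum).
#' @param seed integer seed for the resampling stream.
#' @return A `stability_selection` object: `frequency` (named),
#'   `retained`, `hr` (data frame of retained-variable summaries), `B`,
#'   `threshold`.
#' @export
lasso_stability_selection <- function(time, event, x, B = 500L,
                                      threshold = 2 / 3, nfolds = 5L,
                                      lambda = c("1se", "min"), seed = 1L) {
  lambda <- match.arg(lambda)
  if (B < 1L) stop("B must be at least 1")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  n <- nrow(x)
  if (n < 20L) stop("need at least 20 patients for stability selection")
  stopifnot(length(time) == n, length(event) == n)
  event <- as.integer(event)
  p <- ncol(x)
  sel <- matrix(FALSE, B, p, dimnames = list(NULL, colnames(x)))
  coefs <- matrix(NA_real_, B, p, dimnames = list(NULL, colnames(x)))
  with_local_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx, , drop = FALSE]
      yb <- survival::Surv(time[idx], event[idx])
      fit <- if (sum(event[idx]) >= nfolds) tryCatch(
        glmnet::cv.glmnet(xb, yb, family = "cox", nfolds = nfolds),
        error = function(e) NULL
      ) else NULL
      if (is.null(fit)) next # degenerate resample counts as selecting nothing
      s <- if (lambda == "min") fit$lambda.min else fit$lambda.1se
      cf <- as.numeric(stats::coef(fit, s = s))
      nz <- cf != 0
      sel[b, nz] <- TRUE
      coefs[b, nz] <- cf[nz]
    }
  })
  freq <- colMeans(sel)
  retained <- names(freq)[freq > threshold]
  hr <- do.call(rbind, lapply(retained, function(v) {
    cf <- coefs[sel[, v], v]
    data.frame(variable = v, selection_frequency = freq[[v]],
               hr = exp(stats::median(cf)),
               ci_lower = exp(unname(stats::quantile(cf, 0.025))),
               ci_upper = exp(unname(stats::quantile(cf, 0.975))),
               stringsAsFactors = FALSE)
  }))
  if (is.null(hr)) {
    hr <- data.frame(variable = character(), selection_frequency = numeric(),
                     hr = numeric(), ci_lower = numeric(), ci_upper = numeric(),
                     stringsAsFactors = FALSE)
  }
  structure(list(frequency = freq, retained = retained, hr = hr,
                 B = as.integer(B), threshold = threshold),
            class = "stability_selection")
}

#' @export
print.stability_selection <- function(x, ...) {
  cat("bootstrap lasso-Cox stability selection (B =", x$B,
      ", threshold >", round(x$threshold, 3), ")\n")
  print(round(sort(x$frequency, decreasing = TRUE), 3))
  if (length(x$retained)) {
    cat("retained:\n")
    print(x$hr, row.names = FALSE)
  } else {
    cat("retained: none\n")
  }
  invisible(x)
}

#' Univariate + multivariate survival report tables
#'
#' The report shape of the study's forest tables: for every requested
#' variable and endpoint, a univariate Cox row (HR for high vs low, Wald
#' CI, p); continuous variables are first dichotomized at the maximally
#' selected rank-statistic cutoff, re-estimated per endpoint. Variables
#' with univariate p < `entry_p` then enter bootstrap lasso-Cox stability
#' selection, and the multivariate table reports the retained variables
#' only.
#'
#' @param patients data frame with `pfs_time`/`pfs_event` and/or
#'   `os_time`/`os_event` plus the variable columns.
#' @param variables character vector of variable columns; binary 0/1
#'   columns are used as-is, other numerics are dichotomized.
#' @param endpoints subset of `c("pfs", "os")`.
#' @param entry_p univariate entry filter for the multivariate model.
#' @param B,threshold,seed passed to [lasso_stability_selection()].
#' @param n_perm permutations for the maxstat cutoffs.
#' @return A `tme_report` list: `univariate` (data frame), `multivariate`
#'   (data frame), `selection` (per-endpoint `stability_selection`).
#' @export
report_tables <- function(patients, variables, endpoints = c("pfs", "os"),
                          entry_p = 0.1, B = 500L, threshold = 2 / 3,
                          seed = 1L, n_perm = 200L) {
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  missing_vars <- setdiff(variables, names(patients))
  if (length(missing_vars)) stop("variables absent from patient table: ",
                                 paste(missing_vars, collapse = ", "))
  uni <- list()
  dich <- list()
  for (ep in endpoints) {
    tm <- patients[[paste0(ep, "_time")]]
    ev <- patients[[paste0(ep, "_event")]]
    if (is.null(tm) || is.null(ev)) stop("patient table lacks ", ep, " endpoint columns")
    for (v in variables) {
      val <- as.numeric(patients[[v]])
      is_binary <- all(stats::na.omit(val) %in% c(0, 1))
      cutoff <- NA_real_
      if (!is_binary) {
        ms <- maxstat_cutpoint(val, tm, ev, n_perm = n_perm)
        cutoff <- ms$best_cutoff
        val <- binarize(val, cutoff)
      }
      fit <- tryCatch(cox_univariate(tm, ev, val), error = function(e) NULL)
      uni[[length(uni) + 1L]] <- data.frame(
        variable = v, endpoint = ep, comparison = "High vs Low",
        cutoff = cutoff,
        hr = if (is.null(fit)) NA_real_ else fit$hr,
        ci_lower = if (is.null(fit)) NA_real_ else fit$ci[1L],
        ci_upper = if (is.null(fit)) NA_real_ else fit$ci[2L],
        p = if (is.null(fit)) NA_real_ else fit$p,
        n = sum(stats::complete.cases(tm, ev, val)),
        stringsAsFactors = FALSE
      )
      dich[[paste(ep, v, sep = ".")]] <- val
    }
  }
  univariate <- do.call(rbind, uni)
  multivariate <- list()
  selection <- list()
  for (ep in endpoints) {
    rows <- univariate[univariate$endpoint == ep, ]
    enter <- rows$variable[!is.na(rows$p) & rows$p < entry_p]
    if (length(enter) >= 1L) {
      xmat <- sapply(enter, function(v) dich[[paste(ep, v, sep = ".")]])
      xmat <- as.matrix(xmat)
      colnames(xmat) <- enter
      tm <- patients[[paste0(ep, "_time")]]
      ev <- patients[[paste0(ep, "_event")]]
      cc <- stats::complete.cases(tm, ev, xmat)
      if (length(enter) == 1L) {
        # lasso needs >= 2 columns; single entrant is "retained" by its
        # univariate fit, frequency reported as 1
        fit <- cox_univariate(tm[cc], ev[cc], xmat[cc, 1L])
        sel <- NULL
        multivariate[[ep]] <- data.frame(
          variable = enter, endpoint = ep, selection_frequency = 1,
          hr = fit$hr, ci_lower = fit$ci[1L], ci_upper = fit$ci[2L],
          stringsAsFactors = FALSE)
      } else {
        sel <- lasso_stability_selection(tm[cc], ev[cc], xmat[cc, , drop = FALSE],
                                         B = B, threshold = threshold, seed = seed)
        if (nrow(sel$hr)) {
          multivariate[[ep]] <- cbind(
            sel$hr[, "variable", drop = FALSE],
            endpoint = ep,
            sel$hr[, c("selection_frequency", "hr", "ci_lower", "ci_upper")])
        }
      }
      selection[[ep]] <- sel
    }
  }
  multivariate <- if (length(multivariate)) do.call(rbind, multivariate) else
    data.frame(variable = character(), endpoint = character(),
               selection_frequency = numeric(), hr = numeric(),
               ci_lower = numeric(), ci_upper = numeric(),
               stringsAsFactors = FALSE)
  rownames(multivariate) <- NULL
  rownames(univariate) <- NULL
  structure(list(univariate = univariate, multivariate = multivariate,
                 selection = selection),
            class = "tme_report")
}

#' @export
print.tme_report <- function(x, ...) {
  cat("univariate forest table:\n")
  print(x$univariate, row.names = FALSE, digits = 3)
  cat("\nmultivariate (stability-selected):\n")
  if (nrow(x$multivariate)) print(x$multivariate, row.names = FALSE, digits = 3)
  else cat("  (no variable retained)\n")
  invisible(x)
}
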