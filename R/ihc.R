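#' H-score from staining-density percentages
#'
#' `H = 1 * pct_low + 2 * pct_moderate + 3 * pct_high` (unstained cells
#' weight 0), range 0-300. The four percentages must be non-negative and
#' sum to 100.
#'
#' @param pct_neg,pct_low,pct_mod,pct_high percentages of tumor cells
#'   unstained / low / moderate / high density.
#' @return H-score in [0, 300].
#' @examples
#' h_score(40, 20, 30, 10) # 110
#' @export
h_score <- function(pct_neg, pct_low, pct_mod, pct_high) {
  p <- c(pct_neg, pct_low, pct_mod, pct_high)
  if (any(p < 0)) stop("percentages must be non-negative")
  if (abs(sum(p) - 100) > 1e-6) stop("percentages must sum to 100")
  pct_low * 1 + pct_mod * 2 + pct_high * 3
}

#' Dichotomize marker values at a cutoff
#'
#' High iff `value >= cutoff` (rule "ge", the default) or `value > cutoff`
#' ("gt"). The conventional HLA-E scheme on the 0-3 scale uses cutoff 2
#' (scores 0-1 low, 2-3 high). `NA`s are preserved.
#'
#' @param values numeric marker values.
#' @param cutoff dichotomization cutoff.
#' @param rule `"ge"` or `"gt"`.
#' @return Integer vector (1 = high, 0 = low, `NA` preserved).
#' @export
binarize <- function(values, cutoff, rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  as.integer(if (rule == "ge") values >= cutoff else values > cutoff)
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
fisher_exact_2x2 <- function(tab) {
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  if (n == 0) return(NA_real_)
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  pr <- stats::dhyper(x, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Cross-tabulate two dichotomized variables
#'
#' Builds the 2x2 contingency table of `group` (rows, e.g. HLA-E high/low)
#' against `outcome` (columns, e.g. marker positive/negative), after
#' pairwise deletion of missing values. Row percentages are rounded
#' half-up to one decimal, matching the usual presentation. Both a Pearson
#' chi-square p (continuity correction configurable) and a two-sided
#' Fisher exact p (hypergeometric enumeration) are always reported, with a
#' flag when any expected count is below 5.
#'
#' @param group,outcome vectors coercible to 0/1 (logical or integer).
#' @param labels optional `list(group = c(low, high), outcome = c(neg, pos))`.
#' @param correct apply Yates continuity correction to the chi-square test.
#' @return A `crosstab` object: `counts` (2x2, rows = group high/low),
#'   `row_pct`, `chi_square_p`, `fisher_p`, `n_assessable`,
#'   `low_expected`.
#' @export
crosstab <- function(group, outcome, labels = NULL, correct = FALSE) {
  keep <- !(is.na(group) | is.na(outcome))
  g <- as.integer(group[keep])
  o <- as.integer(outcome[keep])
  if (!length(g)) stop("no complete pairs to tabulate")
  counts <- matrix(c(sum(g == 1 & o == 1), sum(g == 1 & o == 0),
                     sum(g == 0 & o == 1), sum(g == 0 & o == 0)),
                   nrow = 2L, byrow = TRUE,
                   dimnames = list(
                     group = if (is.null(labels$group)) c("high", "low") else rev(labels$group),
                     outcome = if (is.null(labels$outcome)) c("pos", "neg") else rev(labels$outcome)
                   ))
  crosstab_from_counts(counts, correct = correct)
}

#' @rdname crosstab
#' @param counts a 2x2 integer matrix (rows = groups).
#' @export
crosstab_from_counts <- function(counts, correct = FALSE) {
  stopifnot(is.matrix(counts), all(dim(counts) == 2L), all(counts >= 0))
  n <- sum(counts)
  row_tot <- rowSums(counts)
  row_pct <- counts / ifelse(row_tot > 0, row_tot, NA) * 100
  row_pct <- round_half_up(row_pct, 1L)
  exp_counts <- outer(rowSums(counts), colSums(counts)) / n
  chi_p <- tryCatch(
    suppressWarnings(stats::chisq.test(counts, correct = correct)$p.value),
    error = function(e) NA_real_
  )
  structure(list(counts = counts, row_pct = row_pct,
                 chi_square_p = chi_p,
                 fisher_p = fisher_exact_2x2(counts),
                 n_assessable = n,
                 low_expected = any(exp_counts < 5)),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat("2x2 cross-tabulation (n =", x$n_assessable, "assessable)\n")
  print(x$counts)
  cat("row %:\n")
  print(x$row_pct)
  cat(sprintf("chi-square p = %.4g; Fisher exact p = %.4g%s\n",
              x$chi_square_p, x$fisher_p,
              if (x$low_expected) " (expected count < 5)" else ""))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Exact p by complete enumeration of group assignments when both groups
#' have at most `exact_max` observations (ties handled through midranks);
#' otherwise the normal approximation with tie-corrected variance.
#'
#' @param x,y numeric values of the two groups (non-empty).
#' @param exact_max enumeration bound per group (default 10).
#' @return List with `statistic` (rank-sum W of `x`), `p`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 10L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  n <- nx + ny
  EW <- nx * (n + 1) / 2
  if (nx <= exact_max && ny <= exact_max) {
    dev <- abs(W - EW)
    combs <- utils::combn(n, nx)
    Ws <- colSums(matrix(r[combs], nrow = nx))
    p <- mean(abs(Ws - EW) >= dev - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    VW <- nx * ny / 12 * ((n + 1) - tie_term)
    z <- (W - EW) / sqrt(VW)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation, tie-corrected"
  }
  list(statistic = W, p = p, method = method)
}

#' @rdname rank_sum_test
#' @param values numeric vector.
#' @param groups two-level grouping vector aligned with `values`.
#' @export
group_compare_continuous <- function(values, groups, exact_max = 10L) {
  keep <- !(is.na(values) | is.na(groups))
  values <- values[keep]; groups <- groups[keep]
  lev <- unique(groups)
  if (length(lev) != 2L) stop("need exactly two groups")
  rank_sum_test(values[groups == lev[1L]], values[groups == lev[2L]],
                exact_max = exact_max)
}
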