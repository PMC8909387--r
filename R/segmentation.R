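#' Segmentation configuration
#'
#' Parameters for probe centering, change-point detection and status
#' calling. Splits are accepted when the permutation p-value of the maximal
#' two-sample t statistic is at most `alpha`. The gain/loss thresholds are
#' log2-ratio cutoffs for segment status; +/-0.2 is a conventional CGH
#' choice (the underlying study never states its thresholds).
#'
#' @param alpha significance level for accepting a split (default 0.01).
#' @param min_probes minimum probes per segment (>= 2; default 3).
#' @param gain_threshold log2 ratio at or above which a segment is "gain".
#' @param loss_threshold log2 ratio at or below which a segment is "loss".
#' @param baseline_offset log2 offset subtracted by [recalibrate_baseline()].
#' @param n_perm permutations per split test.
#' @param seed integer seed for the deterministic per-window permutation
#'   streams (keeps segment counts monotone in `alpha` across runs).
#' @return A `seg_config` list.
#' @export
seg_config <- function(alpha = 0.01, min_probes = 3L, gain_threshold = 0.2,
                       loss_threshold = -0.2, baseline_offset = 0,
                       n_perm = 200L, seed = 1L) {
  stopifnot(alpha > 0, alpha <= 1, min_probes >= 2L,
            loss_threshold < 0, gain_threshold > 0, n_perm >= 1L)
  structure(list(alpha = alpha, min_probes = as.integer(min_probes),
                 gain_threshold = gain_threshold, loss_threshold = loss_threshold,
                 baseline_offset = baseline_offset, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "seg_config")
}

# evaluate code under a temporary RNG state seeded by `seed`
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Median-center a probe series
#'
#' Baseline normalization reduced to its essential: subtract the sample-wide
#' median log ratio so the modal copy state sits at 0.
#'
#' @param probes a [cn_probes()] series with at least one probe.
#' @return The centered series (output median is 0 within 1e-12).
#' @export
center_probes <- function(probes) {
  stopifnot(inherits(probes, "cn_probes"))
  if (nrow(probes) < 1L) stop("empty probe series")
  probes$log2ratio <- probes$log2ratio - stats::median(probes$log2ratio)
  probes
}

# max |pooled t| over all splits leaving >= mp probes each side;
# returns NULL when no candidate split exists
scan_max_t <- function(x, mp) {
  n <- length(x)
  if (n < 2L * mp) return(NULL)
  ks <- mp:(n - mp)
  cs <- cumsum(x)
  tot <- cs[n]
  css <- sum(x * x)
  m1 <- cs[ks] / ks
  m2 <- (tot - cs[ks]) / (n - ks)
  rss <- pmax(css - ks * m1^2 - (n - ks) * m2^2, 0)
  s2 <- rss / max(n - 2L, 1L)
  se <- sqrt(s2 * (1 / ks + 1 / (n - ks)))
  d <- abs(m1 - m2)
  t <- ifelse(se > 0, d / se, ifelse(d < 1e-12, 0, Inf))
  i <- which.max(t) # leftmost maximizer on ties
  list(k = ks[i], t = t[i])
}

#' Segment a probe series into a tiling copy-number profile
#'
#' Recursive binary segmentation with a two-sample t statistic and
#' permutation acceptance at level `alpha` — a deliberately transparent
#' stand-in for circular binary segmentation; callers with pre-segmented
#' data can skip this stage entirely via [read_segments()]. Each chromosome
#' is processed independently; segment boundaries fall at probe midpoints
#' and are extended to the chromosome ends, so the output tiles the genome.
#'
#' @param probes a sorted [cn_probes()] series.
#' @param genome a [genome_model()] supplying chromosome lengths.
#' @param cfg a [seg_config()].
#' @return A [cn_profile()] (status not yet called; see [call_status()]).
#' @export
segment_probes <- function(probes, genome, cfg = seg_config()) {
  stopifnot(inherits(probes, "cn_probes"), inherits(genome, "genome_model"))
  if (nrow(probes) < 1L) stop("empty probe series")
  unknown <- setdiff(unique(probes$chrom), genome$chrom)
  if (length(unknown)) stop("unknown chromosome: ", paste(unknown, collapse = ", "))
  pieces <- list()
  for (ch in intersect(genome$chrom, unique(probes$chrom))) {
    p <- probes[probes$chrom == ch, , drop = FALSE]
    len <- genome$length_bp[match(ch, genome$chrom)]
    x <- p$log2ratio
    n <- length(x)
    if (n < cfg$min_probes) {
      warning("chromosome ", ch, " has fewer than min_probes probes; single segment")
      splits <- integer()
    } else {
      splits <- sort(split_window(x, cfg, offset = 0L))
    }
    starts_i <- c(1L, splits + 1L)
    ends_i <- c(splits, n)
    mids <- if (length(splits)) (p$pos[splits] + p$pos[splits + 1L]) / 2 else numeric()
    pieces[[length(pieces) + 1L]] <- data.frame(
      chrom = ch,
      start = c(0, mids),
      end = c(mids, len),
      mean_log2 = vapply(seq_along(starts_i),
                         function(i) mean(x[starts_i[i]:ends_i[i]]), 0),
      status = NA_character_,
      n_probes = ends_i - starts_i + 1L,
      stringsAsFactors = FALSE
    )
  }
  cn_profile(do.call(rbind, pieces), sample_id = sample_id(probes))
}

# recursive splitter used by segment_probes
split_window <- function(x, cfg, offset) {
  best <- scan_max_t(x, cfg$min_probes)
  if (is.null(best) || best$t <= 0) return(integer())
  seed_w <- (abs(cfg$seed) * 1000003 + offset * 131 + length(x)) %% 2147483647
  perm_t <- with_local_seed(seed_w, {
    vapply(seq_len(cfg$n_perm), function(b) {
      r <- scan_max_t(sample(x), cfg$min_probes)
      if (is.null(r)) 0 else r$t
    }, 0)
  })
  p <- (1 + sum(perm_t >= best$t)) / (cfg$n_perm + 1)
  if (p > cfg$alpha) return(integer())
  k <- best$k
  left <- split_window(x[seq_len(k)], cfg, offset)
  right <- split_window(x[(k + 1L):length(x)], cfg, offset + k)
  c(left, k, k + right)
}

#' Call gain/loss/normal status on segments
#'
#' Status is a pure function of the segment mean and the thresholds:
#' gain iff `mean_log2 >= gain_threshold`, loss iff
#' `mean_log2 <= loss_threshold`, normal otherwise.
#'
#' @param profile a [cn_profile()].
#' @param cfg a [seg_config()].
#' @return The profile with `status` filled in.
#' @export
call_status <- function(profile, cfg = seg_config()) {
  stopifnot(inherits(profile, "cn_profile"))
  profile$status <- ifelse(profile$mean_log2 >= cfg$gain_threshold, "gain",
                    ifelse(profile$mean_log2 <= cfg$loss_threshold, "loss", "normal"))
  profile
}

#' Shift the profile baseline and re-call status
#'
#' Replaces the study's interactive baseline recalibration: subtract a fixed
#' log2 offset from every segment mean and recompute statuses.
#'
#' @param profile a [cn_profile()].
#' @param offset log2 shift to subtract.
#' @param cfg a [seg_config()] providing the status thresholds.
#' @return The recalibrated, status-called profile.
#' @export
recalibrate_baseline <- function(profile, offset, cfg = seg_config()) {
  stopifnot(inherits(profile, "cn_profile"))
  profile$mean_log2 <- profile$mean_log2 - offset
  call_status(profile, cfg)
}
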