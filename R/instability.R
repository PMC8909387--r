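#' LGA / HRD scoring configuration
#'
#' Tunables for the shallowHRD-style large-genomic-alteration (LGA) caller
#' and for event classification. "Large" segments (LGA flanks) are
#' `large_segment_mb` (> 10 Mb per the source method); segments below
#' `small_segment_mb` are integrated into their neighbours before counting;
#' interstitial copy-number alterations shorter than `large_segment_mb`
#' sandwiched between concordant large flanks are absorbed. A profile is
#' called HRD when its LGA count reaches `hrd_threshold` (inclusive).
#'
#' The per-profile one-copy cutoff is the histogram mode (bin
#' `cutoff_bin`) of absolute shifts between adjacent large segments,
#' restricted to `[cutoff_floor, cutoff_ceiling]`; with fewer than
#' `min_pairs` eligible shifts the fixed `cutoff_fallback` is used.
#' Smoothing and LGA counting compare shifts against
#' `cutoff * (1 - step_tolerance)`: the mode estimate sits at the one-copy
#' step itself, so a small relative slack keeps genuinely one-copy breaks
#' from being merged away by probe noise.
#'
#' @param large_segment_mb large-segment bound in Mb (default 10).
#' @param small_segment_mb small-segment bound in Mb (default 3).
#' @param max_gap_mb maximum gap between LGA flanks in Mb (0 for tiling
#'   profiles; default 3).
#' @param hrd_threshold LGA count at and above which a profile is HRD.
#' @param cutoff_floor,cutoff_ceiling shift range eligible for cutoff
#'   estimation (log2).
#' @param cutoff_fallback cutoff used when too few shifts are available.
#' @param cutoff_bin histogram bin width for the mode.
#' @param min_pairs minimum eligible adjacent large-segment pairs.
#' @param step_tolerance relative slack on the cutoff comparison.
#' @param arm_coverage_min arm fraction both arms must reach (same status)
#'   for chromosome-level classification.
#' @param sex_chroms chromosome names excluded from all scoring.
#' @return An `lga_config` list.
#' @export
lga_config <- function(large_segment_mb = 10, small_segment_mb = 3,
                       max_gap_mb = 3, hrd_threshold = 18L,
                       cutoff_floor = 0.15, cutoff_ceiling = 0.9,
                       cutoff_fallback = 0.3, cutoff_bin = 0.05,
                       min_pairs = 5L, step_tolerance = 0.1,
                       arm_coverage_min = 0.8,
                       sex_chroms = c("X", "Y", "chrX", "chrY", "23", "24")) {
  stopifnot(small_segment_mb < large_segment_mb, large_segment_mb > 0,
            hrd_threshold > 0, cutoff_floor > 0, cutoff_ceiling > cutoff_floor,
            cutoff_fallback > 0, cutoff_bin > 0, min_pairs >= 1,
            step_tolerance >= 0, step_tolerance < 1,
            arm_coverage_min > 0.5, arm_coverage_min <= 1)
  structure(list(large_segment_mb = large_segment_mb,
                 small_segment_mb = small_segment_mb,
                 max_gap_mb = max_gap_mb, hrd_threshold = as.integer(hrd_threshold),
                 cutoff_floor = cutoff_floor, cutoff_ceiling = cutoff_ceiling,
                 cutoff_fallback = cutoff_fallback, cutoff_bin = cutoff_bin,
                 min_pairs = as.integer(min_pairs), step_tolerance = step_tolerance,
                 arm_coverage_min = arm_coverage_min, sex_chroms = sex_chroms),
            class = "lga_config")
}

drop_sex_chroms <- function(profile, cfg) {
  keep <- !(profile$chrom %in% cfg$sex_chroms)
  out <- profile[keep, , drop = FALSE]
  attr(out, "sample_id") <- sample_id(profile)
  class(out) <- class(profile)
  out
}

lga_threshold <- function(cutoff, cfg) cutoff * (1 - cfg$step_tolerance)

#' Genomic Index
#'
#' GI = A^2 / C, where A is the total number of alterations — maximal runs
#' of adjacent same-status gained or lost segments — and C the number of
#' distinct (autosomal) chromosomes carrying at least one alteration. A
#' profile with no alterations scores 0.
#'
#' @param profile a status-called [cn_profile()].
#' @param cfg an [lga_config()] (controls sex-chromosome exclusion).
#' @return List with `gi`, `A`, `C`.
#' @export
genomic_index <- function(profile, cfg = lga_config()) {
  stopifnot(inherits(profile, "cn_profile"))
  if (anyNA(profile$status)) stop("profile must be status-called first")
  profile <- drop_sex_chroms(profile, cfg)
  A <- 0L
  chroms_hit <- character()
  for (ch in unique(profile$chrom)) {
    st <- profile$status[profile$chrom == ch]
    runs <- rle(st)
    n_alt <- sum(runs$values %in% c("gain", "loss"))
    if (n_alt > 0L) {
      A <- A + n_alt
      chroms_hit <- c(chroms_hit, ch)
    }
  }
  C <- length(chroms_hit)
  list(gi = if (A == 0L) 0 else A^2 / C, A = A, C = C)
}

#' Build alteration events from a status-called profile
#'
#' Maximal runs of adjacent same-status altered segments become events.
#' Runs crossing the centromere are split into their p and q parts before
#' any classification; each event carries `arm_fraction` = event span /
#' containing arm length.
#'
#' @param profile a status-called [cn_profile()].
#' @param genome a [genome_model()].
#' @param cfg an [lga_config()].
#' @return Data frame of events: `chrom`, `status`, `start`, `end`, `arm`,
#'   `arm_fraction`.
#' @export
build_events <- function(profile, genome, cfg = lga_config()) {
  stopifnot(inherits(profile, "cn_profile"), inherits(genome, "genome_model"))
  if (anyNA(profile$status)) stop("profile must be status-called first")
  profile <- drop_sex_chroms(profile, cfg)
  arms <- arm_table(genome)
  out <- list()
  for (ch in unique(profile$chrom)) {
    s <- profile[profile$chrom == ch, , drop = FALSE]
    cen <- genome$centromere_bp[match(ch, genome$chrom)]
    runs <- rle(s$status)
    hi <- cumsum(runs$lengths)
    lo <- hi - runs$lengths + 1L
    for (r in which(runs$values %in% c("gain", "loss"))) {
      ev_start <- s$start[lo[r]]
      ev_end <- s$end[hi[r]]
      parts <- list()
      if (ev_start < cen) parts[[length(parts) + 1L]] <- c(ev_start, min(ev_end, cen), "p")
      if (ev_end > cen) parts[[length(parts) + 1L]] <- c(max(ev_start, cen), ev_end, "q")
      for (pt in parts) {
        arm_len <- arms$length_bp[arms$chrom == ch & arms$arm == pt[3L]]
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, status = runs$values[r],
          start = as.numeric(pt[1L]), end = as.numeric(pt[2L]), arm = pt[3L],
          arm_fraction = (as.numeric(pt[2L]) - as.numeric(pt[1L])) / arm_len,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), status = character(),
                      start = numeric(), end = numeric(), arm = character(),
                      arm_fraction = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify alteration events as focal, arm or chromosome level
#'
#' Focal: the event spans less than 50% of its arm. Among non-focal events,
#' a chromosome's events of one status are chromosome-level when both arms
#' carry a non-focal event of that status covering at least
#' `arm_coverage_min` of the arm; every remaining non-focal event is
#' arm-level.
#'
#' @param events output of [build_events()].
#' @param genome a [genome_model()].
#' @param cfg an [lga_config()].
#' @return `events` with a `level` column.
#' @export
classify_events <- function(events, genome, cfg = lga_config()) {
  if (!nrow(events)) {
    events$level <- character()
    return(events)
  }
  events$level <- ifelse(events$arm_fraction < 0.5, "focal", "arm")
  for (ch in unique(events$chrom)) {
    for (st in c("gain", "loss")) {
      sel <- events$chrom == ch & events$status == st & events$level != "focal"
      covered <- events$arm_fraction >= cfg$arm_coverage_min
      p_ok <- any(sel & covered & events$arm == "p")
      q_ok <- any(sel & covered & events$arm == "q")
      if (p_ok && q_ok) events$level[sel & covered] <- "chromosome"
    }
  }
  events
}

#' SCNA scores: event counts per level and direction
#'
#' Counts classified events; the two arms of a chromosome-level change
#' count once per chromosome.
#'
#' @param events classified events from [classify_events()].
#' @return Named list: `focal_amp`, `focal_del`, `arm_amp`, `arm_del`,
#'   `chrom_amp`, `chrom_del`.
#' @export
scna_scores <- function(events) {
  cnt <- function(level, status) {
    sel <- events$level == level & events$status == status
    if (level == "chromosome") length(unique(events$chrom[sel])) else sum(sel)
  }
  list(focal_amp = cnt("focal", "gain"), focal_del = cnt("focal", "loss"),
       arm_amp = cnt("arm", "gain"), arm_del = cnt("arm", "loss"),
       chrom_amp = cnt("chromosome", "gain"), chrom_del = cnt("chromosome", "loss"))
}

# absolute shifts between adjacent segments on one chromosome, with lengths
adjacent_pairs <- function(profile, genome = NULL) {
  out <- list()
  for (ch in unique(profile$chrom)) {
    s <- profile[profile$chrom == ch, , drop = FALSE]
    if (nrow(s) < 2L) next
    i <- seq_len(nrow(s) - 1L)
    cen <- if (is.null(genome)) NA_real_ else genome$centromere_bp[match(ch, genome$chrom)]
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch,
      left_len = s$end[i] - s$start[i],
      right_len = s$end[i + 1L] - s$start[i + 1L],
      gap = s$start[i + 1L] - s$end[i],
      delta = abs(s$mean_log2[i + 1L] - s$mean_log2[i]),
      at_centromere = if (is.na(cen)) FALSE else (s$end[i] <= cen & s$start[i + 1L] >= cen),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), left_len = numeric(),
                      right_len = numeric(), gap = numeric(), delta = numeric(),
                      at_centromere = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Estimate the per-profile one-copy log-ratio cutoff
#'
#' Takes absolute mean shifts over adjacent pairs of large segments
#' (centromere junctions excluded when a genome is given), keeps those in
#' `[cutoff_floor, cutoff_ceiling]`, and returns the midpoint of the modal
#' histogram bin (width `cutoff_bin`, ties to the smaller bin). Falls back
#' to `cutoff_fallback` with fewer than `min_pairs` eligible shifts.
#'
#' @param profile a [cn_profile()].
#' @param cfg an [lga_config()].
#' @param genome optional [genome_model()] for centromere exclusion.
#' @return The cutoff (log2, > 0).
#' @export
estimate_one_copy_cutoff <- function(profile, cfg = lga_config(), genome = NULL) {
  stopifnot(inherits(profile, "cn_profile"))
  profile <- drop_sex_chroms(profile, cfg)
  pairs <- adjacent_pairs(profile, genome)
  big <- cfg$large_segment_mb * 1e6
  d <- pairs$delta[pairs$left_len >= big & pairs$right_len >= big &
                     !pairs$at_centromere &
                     pairs$delta >= cfg$cutoff_floor &
                     pairs$delta <= cfg$cutoff_ceiling]
  if (length(d) < cfg$min_pairs) return(cfg$cutoff_fallback)
  breaks <- seq(cfg$cutoff_floor,
                cfg$cutoff_ceiling + cfg$cutoff_bin, by = cfg$cutoff_bin)
  bin <- findInterval(d, breaks, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  modal <- which.max(counts) # first max = smaller bin on ties
  breaks[modal] + cfg$cutoff_bin / 2
}

merge_rows <- function(s, i, j) {
  # replace rows i..j (same chromosome) by one length-weighted segment
  len <- s$end[i:j] - s$start[i:j]
  merged <- s[i, , drop = FALSE]
  merged$end <- s$end[j]
  merged$mean_log2 <- sum(s$mean_log2[i:j] * len) / sum(len)
  merged$status <- NA_character_
  merged$n_probes <- sum(s$n_probes[i:j])
  rbind(if (i > 1L) s[seq_len(i - 1L), , drop = FALSE] else NULL,
        merged,
        if (j < nrow(s)) s[(j + 1L):nrow(s), , drop = FALSE] else NULL)
}

#' Step-wise smoothing of a segmented profile
#'
#' Repeatedly merges the adjacent pair of same-chromosome segments (both at
#' least `small_segment_mb` long, never across the centromere) whose
#' absolute mean shift is smallest among pairs below the working threshold
#' `cutoff * (1 - step_tolerance)`; the pair is replaced by its
#' length-weighted mean. Iterates to a fixpoint; ties break by genomic
#' position.
#'
#' @param profile a [cn_profile()].
#' @param cutoff one-copy cutoff from [estimate_one_copy_cutoff()].
#' @param cfg an [lga_config()].
#' @param genome optional [genome_model()] (enables the centromere rule).
#' @return The smoothed profile.
#' @export
smooth_profile <- function(profile, cutoff, cfg = lga_config(), genome = NULL) {
  stopifnot(inherits(profile, "cn_profile"), cutoff > 0)
  thr <- lga_threshold(cutoff, cfg)
  small <- cfg$small_segment_mb * 1e6
  s <- as.data.frame(profile)
  repeat {
    if (nrow(s) < 2L) break
    i <- seq_len(nrow(s) - 1L)
    same <- s$chrom[i] == s$chrom[i + 1L]
    len_ok <- (s$end[i] - s$start[i]) >= small &
      (s$end[i + 1L] - s$start[i + 1L]) >= small
    cen_ok <- rep(TRUE, length(i))
    if (!is.null(genome)) {
      cen <- genome$centromere_bp[match(s$chrom[i], genome$chrom)]
      cen_ok <- is.na(cen) | !(s$end[i] <= cen & s$start[i + 1L] >= cen)
    }
    delta <- abs(s$mean_log2[i + 1L] - s$mean_log2[i])
    cand <- which(same & len_ok & cen_ok & delta < thr)
    if (!length(cand)) break
    k <- cand[which.min(delta[cand])] # first minimum = leftmost
    s <- merge_rows(s, k, k + 1L)
  }
  out <- cn_profile(s, sample_id = sample_id(profile))
  out
}

#' Integrate small and interstitial segments
#'
#' Two passes, both iterated to fixpoints. (1) Interstitial filtering: a
#' copy-number alteration shorter than `large_segment_mb` flanked by two
#' large segments whose means differ by less than the working threshold is
#' absorbed into both (three-way length-weighted merge). (2) Small-segment
#' integration: every segment shorter than `small_segment_mb` merges into
#' the same-chromosome neighbour whose mean is closer (ties to the left;
#' chromosome-terminal small segments merge inward).
#'
#' @inheritParams smooth_profile
#' @return The integrated profile.
#' @export
integrate_small_segments <- function(profile, cutoff, cfg = lga_config(),
                                     genome = NULL) {
  stopifnot(inherits(profile, "cn_profile"), cutoff > 0)
  thr <- lga_threshold(cutoff, cfg)
  big <- cfg$large_segment_mb * 1e6
  small <- cfg$small_segment_mb * 1e6
  s <- as.data.frame(profile)
  seg_len <- function(s, i) s$end[i] - s$start[i]
  # pass 1: interstitial CNAs between concordant large flanks
  repeat {
    done <- TRUE
    for (k in seq_len(nrow(s))) {
      if (k == 1L || k == nrow(s)) next
      if (s$chrom[k - 1L] != s$chrom[k] || s$chrom[k + 1L] != s$chrom[k]) next
      if (seg_len(s, k) >= big) next
      if (seg_len(s, k - 1L) < big || seg_len(s, k + 1L) < big) next
      if (abs(s$mean_log2[k + 1L] - s$mean_log2[k - 1L]) >= thr) next
      s <- merge_rows(s, k - 1L, k + 1L)
      done <- FALSE
      break
    }
    if (done) break
  }
  # pass 2: small segments into the closer-mean neighbour
  repeat {
    done <- TRUE
    for (k in seq_len(nrow(s))) {
      if (seg_len(s, k) >= small) next
      left_ok <- k > 1L && s$chrom[k - 1L] == s$chrom[k]
      right_ok <- k < nrow(s) && s$chrom[k + 1L] == s$chrom[k]
      if (!left_ok && !right_ok) next
      go_left <- if (left_ok && right_ok) {
        abs(s$mean_log2[k - 1L] - s$mean_log2[k]) <=
          abs(s$mean_log2[k + 1L] - s$mean_log2[k])
      } else left_ok
      s <- if (go_left) merge_rows(s, k - 1L, k) else merge_rows(s, k, k + 1L)
      done <- FALSE
      break
    }
    if (done) break
  }
  cn_profile(s, sample_id = sample_id(profile))
}

#' Count large genomic alterations (LGAs)
#'
#' On a smoothed, integrated profile: an LGA is a break between two
#' adjacent same-arm segments, both at least `large_segment_mb` long, with
#' an inter-segment gap of at most `max_gap_mb` and an absolute mean shift
#' of at least the working threshold `cutoff * (1 - step_tolerance)`.
#' Breaks at or across the centromere are never counted.
#'
#' @inheritParams smooth_profile
#' @param genome a [genome_model()] (needed for the centromere rule).
#' @return Integer LGA count.
#' @export
count_lga <- function(profile, cutoff, cfg = lga_config(), genome = NULL) {
  stopifnot(inherits(profile, "cn_profile"), cutoff > 0)
  profile <- drop_sex_chroms(profile, cfg)
  thr <- lga_threshold(cutoff, cfg)
  big <- cfg$large_segment_mb * 1e6
  pairs <- adjacent_pairs(profile, genome)
  sum(pairs$left_len >= big & pairs$right_len >= big &
        pairs$gap <= cfg$max_gap_mb * 1e6 &
        !pairs$at_centromere &
        pairs$delta >= thr)
}

#' HRD call from an LGA count
#'
#' HRD iff the LGA count reaches `hrd_threshold` (inclusive); `NA` counts
#' (failed upstream QC) give "undetermined".
#'
#' @param lga_count integer LGA count (or `NA`).
#' @param cfg an [lga_config()].
#' @return `"HRD"`, `"HRP"` or `"undetermined"`.
#' @export
call_hrd <- function(lga_count, cfg = lga_config()) {
  ifelse(is.na(lga_count), "undetermined",
         ifelse(lga_count >= cfg$hrd_threshold, "HRD", "HRP"))
}

#' Full instability scoring of one profile
#'
#' Runs every genomic-instability readout on a status-called profile:
#' Genomic Index, focal/arm/chromosome SCNA scores, and the LGA/HRD path
#' (cutoff estimation, smoothing, small-segment integration, re-smoothing,
#' LGA counting, HRD call).
#'
#' @param profile a status-called [cn_profile()].
#' @param genome a [genome_model()].
#' @param cfg an [lga_config()].
#' @return An `instability_scores` list: `sample`, `gi`, `A`, `C`, the six
#'   SCNA counts, `one_copy_cutoff`, `lga`, `hrd_call`.
#' @export
score_profile <- function(profile, genome, cfg = lga_config()) {
  gi <- genomic_index(profile, cfg)
  ev <- classify_events(build_events(profile, genome, cfg), genome, cfg)
  sc <- scna_scores(ev)
  cutoff <- estimate_one_copy_cutoff(profile, cfg, genome)
  sm <- smooth_profile(drop_sex_chroms(profile, cfg), cutoff, cfg, genome)
  sm <- integrate_small_segments(sm, cutoff, cfg, genome)
  sm <- smooth_profile(sm, cutoff, cfg, genome)
  lga <- count_lga(sm, cutoff, cfg, genome)
  structure(c(list(sample = sample_id(profile), gi = gi$gi, A = gi$A, C = gi$C),
              sc,
              list(one_copy_cutoff = cutoff, lga = lga,
                   hrd_call = call_hrd(lga, cfg))),
            class = "instability_scores")
}

#' @export
print.instability_scores <- function(x, ...) {
  cat(sprintf("sample %s: GI=%.2f (A=%d, C=%d), LGA=%d (cutoff %.3f) -> %s\n",
              x$sample, x$gi, x$A, x$C, x$lga, x$one_copy_cutoff, x$hrd_call))
  cat(sprintf("  SCNA focal %d+/%d-, arm %d+/%d-, chromosome %d+/%d-\n",
              x$focal_amp, x$focal_del, x$arm_amp, x$arm_del,
              x$chrom_amp, x$chrom_del))
  invisible(x)
}

#' Score a list of profiles into a table
#'
#' @param profiles list of status-called [cn_profile()] objects.
#' @param genome a [genome_model()].
#' @param cfg an [lga_config()].
#' @return Data frame, one row per sample, columns `sample`, `gi`, `A`,
#'   `C`, `focal_amp`, `focal_del`, `arm_amp`, `arm_del`, `chrom_amp`,
#'   `chrom_del`, `one_copy_cutoff`, `lga`, `hrd_call`.
#' @export
score_cohort <- function(profiles, genome, cfg = lga_config()) {
  rows <- lapply(profiles, function(p) {
    s <- score_profile(p, genome, cfg)
    as.data.frame(unclass(s), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
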