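# Independent brute-force oracles. These deliberately re-derive each
# quantity by naive iteration, without calling the package's vectorized
# implementations, so implementation and oracle can disagree.

# GI by naive row iteration: walk the segment table, counting transitions
# into altered states per chromosome.
oracle_gi <- function(profile) {
  df <- as.data.frame(profile)
  A <- 0L
  hit <- character()
  prev_chrom <- ""
  prev_status <- ""
  for (i in seq_len(nrow(df))) {
    st <- df$status[i]
    new_run <- df$chrom[i] != prev_chrom || st != prev_status
    if (new_run && (st == "gain" || st == "loss")) {
      A <- A + 1L
      hit <- union(hit, df$chrom[i])
    }
    prev_chrom <- df$chrom[i]
    prev_status <- st
  }
  list(gi = if (A == 0L) 0 else A^2 / length(hit), A = A, C = length(hit))
}

# LGA count by naive loop over adjacent rows with explicit conditions.
oracle_lga <- function(profile, cutoff, cfg, genome) {
  df <- as.data.frame(profile)
  df <- df[!(df$chrom %in% cfg$sex_chroms), ]
  thr <- cutoff * (1 - cfg$step_tolerance)
  count <- 0L
  for (i in seq_len(nrow(df) - 1L)) {
    if (df$chrom[i] != df$chrom[i + 1L]) next
    len_l <- df$end[i] - df$start[i]
    len_r <- df$end[i + 1L] - df$start[i + 1L]
    if (len_l < cfg$large_segment_mb * 1e6) next
    if (len_r < cfg$large_segment_mb * 1e6) next
    if (df$start[i + 1L] - df$end[i] > cfg$max_gap_mb * 1e6) next
    cen <- genome$centromere_bp[genome$chrom == df$chrom[i]]
    if (length(cen) && df$end[i] <= cen && df$start[i + 1L] >= cen) next
    if (abs(df$mean_log2[i + 1L] - df$mean_log2[i]) < thr) next
    count <- count + 1L
  }
  count
}

# Event building + classification by direct re-derivation.
oracle_scna <- function(profile, genome, cfg) {
  df <- as.data.frame(profile)
  df <- df[!(df$chrom %in% cfg$sex_chroms), ]
  ev <- list()
  for (ch in unique(df$chrom)) {
    s <- df[df$chrom == ch, ]
    cen <- genome$centromere_bp[genome$chrom == ch]
    len <- genome$length_bp[genome$chrom == ch]
    i <- 1L
    while (i <= nrow(s)) {
      if (s$status[i] %in% c("gain", "loss")) {
        j <- i
        while (j < nrow(s) && s$status[j + 1L] == s$status[i]) j <- j + 1L
        span <- c(s$start[i], s$end[j])
        for (arm in c("p", "q")) {
          lo <- if (arm == "p") 0 else cen
          hi <- if (arm == "p") cen else len
          a <- max(span[1], lo); b <- min(span[2], hi)
          if (b > a) {
            ev[[length(ev) + 1L]] <- list(chrom = ch, status = s$status[i],
                                          arm = arm, frac = (b - a) / (hi - lo))
          }
        }
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  lev <- character(length(ev))
  for (k in seq_along(ev)) lev[k] <- if (ev[[k]]$frac < 0.5) "focal" else "arm"
  for (k in seq_along(ev)) {
    e <- ev[[k]]
    if (lev[k] == "focal" || e$frac < cfg$arm_coverage_min) next
    other <- if (e$arm == "p") "q" else "p"
    partner <- FALSE
    for (m in seq_along(ev)) {
      o <- ev[[m]]
      if (o$chrom == e$chrom && o$status == e$status && o$arm == other &&
          o$frac >= cfg$arm_coverage_min) partner <- TRUE
    }
    if (partner) lev[k] <- "chromosome"
  }
  cnt <- function(level, status) {
    sel <- which(lev == level & vapply(ev, function(e) e$status, "") == status)
    if (level == "chromosome") {
      length(unique(vapply(ev[sel], function(e) e$chrom, "")))
    } else length(sel)
  }
  list(focal_amp = cnt("focal", "gain"), focal_del = cnt("focal", "loss"),
       arm_amp = cnt("arm", "gain"), arm_del = cnt("arm", "loss"),
       chrom_amp = cnt("chromosome", "gain"), chrom_del = cnt("chromosome", "loss"))
}

# Maxstat by fully naive loops: Nelson-Aalen scores and per-split statistic
# recomputed from scratch for every candidate.
oracle_maxstat_cut <- function(values, time, event, q_range = c(0.1, 0.9)) {
  n <- length(values)
  a <- numeric(n)
  for (i in seq_len(n)) {
    ch <- 0
    for (tt in sort(unique(time[event == 1]))) {
      if (tt <= time[i]) ch <- ch + sum(event == 1 & time == tt) / sum(time >= tt)
    }
    a[i] <- event[i] - ch
  }
  abar <- mean(a)
  ssq <- sum((a - abar)^2)
  v <- sort(unique(values))
  best_cut <- NA_real_; best_stat <- -Inf
  for (j in seq_len(length(v) - 1L)) {
    mu <- (v[j] + v[j + 1L]) / 2
    grp <- values <= mu
    m <- sum(grp)
    if (m / n < q_range[1] || m / n > q_range[2]) next
    S <- sum(a[grp])
    T <- abs(S - m * abar) / sqrt(m * (n - m) / (n * (n - 1)) * ssq)
    if (T > best_stat + 1e-12) {
      best_stat <- T
      best_cut <- mu
    }
  }
  list(best_cutoff = best_cut, max_statistic = best_stat)
}

# random status-called tiling profile on a genome
random_called_profile <- function(genome, max_breaks = 6L,
                                  levels = c(-0.9, -0.6, -0.3, 0, 0, 0.3, 0.6, 0.9)) {
  segs <- list()
  for (ci in seq_len(nrow(genome))) {
    len <- genome$length_bp[ci]
    k <- sample(0:max_breaks, 1L)
    cuts <- sort(sample(seq(5e6, len - 5e6, by = 1e6), k))
    bounds <- c(0, cuts, len)
    segs[[ci]] <- data.frame(
      chrom = genome$chrom[ci],
      start = bounds[-length(bounds)], end = bounds[-1L],
      mean_log2 = sample(levels, k + 1L, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  call_status(cn_profile(do.call(rbind, segs)), seg_config())
}

# survival data with an optional group effect
sim_surv_data <- function(n, hr = 1, rate = 0.05, horizon = 60) {
  grp <- rep(0:1, length.out = n)
  t_ev <- stats::rexp(n, rate * hr^grp)
  time <- pmin(t_ev, horizon)
  data.frame(time = time, event = t_ev <= horizon, group = grp)
}
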