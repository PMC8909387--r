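mk_profile <- function(chrom, start_mb, end_mb, mean_log2) {
  call_status(cn_profile(data.frame(
    chrom = chrom, start = start_mb * 1e6, end = end_mb * 1e6,
    mean_log2 = mean_log2)), seg_config())
}

test_that("genomic index follows A^2/C with run merging", {
  flat <- mk_profile("1", 0, 100, 0)
  expect_equal(genomic_index(flat), list(gi = 0, A = 0L, C = 0L))

  # 4 alterations on 2 chromosomes -> 16/2 = 8
  p <- mk_profile(rep(c("1", "2"), each = 4),
                  c(0, 25, 50, 75, 0, 20, 40, 60),
                  c(25, 50, 75, 100, 20, 40, 60, 80),
                  c(0.6, 0, 0.6, 0, -0.6, 0, -0.6, 0))
  expect_equal(genomic_index(p)[c("A", "C", "gi")], list(A = 4L, C = 2L, gi = 8))

  # adjacent same-status segments merge into one alteration
  p2 <- mk_profile("1", c(0, 10, 20), c(10, 20, 100), c(0.6, 0.7, 0))
  expect_equal(genomic_index(p2)$A, 1L)

  # sex chromosomes are excluded
  p3 <- mk_profile(c("1", "X"), c(0, 0), c(100, 50), c(0.6, 0.6))
  expect_equal(genomic_index(p3)[c("A", "C")], list(A = 1L, C = 1L))
})

test_that("genomic index equals the naive recount oracle on random profiles", {
  g <- toy_genome()
  set.seed(31)
  for (r in 1:50) {
    p <- random_called_profile(g)
    expect_equal(genomic_index(p), oracle_gi(p))
  }
})

test_that("event building merges runs and splits at the centromere", {
  g <- toy_genome() # chr1 centromere 40 Mb, arms 40/60 Mb
  ev <- build_events(mk_profile("1", c(0, 10, 22), c(10, 22, 100), c(0, 0.6, 0)), g)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$arm_fraction, 12 / 40)

  # adjacent same-status segments become one merged event
  p <- mk_profile("1", c(0, 5, 15, 25), c(5, 15, 25, 100), c(0, 0.6, 0.7, 0))
  ev <- build_events(p, g)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 5e6)
  expect_equal(ev$end, 25e6)

  # a gain crossing the centromere splits into p and q parts
  p <- mk_profile("1", c(0, 30, 50), c(30, 50, 100), c(0, 0.6, 0))
  ev <- build_events(p, g)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$arm, c("p", "q"))
  expect_equal(ev$arm_fraction, c(10 / 40, 10 / 60))
})

test_that("event classification follows the focal/arm/chromosome rules", {
  g <- toy_genome()
  # 30% of the p arm -> focal
  ev <- classify_events(build_events(mk_profile("1", c(0, 12), c(12, 100), c(0.6, 0)), g), g)
  expect_equal(ev$level, "focal")

  # 90% of p and 85% of q with the same status -> both chromosome-level
  p <- mk_profile("1", c(0, 36, 40, 91), c(36, 40, 91, 100), c(0.6, 0, 0.6, 0))
  ev <- classify_events(build_events(p, g), g)
  expect_equal(sort(ev$level[ev$status == "gain"]), c("chromosome", "chromosome"))
  expect_equal(scna_scores(ev)$chrom_amp, 1L) # both arms count once

  # 90% of p only -> arm level
  p <- mk_profile("1", c(0, 36), c(36, 100), c(0.6, 0))
  ev <- classify_events(build_events(p, g), g)
  expect_equal(ev$level, "arm")

  # opposite signs on the two arms stay arm-level
  p <- mk_profile("1", c(0, 40), c(40, 100), c(0.6, -0.6))
  ev <- classify_events(build_events(p, g), g)
  expect_equal(ev$level, c("arm", "arm"))
})

test_that("scna scores count events by level and direction", {
  expect_equal(scna_scores(data.frame(chrom = character(), status = character(),
                                      level = character()))$focal_amp, 0L)
  g <- toy_genome()
  set.seed(17)
  for (r in 1:50) {
    p <- random_called_profile(g)
    got <- scna_scores(classify_events(build_events(p, g), g))
    expect_equal(got, oracle_scna(p, g, lga_config()))
  }
})

test_that("one-copy cutoff estimation finds the shift mode", {
  # all inter-segment steps exactly 0.58
  p <- mk_profile("1", seq(0, 80, 20), seq(20, 100, 20), c(0, 0.58, 0, 0.58, 0))
  cut <- estimate_one_copy_cutoff(p, lga_config(min_pairs = 4))
  expect_gte(cut, 0.55); expect_lte(cut, 0.60)

  # mixture of null and 0.6 steps: the sub-floor shifts are ignored
  set.seed(23)
  means <- rep(c(0, 0.6), 10) + rnorm(20, 0, 0.005)
  p <- mk_profile("big", seq(0, 380, 20), seq(20, 400, 20), means)
  cut <- estimate_one_copy_cutoff(p, lga_config())
  expect_gte(cut, 0.55); expect_lte(cut, 0.65)

  # too few pairs -> fallback
  p <- mk_profile("1", c(0, 50), c(50, 100), c(0, 0.6))
  expect_equal(estimate_one_copy_cutoff(p, lga_config()), 0.3)
})

test_that("smoothing merges sub-cutoff steps and respects split-invariance", {
  cfg <- lga_config()
  # equal-mean split halves re-merge
  p <- mk_profile("1", c(0, 50), c(50, 100), c(0.2, 0.2))
  sm <- smooth_profile(p, 0.3, cfg)
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$mean_log2, 0.2)

  # steps of 0.1 merge under cutoff 0.3; steps of 0.6 survive
  p <- mk_profile("1", c(0, 30, 60), c(30, 60, 100), c(0, 0.1, 0.7))
  sm <- smooth_profile(p, 0.3, cfg)
  expect_equal(nrow(sm), 2L)
  expect_equal(sm$mean_log2[1], (30 * 0 + 30 * 0.1) / 60)

  # smoothing(random split of x) == smoothing(x)
  g <- toy_genome()
  set.seed(41)
  for (r in 1:50) {
    p <- random_called_profile(g, max_breaks = 4L)
    base <- smooth_profile(p, 0.45, cfg, g)
    df <- as.data.frame(p)
    i <- sample(nrow(df), 1L)
    if (df$end[i] - df$start[i] < 6.5e6) next # halves must stay mergeable
    mid <- (df$start[i] + df$end[i]) / 2
    split_df <- rbind(df[seq_len(i - 1L), ],
                      transform(df[i, ], end = mid),
                      transform(df[i, ], start = mid),
                      df[seq_len(nrow(df)) > i, ])
    p2 <- call_status(cn_profile(split_df), seg_config())
    resm <- smooth_profile(p2, 0.45, cfg, g)
    expect_equal(resm$mean_log2, base$mean_log2, tolerance = 1e-9)
    expect_equal(resm$start, base$start)
  }
})

test_that("small-segment integration absorbs interstitial CNAs", {
  cfg <- lga_config()
  # large(0) | 8 Mb CNA (0.6) | large(0) -> one ~neutral segment
  p <- mk_profile("1", c(0, 20, 28), c(20, 28, 48), c(0, 0.6, 0))
  out <- integrate_small_segments(p, 0.3, cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$mean_log2, (20 * 0 + 8 * 0.6 + 20 * 0) / 48)
  expect_lt(out$mean_log2, 0.2) # neutral after absorption

  # a small chromosome-leading segment merges rightward
  p <- mk_profile("1", c(0, 2, 30), c(2, 30, 100), c(0.5, 0, 0))
  out <- integrate_small_segments(p, 0.3, cfg)
  expect_equal(nrow(out), 2L)
  expect_equal(out$start[1], 0)
  expect_equal(out$mean_log2[1], 2 * 0.5 / 30)

  # small segment between unequal flanks goes to the closer mean
  p <- mk_profile("1", c(0, 20, 22), c(20, 22, 100), c(0, 0.55, 0.6))
  out <- integrate_small_segments(p, 0.3, cfg)
  expect_equal(nrow(out), 2L)
  expect_equal(out$end[1], 20e6) # merged right, not left

  # nothing small -> identity
  p <- mk_profile("1", c(0, 50), c(50, 100), c(0, 0.6))
  expect_equal(as.data.frame(integrate_small_segments(p, 0.3, cfg)),
               as.data.frame(p))
})

test_that("LGA counting matches the worked examples and the oracle", {
  g <- genome_model("1", 200e6, 110e6) # one 110 Mb p arm
  cfg <- lga_config()
  # 5 alternating 20 Mb segments -> 4 LGAs at cutoff 0.3
  p <- mk_profile("1", c(seq(0, 80, 20), 100), c(seq(20, 100, 20), 200),
                  c(rep(c(0, 0.6), length.out = 5), 0))
  expect_equal(count_lga(p, 0.3, cfg, g), 4L)

  # single-segment arms -> 0
  flat <- mk_profile("1", 0, 200, 0)
  expect_equal(count_lga(flat, 0.3, cfg, g), 0L)

  # the 8 Mb middle CNA between equal flanks vanishes after filtering
  p <- mk_profile("1", c(0, 20, 28), c(20, 28, 48), c(0, 0.6, 0))
  filtered <- integrate_small_segments(p, 0.3, cfg, g)
  expect_equal(count_lga(filtered, 0.3, cfg, g), 0L)

  # breaks across the centromere are never counted
  p <- mk_profile("1", c(0, 110), c(110, 200), c(0, 0.6))
  expect_equal(count_lga(p, 0.3, cfg, g), 0L)

  # oracle equivalence on random profiles
  gt <- toy_genome()
  set.seed(53)
  for (r in 1:50) {
    p <- random_called_profile(gt)
    cut <- runif(1, 0.2, 0.7)
    expect_equal(count_lga(p, cut, cfg, gt), oracle_lga(p, cut, cfg, gt))
  }
})

test_that("HRD calling is threshold-inclusive", {
  cfg <- lga_config()
  expect_equal(call_hrd(18L, cfg), "HRD")
  expect_equal(call_hrd(17L, cfg), "HRP")
  expect_equal(call_hrd(0L, cfg), "HRP")
  expect_equal(call_hrd(NA_integer_, cfg), "undetermined")
})

test_that("noise-free simulated profiles score back to their construction", {
  g <- hg_autosomes()
  set.seed(61)
  for (k in c(0L, 5L, 10L, 17L, 18L, 25L)) {
    for (ne in 0:2) {
      p <- simulate_profile(g, target_lga = k, n_focal = ne, n_arm = ne, n_chrom = ne)
      s <- score_profile(p, g)
      e <- attr(p, "expected")
      expect_equal(s$lga, e$lga)
      expect_equal(s$hrd_call, if (k >= 18) "HRD" else "HRP")
      expect_equal(s$focal_amp, e$focal_amp)
      expect_equal(s$focal_del, e$focal_del)
      expect_equal(s$arm_amp, e$arm_amp)
      expect_equal(s$arm_del, e$arm_del)
      expect_equal(s$chrom_amp, e$chrom_amp)
      expect_equal(s$chrom_del, e$chrom_del)
      expect_equal(s$A, e$A)
      expect_equal(s$C, e$C)
      # with no LGA staircases the raw requested counts are recovered as-is
      if (k == 0L) expect_equal(s$arm_amp + s$arm_del, ne)
    }
  }
})

test_that("adding one qualifying break raises the LGA count by exactly 1", {
  g <- hg_autosomes()
  set.seed(67)
  for (k in c(3L, 9L, 15L)) {
    p1 <- simulate_profile(g, target_lga = k)
    p2 <- simulate_profile(g, target_lga = k + 1L)
    s1 <- score_profile(p1, g)
    s2 <- score_profile(p2, g)
    expect_equal(s2$lga - s1$lga, 1L)
  }
})
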