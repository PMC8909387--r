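#' Simulate a noise-free segmented profile with controlled scores
#'
#' Constructs a tiling, status-called profile whose instability scores are
#' known exactly by design:
#'
#' * `target_lga` copy-number breaks are realized as full-arm "staircases"
#'   of alternating gain levels (`step_log2`, `2 * step_log2`) with every
#'   tread at least `min_seg_mb` long; at most one staircase arm per
#'   chromosome, so each hosting arm contributes exactly one extra
#'   arm-level amplification and nothing else.
#' * focal events are single blocks of `focal_mb` centered in an otherwise
#'   flat arm (always < 50% of the arm, and short enough to be filtered as
#'   interstitial CNAs before LGA counting);
#' * arm events cover one full arm; chromosome events cover both arms of a
#'   chromosome with one status.
#'
#' Event directions alternate gain, loss, gain, ... within each level.
#' Chromosomes are drawn without replacement using the current RNG, so a
#' fixed seed gives identical output. The exact expected scores (including
#' the staircase-induced arm amplifications) are attached as
#' `attr(profile, "expected")`.
#'
#' @param genome a [genome_model()].
#' @param target_lga exact LGA count to realize.
#' @param n_focal,n_arm,n_chrom event counts per level.
#' @param step_log2 one-copy log-ratio step (default 0.6).
#' @param focal_mb focal block size in Mb (default 8; must stay below
#'   `large_segment_mb` so focal events never spawn LGAs).
#' @param min_seg_mb minimum staircase tread in Mb (default 12, safely
#'   above the 10 Mb LGA flank bound even after noisy re-segmentation).
#' @param cfg an [lga_config()] (sex-chromosome exclusion).
#' @return A status-called [cn_profile()]; errors when the genome cannot
#'   host the requested events (never silently fewer).
#' @export
simulate_profile <- function(genome, target_lga = 0L, n_focal = 0L,
                             n_arm = 0L, n_chrom = 0L, step_log2 = 0.6,
                             focal_mb = 8, min_seg_mb = 12,
                             cfg = lga_config()) {
  stopifnot(inherits(genome, "genome_model"), target_lga >= 0,
            n_focal >= 0, n_arm >= 0, n_chrom >= 0, step_log2 > 0,
            focal_mb > 0, min_seg_mb > cfg$large_segment_mb)
  autos <- genome[!(genome$chrom %in% cfg$sex_chroms), , drop = FALSE]
  chroms <- autos$chrom[sample.int(nrow(autos))]
  arms <- arm_table(genome_model(autos$chrom, autos$length_bp, autos$centromere_bp))

  take_chroms <- function(k, why) {
    if (k > length(chroms)) stop("capacity exceeded: not enough chromosomes for ", why)
    got <- chroms[seq_len(k)]
    chroms <<- chroms[-seq_len(k)]
    got
  }
  blocks <- list() # chrom, start, end, level
  add_block <- function(chrom, start, end, level) {
    blocks[[length(blocks) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, level = level,
      stringsAsFactors = FALSE)
  }
  sign_of <- function(i) if (i %% 2L == 1L) 1 else -1

  # chromosome-level events: whole chromosome, one segment
  for (i in seq_len(n_chrom)) {
    ch <- take_chroms(1L, "chromosome events")
    len <- autos$length_bp[match(ch, autos$chrom)]
    add_block(ch, 0, len, sign_of(i) * step_log2)
  }
  # arm-level events: the longer arm of a fresh chromosome
  arm_used <- character()
  for (i in seq_len(n_arm)) {
    ch <- take_chroms(1L, "arm events")
    a <- arms[arms$chrom == ch, , drop = FALSE]
    a <- a[which.max(a$length_bp), , drop = FALSE]
    add_block(ch, a$start, a$end, sign_of(i) * step_log2)
    arm_used <- c(arm_used, ch)
  }
  # focal events: one centered block per fresh chromosome (longer arm)
  for (i in seq_len(n_focal)) {
    ch <- take_chroms(1L, "focal events")
    a <- arms[arms$chrom == ch, , drop = FALSE]
    a <- a[which.max(a$length_bp), , drop = FALSE]
    if (focal_mb * 1e6 >= 0.5 * a$length_bp) {
      stop("capacity exceeded: focal block would reach 50% of arm on chromosome ", ch)
    }
    s <- a$start + (a$length_bp - focal_mb * 1e6) / 2
    add_block(ch, s, s + focal_mb * 1e6, sign_of(i) * step_log2)
  }
  # LGA staircases: one arm per remaining chromosome, largest arms first
  n_stairs <- 0L
  if (target_lga > 0L) {
    pool <- arms[arms$chrom %in% chroms, , drop = FALSE]
    if (!nrow(pool)) {
      stop("capacity exceeded: no chromosomes left to host ", target_lga, " LGAs")
    }
    pool <- do.call(rbind, lapply(split(pool, pool$chrom), function(a) {
      a[which.max(a$length_bp), , drop = FALSE]
    }))
    pool <- pool[order(-pool$length_bp), , drop = FALSE]
    pool$capacity <- pmax(floor(pool$length_bp / (min_seg_mb * 1e6)) - 1L, 0L)
    if (sum(pool$capacity) < target_lga) {
      stop("capacity exceeded: genome can host at most ", sum(pool$capacity),
           " LGAs with ", min_seg_mb, " Mb treads, need ", target_lga)
    }
    left <- as.integer(target_lga)
    r <- 1L
    while (left > 0L) {
      k <- min(left, pool$capacity[r])
      a <- pool[r, ]
      bounds <- a$start + round(a$length_bp * seq(0, k + 1L) / (k + 1L))
      for (j in seq_len(k + 1L)) {
        add_block(a$chrom, bounds[j], bounds[j + 1L],
                  step_log2 * (1 + (j %% 2L)))
      }
      n_stairs <- n_stairs + 1L
      left <- left - k
      r <- r + 1L
    }
  }

  # assemble: fill everything not covered by a block with level 0
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               level = numeric(), stringsAsFactors = FALSE)
  segs <- list()
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]
    len <- genome$length_bp[ci]
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    pos <- 0
    for (k in seq_len(nrow(b))) {
      if (b$start[k] > pos) {
        segs[[length(segs) + 1L]] <- data.frame(
          chrom = ch, start = pos, end = b$start[k], mean_log2 = 0,
          stringsAsFactors = FALSE)
      }
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = b$start[k], end = b$end[k], mean_log2 = b$level[k],
        stringsAsFactors = FALSE)
      pos <- b$end[k]
    }
    if (pos < len) {
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = pos, end = len, mean_log2 = 0,
        stringsAsFactors = FALSE)
    }
  }
  prof <- cn_profile(do.call(rbind, segs), sample_id = "sim")
  prof <- call_status(prof, seg_config())
  half <- function(n) c(ceiling(n / 2), floor(n / 2)) # gains, losses
  f <- half(n_focal); a <- half(n_arm); c2 <- half(n_chrom)
  attr(prof, "expected") <- list(
    lga = as.integer(target_lga),
    focal_amp = f[1L], focal_del = f[2L],
    arm_amp = a[1L] + n_stairs, arm_del = a[2L],
    chrom_amp = c2[1L], chrom_del = c2[2L],
    staircase_arms = n_stairs,
    A = n_focal + n_arm + n_chrom + n_stairs,
    C = n_focal + n_arm + n_chrom + n_stairs
  )
  attr(prof, "true_lga") <- as.integer(target_lga)
  prof
}

#' Render noisy array probes from a segmented profile
#'
#' Probes are laid at regular positions (`spacing/2, 3*spacing/2, ...`)
#' along each chromosome covered by the profile; each probe takes its
#' segment's mean plus Gaussian noise.
#'
#' @param profile a tiling [cn_profile()].
#' @param probe_spacing probe spacing in bp (> 0).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @return A [cn_probes()] series.
#' @export
render_probes <- function(profile, probe_spacing = 1e5, noise_sd = 0) {
  stopifnot(inherits(profile, "cn_profile"), probe_spacing > 0, noise_sd >= 0)
  out <- list()
  for (ch in unique(profile$chrom)) {
    s <- profile[profile$chrom == ch, , drop = FALSE]
    pos <- seq(probe_spacing / 2, max(s$end), by = probe_spacing)
    idx <- findInterval(pos, s$start)
    keep <- idx >= 1L & pos < s$end[pmin(idx, nrow(s))]
    pos <- pos[keep]; idx <- idx[keep]
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, pos = pos,
      log2ratio = s$mean_log2[idx] + if (noise_sd > 0) stats::rnorm(length(pos), 0, noise_sd) else 0,
      stringsAsFactors = FALSE)
  }
  cn_probes(do.call(rbind, out), sample_id = sample_id(profile))
}

#' Default marker specification
#'
#' Conditional marker distributions given latent HRD status. HLA-E defaults
#' to the published conditional proportions (high in 89% of HRD vs 44% of
#' HRP tumors, on the 0-3 scale dichotomized at >= 2); the MXA H-score is
#' higher in HRD; every other marker defaults to 50%/50% (no published
#' joint structure to emulate). Scales: `semiquant` (0-3, "high" drawn
#' then a level sampled within \{2,3\} or \{0,1\}), `binary`, `count`
#' (Poisson), `hscore` (normal clipped to [0, 300]).
#'
#' @return Named list of marker specs.
#' @export
default_marker_spec <- function() {
  list(
    HLA_E = list(scale = "semiquant", p_high_hrd = 0.89, p_high_hrp = 0.44),
    CD3_tumor = list(scale = "semiquant", p_high_hrd = 0.5, p_high_hrp = 0.5),
    ICOS = list(scale = "binary", p_high_hrd = 0.5, p_high_hrp = 0.5),
    FOXP3 = list(scale = "binary", p_high_hrd = 0.5, p_high_hrp = 0.5),
    IgG = list(scale = "binary", p_high_hrd = 0.5, p_high_hrp = 0.5),
    CD39_vessels = list(scale = "binary", p_high_hrd = 0.5, p_high_hrp = 0.5),
    CD8 = list(scale = "count", lambda_hrd = 60, lambda_hrp = 40),
    MXA = list(scale = "hscore", mean_hrd = 150, mean_hrp = 100, sd = 40)
  )
}

#' Simulate marker values conditional on HRD status
#'
#' Each marker is drawn independently given the latent HRD state.
#'
#' @param true_hrd logical vector of latent HRD states.
#' @param marker_spec named list as in [default_marker_spec()].
#' @return Data frame, one column per marker.
#' @export
simulate_markers <- function(true_hrd, marker_spec = default_marker_spec()) {
  n <- length(true_hrd)
  out <- list()
  for (mk in names(marker_spec)) {
    sp <- marker_spec[[mk]]
    out[[mk]] <- switch(
      sp$scale,
      binary = {
        p <- ifelse(true_hrd, sp$p_high_hrd, sp$p_high_hrp)
        stats::rbinom(n, 1L, p)
      },
      semiquant = {
        p <- ifelse(true_hrd, sp$p_high_hrd, sp$p_high_hrp)
        high <- stats::rbinom(n, 1L, p)
        ifelse(high == 1L, sample(2:3, n, replace = TRUE),
               sample(0:1, n, replace = TRUE))
      },
      count = {
        lam <- ifelse(true_hrd, sp$lambda_hrd, sp$lambda_hrp)
        stats::rpois(n, lam)
      },
      hscore = {
        m <- ifelse(true_hrd, sp$mean_hrd, sp$mean_hrp)
        pmin(pmax(stats::rnorm(n, m, sp$sd), 0), 300)
      },
      stop("unknown marker scale: ", sp$scale)
    )
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Survival generator specification
#'
#' Proportional-hazards times by inversion: `T = H0^{-1}(-log(U) /
#' exp(beta'x))` with an exponential (`shape = 1`) or Weibull baseline of
#' cumulative hazard `H0(t) = (rate * t)^shape`. Censoring is the minimum
#' of an administrative horizon and an exponential random censoring time.
#' The default baseline rate puts the reference-group median around 19.6
#' months (trial-scale progression times).
#'
#' @param dist `"exponential"` or `"weibull"`.
#' @param rate baseline rate (1/months).
#' @param shape Weibull shape (1 = exponential).
#' @param admin_horizon administrative censoring time, months (> 0).
#' @param censor_rate exponential random-censoring rate (0 disables).
#' @return A `survival_spec` list.
#' @export
survival_spec <- function(dist = c("exponential", "weibull"),
                          rate = log(2) / 19.6, shape = 1,
                          admin_horizon = 72, censor_rate = 0.005) {
  dist <- match.arg(dist)
  if (dist == "exponential") shape <- 1
  if (admin_horizon <= 0) stop("administrative censoring horizon must be > 0")
  stopifnot(rate > 0, shape > 0, censor_rate >= 0)
  structure(list(dist = dist, rate = rate, shape = shape,
                 admin_horizon = admin_horizon, censor_rate = censor_rate),
            class = "survival_spec")
}

#' Simulate survival times under proportional hazards
#'
#' @param linear_predictor numeric vector `beta' x`, one entry per subject.
#' @param spec a [survival_spec()].
#' @return Data frame with `time` (months, > 0) and `event` (logical).
#' @export
simulate_survival <- function(linear_predictor, spec = survival_spec()) {
  stopifnot(inherits(spec, "survival_spec"))
  n <- length(linear_predictor)
  u <- stats::runif(n)
  t_event <- (-log(u) / exp(linear_predictor))^(1 / spec$shape) / spec$rate
  t_cens <- rep(spec$admin_horizon, n)
  if (spec$censor_rate > 0) {
    t_cens <- pmin(t_cens, stats::rexp(n, spec$censor_rate))
  }
  data.frame(time = pmax(pmin(t_event, t_cens), 1e-9),
             event = t_event <= t_cens)
}

#' Cohort generator configuration
#'
#' Defaults state the simulated world once: 103 patients (the translational
#' cohort size), HRD prevalence 0.58 (39 HRD / 28 HRP among determinable
#' profiles), latent LGA means 25 (HRD) and 6 (HRP), event rates typical of
#' a copy-number-driven carcinoma (8 focal / 4 arm / 2 chromosome expected
#' events per genome), one-copy step 0.6, 100 kb probe spacing with 0.1
#' noise SD. Survival: PFS baseline median 19.6 months with a protective
#' log-hazard `log(0.52)` for CD3-high tumors; OS baseline median 52.9
#' months with `log(0.36)` for HLA-E-high tumors.
#'
#' @param n_patients cohort size.
#' @param hrd_prevalence probability of the latent HRD state.
#' @param lga_mean_hrd,lga_mean_hrp Poisson means of the latent LGA count.
#' @param focal_rate,arm_rate,chrom_rate Poisson event-count means.
#' @param step_log2 one-copy log-ratio step.
#' @param probe_spacing probe spacing in bp.
#' @param noise_sd probe noise SD.
#' @param marker_spec see [default_marker_spec()].
#' @param pfs_spec,os_spec [survival_spec()]s for the two endpoints.
#' @param pfs_beta,os_beta named log-hazard vectors over columns of the
#'   patient table (built after markers are drawn).
#' @param genome a [genome_model()].
#' @param seed integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 103L, hrd_prevalence = 0.58,
                          lga_mean_hrd = 25, lga_mean_hrp = 6,
                          focal_rate = 8, arm_rate = 4, chrom_rate = 2,
                          step_log2 = 0.6, probe_spacing = 1e5, noise_sd = 0.1,
                          marker_spec = default_marker_spec(),
                          pfs_spec = survival_spec(rate = log(2) / 19.6),
                          os_spec = survival_spec(rate = log(2) / 52.9,
                                                  admin_horizon = 84),
                          pfs_beta = c(CD3_tumor_high = log(0.52)),
                          os_beta = c(HLA_E_high = log(0.36)),
                          genome = hg_autosomes(), seed = 1L) {
  stopifnot(n_patients >= 1, hrd_prevalence >= 0, hrd_prevalence <= 1,
            lga_mean_hrd >= 0, lga_mean_hrp >= 0, focal_rate >= 0,
            arm_rate >= 0, chrom_rate >= 0, step_log2 > 0)
  structure(list(n_patients = as.integer(n_patients),
                 hrd_prevalence = hrd_prevalence, lga_mean_hrd = lga_mean_hrd,
                 lga_mean_hrp = lga_mean_hrp, focal_rate = focal_rate,
                 arm_rate = arm_rate, chrom_rate = chrom_rate,
                 step_log2 = step_log2, probe_spacing = probe_spacing,
                 noise_sd = noise_sd, marker_spec = marker_spec,
                 pfs_spec = pfs_spec, os_spec = os_spec,
                 pfs_beta = pfs_beta, os_beta = os_beta,
                 genome = genome, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a full synthetic cohort
#'
#' Draws, per patient: a latent HRD state, a latent LGA count (Poisson by
#' group) and event counts, a noise-free profile realizing them exactly,
#' HRD-conditional markers, and proportional-hazards PFS/OS with
#' administrative plus random censoring. Dichotomized helper columns
#' (`*_high`) are added for semiquantitative markers (cutoff 2) and binary
#' markers before the survival draw so log-hazard vectors can reference
#' them. A capacity-exceeded draw (more events than the genome can host)
#' is redrawn, which at the default rates is vanishingly rare.
#'
#' @param config a [cohort_config()].
#' @param render_probes also render noisy probe series (slower; default
#'   FALSE).
#' @return List with `patients` (data frame), `profiles` (named list of
#'   [cn_profile()]), and `probes` (named list of [cn_probes()] or NULL).
#' @export
simulate_cohort <- function(config = cohort_config(), render_probes = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  true_hrd <- stats::runif(n) < config$hrd_prevalence
  profiles <- vector("list", n)
  true_lga <- integer(n)
  for (i in seq_len(n)) {
    for (attempt in 1:25) {
      lga <- stats::rpois(1L, if (true_hrd[i]) config$lga_mean_hrd else config$lga_mean_hrp)
      nf <- stats::rpois(1L, config$focal_rate)
      na_ <- stats::rpois(1L, config$arm_rate)
      nc <- stats::rpois(1L, config$chrom_rate)
      p <- tryCatch(
        simulate_profile(config$genome, target_lga = lga, n_focal = nf,
                         n_arm = na_, n_chrom = nc,
                         step_log2 = config$step_log2),
        error = function(e) if (grepl("capacity exceeded", conditionMessage(e))) NULL else stop(e)
      )
      if (!is.null(p)) break
    }
    if (is.null(p)) stop("could not place simulated events after 25 attempts")
    attr(p, "sample_id") <- ids[i]
    profiles[[i]] <- p
    true_lga[i] <- lga
  }
  names(profiles) <- ids
  markers <- simulate_markers(true_hrd, config$marker_spec)
  patients <- cbind(data.frame(patient_id = ids, true_hrd = true_hrd,
                               true_lga = true_lga, stringsAsFactors = FALSE),
                    markers)
  for (mk in names(config$marker_spec)) {
    sc <- config$marker_spec[[mk]]$scale
    if (sc == "semiquant") patients[[paste0(mk, "_high")]] <- as.integer(markers[[mk]] >= 2)
    if (sc == "binary") patients[[paste0(mk, "_high")]] <- markers[[mk]]
  }
  lp <- function(beta) {
    v <- rep(0, n)
    for (nm in names(beta)) {
      if (!nm %in% names(patients)) stop("unknown covariate in beta: ", nm)
      v <- v + beta[[nm]] * as.numeric(patients[[nm]])
    }
    v
  }
  pfs <- simulate_survival(lp(config$pfs_beta), config$pfs_spec)
  os <- simulate_survival(lp(config$os_beta), config$os_spec)
  patients$pfs_time <- pfs$time
  patients$pfs_event <- pfs$event
  patients$os_time <- pmax(os$time, pfs$time) # progression precedes death
  patients$os_event <- os$event
  probes <- NULL
  if (render_probes) {
    probes <- lapply(profiles, render_probes,
                     probe_spacing = config$probe_spacing,
                     noise_sd = config$noise_sd)
  }
  list(patients = patients, profiles = profiles, probes = probes)
}
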