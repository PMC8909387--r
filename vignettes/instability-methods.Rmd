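---
title: "Scoring genomic instability and its microenvironment correlates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genomic instability and its microenvironment correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnatme)
```

# The problem

High-grade serous ovarian carcinoma is driven by copy-number change rather
than point mutation. Shallow copy-number profiles (array CGH or low-pass
WGS log ratios) therefore carry most of the usable genomic signal, and a
family of "scar" statistics summarizes it: how many alterations a genome
carries, how they are distributed over chromosomes, and whether their
pattern indicates homologous recombination deficiency (HRD) — the state
that predicts platinum and PARP-inhibitor sensitivity. This package
implements three such readouts on a common segment representation, plus
the immunohistochemistry (IHC) and survival statistics needed to relate
them to the tumor immune microenvironment in a cohort analysis.

# Data model

All coordinates are 0-based half-open base pairs. A `genome_model` is an
ordered list of chromosomes with a length and a single centromere
breakpoint; arms are `p = [0, cen)` and `q = [cen, len)`. We deliberately
collapse real centromeric/heterochromatic gaps to one breakpoint: every
rule downstream needs only "which arm" and "what fraction of the arm", and
a real cytoband file reduces to this representation. Sex chromosomes are
excluded from every score by default (`lga_config(sex_chroms = )`) —
instability scores are conventionally autosome-only, and tumor/reference
sex mismatches otherwise contaminate the log ratios.

A `cn_profile` is one sample's ordered, non-overlapping, chromosome-tiling
segmentation with a per-segment mean log2 ratio and a called status in
{loss, normal, gain}. Status is a pure threshold function of the mean
(defaults ±0.2 log2, a conventional CGH choice; the thresholds are
configurable because no universal value exists). Users with pre-segmented
data enter here via `read_segments()` and never run the segmentation
stage.

# Segmentation

`segment_probes()` is a transparent stand-in for circular binary
segmentation: recursive binary splitting, where each candidate split is
the maximizer of the two-sample pooled-t statistic over all positions
leaving at least `min_probes` on each side, accepted when its permutation
p-value (default 200 permutations) is at most `alpha` (default 0.01).
Segment boundaries fall at probe midpoints and extend to chromosome ends,
so the output tiles the genome and the probe-weighted mean of segment
means equals the overall probe mean exactly.

Two numerical choices matter:

* **Degenerate windows.** On noise-free data the pooled variance at the
  true split is zero with a nonzero mean difference; the statistic is set
  to `Inf` there (and to 0 when the difference is also zero), which makes
  noise-free recovery exact rather than approximately maximal.
* **Deterministic permutation streams.** Each window's permutations are
  seeded from `cfg$seed` and the window's position, and the global RNG
  state is restored afterwards. Consequences: identical inputs give
  identical segmentations, and the accepted-split set can only grow as
  `alpha` grows, so the segment count is monotone in `alpha` — an
  invariant the test suite checks literally.

Baseline normalization is reduced to median centering
(`center_probes()`); the interactive recalibration of a production
pipeline is replaced by `recalibrate_baseline(profile, offset)`, which
shifts all means and re-calls statuses. Wave/GC correction and raw array
intensity processing are out of scope.

# Instability scores

## Genomic Index

`genomic_index()` computes GI = A²/C with A the number of alterations and
C the number of distinct autosomes carrying one. "Alteration" is defined
as a *maximal run* of adjacent same-status altered segments, not a raw
segment count: raw counts reward over-segmentation, and merging adjacent
same-status segments makes GI invariant to re-splitting a segment into
equal-mean pieces (a property the tests enforce). A flat profile scores 0.

## SCNA levels

Alteration events (maximal same-status runs, split at the centromere
before classification) are classified focal when they span less than 50%
of their arm. Among non-focal events, both arms carrying a same-status
event covering at least `arm_coverage_min` (default 0.8) of each arm makes
those events chromosome-level, counted once per chromosome; every other
non-focal event is arm-level. The 0.8 coverage quantile operationalizes
"both arms changed the same way" — a stricter reading (1.0) would be
defeated by any small telomeric gap, a looser one (0.5) would call a
chromosome from two half-arm events. Scores are plain event counts;
magnitude weighting is deliberately not the default because the source
definition counts events.

## One-copy cutoff, smoothing, LGA, HRD

The large-genomic-alteration (LGA) caller follows the shallowHRD recipe:

1. **Cutoff detection.** The per-profile log-ratio step corresponding to
   one copy is estimated as the histogram mode (bin 0.05, modal-bin
   midpoint, ties to the smaller bin) of absolute shifts between adjacent
   large (≥ 10 Mb) segments, restricted to [0.15, 0.9]. Fewer than 5
   eligible shifts falls back to 0.3 — near-flat genomes have no one-copy
   steps to learn from, and 0.3 is a conservative half-copy-ish value.
2. **Smoothing.** Adjacent same-arm pairs of segments ≥ 3 Mb whose shift
   is below the working threshold are merged (length-weighted mean),
   smallest shift first, ties by genomic position, iterated to a fixpoint.
3. **Integration.** Interstitial CNAs shorter than 10 Mb flanked by two
   concordant large segments are absorbed into both; then segments < 3 Mb
   merge into the closer-mean neighbour (ties to the left).
4. **Counting.** An LGA is a junction between two same-arm segments, both
   ≥ 10 Mb, gap ≤ 3 Mb, shift at least the working threshold; junctions at
   the centromere never count. HRD is called at ≥ 18 LGAs (inclusive —
   "set to 18" is read as 18 already qualifying; the boundary is tested).

The *working threshold* is `cutoff * (1 - step_tolerance)` with
`step_tolerance = 0.1`. This slack exists because the mode estimate sits
essentially *at* the one-copy step: with probe noise, half of the true
one-copy shifts land marginally below the estimate, and comparing against
the raw cutoff would merge them away. A 10% relative slack is far smaller
than the gap between "no change" (0) and "one copy" (≈ 0.55–0.6 in log2
for diploid-dominant tumors), so it admits no spurious breaks; it simply
stops the estimator's own centering from eating real ones.

No borderline HRD class is provided (the dichotomy is what the analysis
uses); `undetermined` is reserved for profiles failing upstream QC.
Ploidy and tumor purity are not modeled — a stated limitation of the
CGH-based approach itself.

# The synthetic cohort: what it emulates and what it does not

`simulate_profile()` inverts the scorer's definitions: focal events are
single sub-10 Mb blocks centered in otherwise flat arms (always < 50% of
the arm, and short enough that interstitial filtering removes them before
LGA counting); arm events cover one full arm; chromosome events cover a
whole chromosome at one status; LGA breaks are realized as full-arm
staircases of alternating gain levels (step, 2·step) with every tread
≥ 12 Mb, at most one staircase arm per chromosome. This placement makes
every score exactly predictable: the one unavoidable interaction is that
a staircase arm is itself one arm-level amplification (classification is
exhaustive — any altered run must land somewhere), so the generator
records its exact expected scores in an attribute and the round-trip
tests assert against that bookkeeping. Requesting more events than the
genome can host is an error, never a silent shortfall.

Defaults state the simulated world once: 103 patients; HRD prevalence
0.58 (39 HRD vs 28 HRP among determinable profiles); latent LGA counts
Poisson with means 25 (HRD) and 6 (HRP); 8 focal / 4 arm / 2 chromosome
expected events per genome (a copy-number-driven carcinoma is busy at the
focal level); one-copy step 0.6; probes every 100 kb with Gaussian noise
SD 0.1 (oligonucleotide-array scale). Markers are drawn independently
given the latent HRD state — HLA-E high in 89% of HRD vs 44% of HRP
tumors, the one published conditional; all others default to 50%/50%
because no joint structure is published, and any marker–marker
correlation beyond HRD-conditioning is left to configuration. Survival is
proportional-hazards by inversion (exponential or Weibull baseline), with
administrative censoring at a trial-scale horizon plus exponential random
censoring; default baselines put the reference medians at 19.6 (PFS) and
52.9 (OS) months with protective effects log(0.52) for CD3-high and
log(0.36) for HLA-E-high.

What the generator does *not* emulate: array waves and GC artifacts,
tumor purity and ploidy, marker–marker correlation, informative
censoring, and any real linkage between a patient's genomic events and
marker values beyond the HRD state. A green round-trip test therefore
establishes that the scoring pipeline implements its definitions exactly
and tolerates probe noise — not that it would reproduce any particular
clinical cohort's numbers. The latent HRD label and the called HRD state
can also disagree in the Poisson tails (a latent-HRD patient can draw
fewer than 18 LGAs); this is intentional — the label is generative truth,
the call is the readout.

# Statistical layer

Kaplan–Meier, log-rank and Cox (Efron ties) are delegated to the survival
package; the median is the smallest observed time with S(t) ≤ 0.5 and is
reported as not reached when the curve never gets there.

`maxstat_cutpoint()` maximizes the standardized log-rank statistic over
candidate dichotomizations (midpoints between consecutive distinct
covariate values whose low-group proportion lies in a quantile window,
default 10–90%). The statistic uses Nelson–Aalen log-rank scores with the
permutation variance; the p-value is obtained by permuting the covariate
against the survival records and re-maximizing each permutation — exact
in distribution, with no correction-formula approximation. Ties in the
statistic resolve to the smaller cutoff. Dichotomization cutoffs are
re-estimated per endpoint, so a marker's PFS and OS cutoffs may differ —
that is a property of best-cutoff methodology, and the univariate tables
report the cutoff used.

`lasso_stability_selection()` bootstraps patients, fits an L1-penalized
Cox model per resample with 5-fold cross-validated penalty choice, and
retains variables selected in more than 2/3 of 500 resamples. Two
documented choices:

* **Penalty rule: 1-SE, not CV-optimum.** Under the CV optimum the
  procedure is visibly miscalibrated at cohort scale — in seeded all-noise
  designs (n = 300, 6 covariates, B = 100) a spurious variable cleared
  the 2/3 threshold in 7 of 20 replicates, while the 1-SE rule gives 0 of
  20 with the true log-HR-1.0 covariate still retained at frequency
  above 2/3. The sparser rule is therefore the default; `lambda = "min"`
  remains available.
* **HR summaries are bootstrap percentiles.** Each retained variable's HR
  is the exponentiated median of its coefficients over the resamples
  where it was selected, with a 2.5/97.5 percentile interval. These are
  shrunk toward the null relative to an unpenalized refit — they describe
  the penalized procedure, not a Wald analysis, and are labelled as such.

Cross-tabulations always report both a Pearson chi-square p (continuity
correction off by default, configurable) and a two-sided Fisher exact p
computed by hypergeometric enumeration, with a flag when any expected
count drops below 5 — published analyses alternate between the two tests
without a stated rule, so we show both. Row percentages round half-up to
one decimal. Missing marker values are deleted pairwise per comparison
and the assessable n is part of the output. The Wilcoxon rank-sum
comparison enumerates all group assignments exactly when both groups have
≤ 10 observations (midranks handle ties) and otherwise uses the
tie-corrected normal approximation without continuity correction.

# Worked example

```{r example, eval = FALSE}
co <- simulate_cohort(cohort_config(n_patients = 103, seed = 1))
scores <- score_cohort(co$profiles, hg_autosomes())
table(scores$hrd_call)

patients <- merge(co$patients, scores, by.x = "patient_id", by.y = "sample")
ct <- crosstab(patients$HLA_E_high, as.integer(patients$hrd_call == "HRD"))
rep <- report_tables(patients, c("CD3_tumor_high", "HLA_E_high", "MXA"),
                     B = 500)
```

# Known limitations

* The segmentation stage is a permutation-tested binary splitter, not
  CBS; on pathological profiles (many short segments near the acceptance
  boundary) the two can differ. Pre-segmented input bypasses it.
* Genome coordinates are an approximate autosome model; comparisons to
  any specific build's absolute coordinates are not meaningful.
* Status thresholds, the chromosome-coverage quantile, the smoothing
  bounds and the HRD threshold are conventions made explicit and
  configurable, not universal constants.
* The package does not attempt to reproduce any cohort-specific hazard
  ratios or medians: patient-level data for the motivating study are not
  public, and every empirical number in the documentation is produced by
  the package's own synthetic pipeline.
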