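test_that("Kaplan-Meier estimate matches hand computation", {
  # no events: flat curve, median not reached
  km <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  expect_false(km$median_reached)

  # all events at 1,2,3: S(2) = (2/3)(1/2) = 1/3, median 2
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)

  # mixed censoring, hand-computed product-limit table:
  # times 1(ev) 2(cens) 3(ev) 4(ev) 5(cens)
  # S(1) = 4/5; S(3) = 4/5 * 2/3 = 8/15; S(4) = 8/15 * 1/2 = 4/15
  km <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0))
  ev <- km$surv[km$n_event > 0]
  expect_equal(ev, c(4 / 5, 8 / 15, 4 / 15))
  expect_equal(km$median, 4) # first time with S <= 0.5 (S(3) = 0.53)

  # without censoring the KM curve is the empirical survival function
  set.seed(30)
  t <- rexp(40)
  km <- km_estimate(t, rep(1, 40))
  expect_equal(km$surv, 1 - seq_along(sort(t)) / 40)
})

test_that("log-rank test matches hand computation and separates groups", {
  d <- sim_surv_data(40, hr = 1)
  same <- logrank_test(d$time, d$event, d$time, d$event)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  # {1,2,3} vs {4,5,6}, all events. Hand computation of O-E and V:
  # event times 1..6, group A at risk 3,2,1 then 0; O_A = 3.
  # E_A = 3/6 + 2/5 + 1/4 = 1.15; remaining times contribute 0.
  # V = sum n1 n2 d (n-d) / (n^2 (n-1)) = (3*3/36)+(2*3/25)+(1*3/16)
  o_e <- 3 - (3 / 6 + 2 / 5 + 1 / 4)
  v <- 3 * 3 * 1 * 5 / (36 * 5) + 2 * 3 * 1 * 4 / (25 * 4) + 1 * 3 * 1 * 3 / (16 * 3)
  lr <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(4, 5, 6), c(1, 1, 1))
  expect_equal(lr$statistic, o_e^2 / v, tolerance = 1e-9)

  # clearly separated large groups
  set.seed(31)
  a <- rexp(150, 0.2); b <- rexp(150, 0.02)
  lr <- logrank_test(a, rep(1, 150), b, rep(1, 150))
  expect_lt(lr$p, 1e-4)

  expect_error(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "no events")

  # invariance to a common time rescaling
  lr1 <- logrank_test(a, rep(1, 150), b, rep(1, 150))
  lr2 <- logrank_test(a * 7, rep(1, 150), b * 7, rep(1, 150))
  expect_equal(lr1$statistic, lr2$statistic)
})

test_that("univariate Cox recovers effects and rejects degenerate input", {
  set.seed(32)
  x <- rep(0:1, 1000)
  sp <- survival_spec(rate = 0.04, admin_horizon = 60, censor_rate = 0.005)
  d <- simulate_survival(log(0.52) * x, sp)
  fit <- cox_univariate(d$time, d$event, x)
  expect_gt(fit$hr, 0.45)
  expect_lt(fit$hr, 0.60)
  expect_lt(fit$p, 0.001)
  expect_true(fit$ci[1] < fit$hr && fit$hr < fit$ci[2])

  expect_error(cox_univariate(d$time, d$event, rep(1, 2000)), "constant")

  # null coverage: the 95% CI covers HR = 1 in roughly 95% of replicates
  set.seed(33)
  cover <- mean(replicate(200, {
    x <- rbinom(80, 1, 0.5)
    d <- simulate_survival(rep(0, 80), sp)
    f <- tryCatch(cox_univariate(d$time, d$event, x), error = function(e) NULL)
    !is.null(f) && f$ci[1] <= 1 && 1 <= f$ci[2]
  }))
  expect_gt(cover, 0.90)
})

test_that("maxstat cutpoint equals the exhaustive-scan oracle", {
  # two distinct values -> the single midpoint is returned
  set.seed(34)
  d <- sim_surv_data(30)
  v2 <- rep(c(1, 5), 15)
  ms <- maxstat_cutpoint(v2, d$time, d$event, n_perm = 20)
  expect_equal(ms$best_cutoff, 3)
  expect_equal(ms$n_candidates, 1L)

  # perfectly ordered toy data: brute force agrees
  tm <- 1:10; ev <- rep(1, 10); vv <- 1:10
  ms <- maxstat_cutpoint(vv, tm, ev, n_perm = 20)
  or <- oracle_maxstat_cut(vv, tm, ev)
  expect_equal(ms$best_cutoff, or$best_cutoff)
  expect_equal(ms$max_statistic, or$max_statistic, tolerance = 1e-9)

  # randomized instances, n <= 50
  set.seed(35)
  for (r in 1:60) {
    n <- sample(15:50, 1)
    d <- sim_surv_data(n, hr = sample(c(0.4, 1, 2.5), 1))
    # half-unit grid keeps candidate midpoints exactly representable
    vals <- sample(seq(-4, 4, by = 0.5), n, replace = TRUE) + d$group
    if (length(unique(vals)) < 3) next
    ms <- maxstat_cutpoint(vals, d$time, d$event, n_perm = 5)
    or <- oracle_maxstat_cut(vals, d$time, d$event)
    expect_equal(ms$best_cutoff, or$best_cutoff)
    expect_equal(ms$max_statistic, or$max_statistic, tolerance = 1e-9)
  }

  expect_error(maxstat_cutpoint(rep(2, length(d$time)), d$time, d$event),
               "constant")
})

test_that("maxstat permutation p is small under strong association", {
  set.seed(36)
  n <- 80
  v <- rnorm(n)
  t_ev <- rexp(n, 0.05 * exp(1.5 * (v > 0)))
  ms <- maxstat_cutpoint(v, pmin(t_ev, 50), t_ev <= 50, n_perm = 199)
  expect_lt(ms$permutation_p, 0.02)
})

test_that("stability selection validates input and respects thresholds", {
  set.seed(37)
  n <- 120
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("v", 1:4)))
  d <- simulate_survival(1.2 * x[, 1],
                         survival_spec(rate = 0.05, admin_horizon = 40))
  expect_error(lasso_stability_selection(d$time, d$event, x, B = 0), "at least 1")
  expect_error(lasso_stability_selection(d$time[1:10], d$event[1:10],
                                         x[1:10, ], B = 5), "at least 20")

  sel <- lasso_stability_selection(d$time, d$event, x, B = 40, seed = 5)
  expect_true(all(sel$frequency >= 0 & sel$frequency <= 1))
  expect_true("v1" %in% sel$retained)
  expect_gt(sel$frequency[["v1"]], 2 / 3)
  # lasso coefficients are shrunk, so the bootstrap-median HR sits between
  # the null and the generating value exp(1.2)
  expect_lt(sel$hr$hr[sel$hr$variable == "v1"], exp(1.4))
  expect_gt(sel$hr$hr[sel$hr$variable == "v1"], 1.3)

  # determinism under a fixed seed
  sel2 <- lasso_stability_selection(d$time, d$event, x, B = 40, seed = 5)
  expect_identical(sel$frequency, sel2$frequency)

  # raising the threshold can only shrink the retained set
  strict <- lasso_stability_selection(d$time, d$event, x, B = 40, seed = 5,
                                      threshold = 0.95)
  expect_true(all(strict$retained %in% sel$retained))
})

test_that("report_tables emits the forest-table shape", {
  set.seed(38)
  co <- simulate_cohort(cohort_config(
    n_patients = 90L, genome = toy_genome(), lga_mean_hrd = 5, lga_mean_hrp = 1,
    focal_rate = 0, arm_rate = 0, chrom_rate = 0,
    pfs_beta = c(CD3_tumor_high = log(0.4)), seed = 39L))
  vars <- c("CD3_tumor_high", "HLA_E_high", "MXA")
  rep <- report_tables(co$patients, vars, endpoints = c("pfs", "os"),
                       B = 25L, n_perm = 30L, seed = 40L)
  expect_equal(nrow(rep$univariate), length(vars) * 2L)
  expect_equal(rep$univariate$comparison, rep("High vs Low", 6))
  expect_true(all(!is.na(rep$univariate$cutoff[rep$univariate$variable == "MXA"])))
  expect_true(all(is.na(rep$univariate$cutoff[rep$univariate$variable == "CD3_tumor_high"])))
  expect_true(all(c("variable", "endpoint", "selection_frequency", "hr",
                    "ci_lower", "ci_upper") %in% names(rep$multivariate)))
  expect_error(report_tables(co$patients, "nope"), "absent")
})
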