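# Block confidence intervals, deviation detection, trial-level MDS.

const_series <- function(value = 0.4, participant = "P01",
                         type = "holographic") {
  data.frame(participant = participant, obstacle_type = type, trial = 1:30,
             phase = exp2_phase(1:30),
             lead_cross = value, trail_cross = value,
             lead_clear = value - 0.3, trail_clear = value - 0.3,
             lead_step = value, trail_step = value)
}

test_that("constant series give degenerate identical intervals", {
  ci <- block_confidence_intervals(const_series(0.4), "trail_cross")
  expect_equal(nrow(ci), 4)
  expect_true(all(ci$mean == 0.4))
  expect_true(all(ci$lower == 0.4))
  expect_true(all(ci$upper == 0.4))
  fd <- first_deviating_block(const_series(0.4), "trail_cross")
  expect_true(is.na(fd$first_block))
  expect_false(any(fd$windows$deviates))
})

test_that("intervals match the t formula", {
  s <- const_series()
  vals <- c(0.12, 0.08, 0.15, 0.10, 0.09)
  s$trail_cross[3:7] <- vals
  ci <- block_confidence_intervals(s, "trail_cross")
  base <- ci[ci$block == "baseline", ]
  half <- qt(0.975, 4) * sd(vals) / sqrt(5)
  expect_equal(base$mean, mean(vals), tolerance = 1e-12)
  expect_equal(base$lower, mean(vals) - half, tolerance = 1e-12)
  expect_equal(base$upper, mean(vals) + half, tolerance = 1e-12)
  # independent cross-check against t.test's interval
  tt <- t.test(vals)
  expect_equal(c(base$lower, base$upper), as.numeric(tt$conf.int),
               tolerance = 1e-12)
})

test_that("separated blocks are flagged as deviating", {
  set.seed(5)
  s <- const_series()
  s$trail_cross[3:7] <- rnorm(5, 0.05, 0.03)
  s$trail_cross[26:30] <- rnorm(5, 0.45, 0.03)
  ci <- block_confidence_intervals(s, "trail_cross")
  base <- ci[ci$block == "baseline", ]
  fu <- ci[ci$block == "followup", ]
  expect_true(fu$lower > base$upper)  # disjoint
})

test_that("a large step change at trial 8 is caught in the first block", {
  set.seed(6)
  s <- const_series()
  s$trail_cross[1:7] <- rnorm(7, 0.05, 0.02)
  s$trail_cross[8:30] <- rnorm(23, 0.45, 0.02)
  fd <- first_deviating_block(s, "trail_cross")
  expect_equal(fd$first_block, 1L)
})

test_that("a calibrated gradual change is caught at the predicted window", {
  # deterministic series: baseline at 0.6, feedback decays linearly;
  # predict the first deviating window with t.test intervals directly
  s <- const_series()
  s$lead_cross[1:7] <- c(0.6, 0.6, 0.61, 0.59, 0.60, 0.605, 0.595)
  s$lead_cross[8:25] <- 0.6 - 0.004 * (1:18)
  s$lead_cross[26:30] <- 0.52
  base_int <- t.test(s$lead_cross[3:7])$conf.int
  expected <- NA_integer_
  for (k in 1:14) {
    w <- s$lead_cross[(7 + k):(11 + k)]
    wi <- t.test(w)$conf.int
    if (wi[2] < base_int[1] || wi[1] > base_int[2]) { expected <- k; break }
  }
  expect_false(is.na(expected))
  expect_gt(expected, 1)
  fd <- first_deviating_block(s, "lead_cross")
  expect_equal(fd$first_block, expected)
})

test_that("simulated no_trail_raise feedback series deviate from block one", {
  prof <- behavior_profile("no_trail_raise",
                           adaptation = list(onset_trial = 8, time_constant = 2,
                                             retention_fraction = 1))
  s <- simulate_exp2_outcomes(prof, seed = 11)
  fd <- first_deviating_block(s, "trail_cross")
  expect_equal(fd$first_block, 1L)
  rep <- feedback_report(
    simulate_exp2_outcomes(prof, obstacle_spec("real", 0.3, 0.02), seed = 12),
    s, "trail_cross")
  expect_true(rep$baseline_vs_real)       # unraised trail vs real crossing
  expect_true(rep$feedback_vs_baseline)   # feedback block deviates
  expect_true(rep$followup_vs_baseline)   # retained at follow-up
})

test_that("trial MDS builds 56 objects and tracks adaptation distances", {
  prof <- behavior_profile("no_trail_raise",
                           adaptation = list(onset_trial = 8, time_constant = 2,
                                             retention_fraction = 1))
  holo <- simulate_exp2_outcomes(prof, seed = 21, participant = "P01")
  real <- simulate_exp2_outcomes(prof, obstacle_spec("real", 0.3, 0.02),
                                 seed = 22, participant = "P01")
  res <- trial_mds_distances(list(real, holo))
  expect_equal(nrow(res$objects), 56)
  expect_equal(nrow(res$embedding$points), 56)
  expect_equal(nrow(res$dist_to_real), 28)
  d <- res$dist_to_real
  # adapted trials sit closer to the real average than baseline trials
  expect_lt(max(d$distance[d$trial >= 8]), min(d$distance[d$trial <= 7]))

  # identical series: distances to the real average are uniformly small
  same <- simulate_exp2_outcomes(behavior_profile("similar"), seed = 31)
  same_real <- same; same_real$obstacle_type <- "real"
  res2 <- trial_mds_distances(list(same_real, same))
  expect_lt(max(res2$dist_to_real$distance),
            2 * mean(res2$dist_to_real$distance) + 0.1)
})

test_that("interval deviation is symmetric and shift invariant", {
  set.seed(8)
  for (rep in 1:10) {
    a <- list(lower = runif(1), upper = NA); a$upper <- a$lower + runif(1)
    b <- list(lower = runif(1), upper = NA); b$upper <- b$lower + runif(1)
    d1 <- holosteps:::ci_disjoint(a, b)
    d2 <- holosteps:::ci_disjoint(b, a)
    expect_identical(d1, d2)
    shift <- function(ci, c) list(lower = ci$lower + c, upper = ci$upper + c)
    expect_identical(holosteps:::ci_disjoint(shift(a, 3.2), shift(b, 3.2)), d1)
  }
})

test_that("undefined intervals are marked, not fabricated", {
  s <- const_series()
  s$trail_cross[3:7] <- NA
  s$trail_cross[3] <- 0.1
  ci <- block_confidence_intervals(s, "trail_cross")
  base <- ci[ci$block == "baseline", ]
  expect_equal(base$n, 1)
  expect_true(is.na(base$lower))
  expect_error(first_deviating_block(s, "trail_cross"), "undefined")
})
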