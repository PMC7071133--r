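# Outcome measures: step height, crossing height, clearance, velocity,
# summaries.

test_that("max step height is the windowed peak of per-frame minima", {
  s <- edges_series(list(pt_frame(0.5, 0.0), pt_frame(0.9, 0.2),
                         pt_frame(1.2, 0.4), pt_frame(1.7, 0.1)))
  expect_equal(max_step_height(s), 0.4)
  s2 <- edges_series(list(pt_frame(0.5, 0.0), pt_frame(0.7, 0.5),
                          pt_frame(0.9, 0.2), pt_frame(1.2, 0.4),
                          pt_frame(1.7, 0.1)))
  expect_equal(max_step_height(s2), 0.4)  # 0.5 at x = 0.7 outside window
  s3 <- edges_series(list(pt_frame(0.5, 0.0)))
  expect_true(is.na(max_step_height(s3)))
  expect_equal(outcome_reason(max_step_height(s3)), "no_frame_in_window")
})

test_that("the windowed frame test uses the argmin point", {
  # frame minimum at x = 0.7 (outside window) even though other edge
  # samples are inside the window: frame must not qualify
  e <- data.frame(x = c(0.7, 1.0), z = c(0.1, 0.3))
  s <- edges_series(list(e))
  expect_true(is.na(max_step_height(s)))
})

test_that("crossing height of a constant-height sweep is that height", {
  frames <- lapply(seq(0.6, 1.8, by = 0.05), function(cx)
    data.frame(x = cx + seq(-0.125, 0.125, by = 0.01), z = 0.35))
  expect_equal(crossing_height(edges_series(frames), 1.2), 0.35)
})

test_that("bracketing interpolation is linear in x", {
  s <- edges_series(list(pt_frame(1.1, 0.30), pt_frame(1.3, 0.40)))
  expect_equal(crossing_height(s, 1.2), 0.35)
  # never brackets: distinct no-crossing marker
  s2 <- edges_series(list(pt_frame(0.9, 0.3), pt_frame(1.0, 0.3)))
  expect_equal(outcome_reason(crossing_height(s2, 1.2)), "no_crossing")
  expect_equal(outcome_reason(crossing_height(edges_series(list(NULL, NULL)),
                                              1.2)), "missing_data")
})

test_that("a pitched sole crosses at the heel value", {
  # rigid sole, heel 0.05 m below toe, swept at constant height
  sole <- function(cx) data.frame(x = cx + seq(-0.125, 0.125, by = 0.005),
                                  z = 0.30 + (seq(-0.125, 0.125, by = 0.005) +
                                                0.125) * 0.2)
  frames <- lapply(seq(0.6, 1.8, by = 0.04), sole)
  ch <- crossing_height(edges_series(frames), 1.2)
  expect_equal(ch, 0.30, tolerance = 1e-9)
  toe_value <- 0.30 + 0.25 * 0.2
  expect_lt(ch, toe_value)
})

test_that("clearance subtracts obstacle height and flags virtual collisions", {
  holo3 <- obstacle_spec("holographic", 0.3, 0.02)
  expect_equal(foot_clearance(0.35, holo3), list(clearance = 0.05, collision = FALSE))
  expect_equal(foot_clearance(0.25, holo3), list(clearance = -0.05, collision = TRUE))
  flat <- obstacle_spec("holographic", 0.0, 0.02)
  expect_equal(foot_clearance(0.25, flat), list(clearance = 0.25, collision = FALSE))
  # real obstacles: collision comes from the bar-fell record, not the sign
  real3 <- obstacle_spec("real", 0.3, 0.02)
  expect_false(foot_clearance(0.25, real3, bar_fell = FALSE)$collision)
  expect_true(foot_clearance(0.35, real3, bar_fell = TRUE)$collision)
})

test_that("forward velocity uses interpolated span crossings", {
  t <- seq(0, 3, by = 1 / 30)
  expect_equal(forward_velocity(data.frame(time = t, x = t)), 1.0)
  expect_equal(forward_velocity(data.frame(time = t, x = 0.85 * t)), 0.85,
               tolerance = 1e-9)
  tr <- data.frame(time = t, x = pmin(0.85 * t, 1.5))
  expect_true(is.na(forward_velocity(tr)))
  expect_equal(outcome_reason(forward_velocity(tr)), "truncated")
})

test_that("adding a constant to edge heights shifts both outcomes exactly", {
  set.seed(31)
  for (rep in 1:5) {
    frames <- lapply(seq(0.6, 1.8, by = 0.05), function(cx) {
      x <- cx + seq(-0.12, 0.12, by = 0.01)
      data.frame(x = x, z = 0.2 + 0.1 * sin(6 * cx) + 0.05 * runif(length(x)))
    })
    s <- edges_series(frames)
    c0 <- crossing_height(s, 1.2)
    m0 <- max_step_height(s)
    shift <- lapply(frames, function(e) { e$z <- e$z + 0.123; e })
    s2 <- edges_series(shift)
    expect_equal(crossing_height(s2, 1.2), c0 + 0.123, tolerance = 1e-12)
    expect_equal(max_step_height(s2), m0 + 0.123, tolerance = 1e-12)
  }
})

test_that("noiseless simulated trials recover all planted outcomes", {
  for (seed in c(2, 13)) {
    spec <- obstacle_spec("holographic", 0.4, 0.30)
    b <- simulate_trial(spec, behavior_profile("similar"), noise = noise_off,
                        seed = seed)
    o <- trial_outcomes(b)
    gt <- b$ground_truth
    expect_equal(o$lead_cross_h1, gt$lead$crossing_height[1], tolerance = 1e-3)
    expect_equal(o$lead_cross_h2, gt$lead$crossing_height[2], tolerance = 1e-3)
    expect_equal(o$trail_cross_h1, gt$trail$crossing_height[1], tolerance = 1e-3)
    expect_equal(o$lead_step, gt$lead$max_step_height, tolerance = 1e-3)
    expect_equal(o$trail_step, gt$trail$max_step_height, tolerance = 1e-3)
    expect_equal(o$velocity, gt$velocity, tolerance = 1e-3)
    # clearance/collision identity on outputs
    expect_equal(o$lead_clear_h1, o$lead_cross_h1 - spec$height)
    expect_identical(o$trail_coll_h1, o$trail_clear_h1 < 0)
  }
})

test_that("lead role goes to the foot crossing hurdle 1 first", {
  b <- quiet_trial(seed = 21)
  o <- trial_outcomes(b)
  # the planted lead foot has the larger planted crossing height here;
  # check role assignment against the generator's truth
  expect_equal(o$lead_cross_h1, b$ground_truth$lead$crossing_height[1],
               tolerance = 1e-3)
  expect_equal(o$trail_cross_h1, b$ground_truth$trail$crossing_height[1],
               tolerance = 1e-3)
})

test_that("condition summaries use the median of repetitions 2-6 only", {
  base <- data.frame(participant = "P01", obstacle_type = "holographic",
                     height = 0.2, depth = 0.02, repetition = 1:6,
                     lead_step = c(9.9, 0.1, 0.2, 0.3, 0.4, 0.5),
                     excluded = FALSE)
  sm <- summarize_trials(base, measures = "lead_step")
  expect_equal(sm$median, 0.3)
  expect_equal(sm$n_used, 5)

  base$lead_step[c(3, 5)] <- NA  # two of five analysed reps missing
  sm2 <- summarize_trials(base, measures = "lead_step")
  expect_equal(sm2$median, median(c(0.1, 0.3, 0.5)))
  expect_equal(sm2$n_used, 3)

  base$lead_step[2:6] <- NA
  sm3 <- summarize_trials(base, measures = "lead_step")
  expect_true(is.na(sm3$median))
  expect_equal(sm3$n_used, 0)
})

test_that("design bookkeeping yields 600 hurdle-1 and 300 hurdle-2 analysed trials", {
  d <- design_cohort(12, seed = 3)
  tr <- d$trials
  holo_analysed <- tr[tr$obstacle_type == "holographic" & tr$repetition >= 2, ]
  expect_equal(nrow(holo_analysed), 600)
  expect_equal(sum(holo_analysed$depth >= 0.1), 300)
  rates <- collision_rates(c(lead_h1 = 39, lead_h2 = 32, trail_h2 = 84),
                           d, hurdle = c(1, 2, 2))
  expect_equal(rates$denominator, c(600, 300, 300))
})
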