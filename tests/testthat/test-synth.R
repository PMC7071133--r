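# Cohort design and trial generator.

test_that("obstacle specs place hurdles by depth", {
  expect_equal(obstacle_spec("real", 0.2, 0.02)$hurdles, 1.2)
  expect_equal(obstacle_spec("holographic", 0.4, 0.30)$hurdles, c(1.2, 1.5))
})

test_that("cohort design produces the full counterbalanced factorial grid", {
  d <- design_cohort(12, seed = 1)
  expect_equal(nrow(d$trials), 1440)  # 12 x 2 types x 10 conditions x 6 reps
  expect_equal(as.vector(table(d$participants$first_type)), c(6L, 6L))

  d1 <- design_cohort(1, mode_assignment = c(P01 = "similar"), seed = 7)
  expect_equal(nrow(d1$trials), 120)
  counts <- table(d1$trials$height, d1$trials$obstacle_type)
  expect_true(all(counts == 12))  # each height 12x per obstacle type

  # each repetition round holds every height x depth condition exactly once
  one_block <- d$trials[d$trials$participant == "P03" &
                          d$trials$obstacle_type == "real" &
                          d$trials$repetition == 4, ]
  expect_equal(nrow(unique(one_block[, c("height", "depth")])), 10)
})

test_that("cohort design is deterministic for a fixed seed", {
  expect_identical(design_cohort(5, seed = 11), design_cohort(5, seed = 11))
  expect_false(identical(design_cohort(5, seed = 11)$trials$trial_seed,
                         design_cohort(5, seed = 12)$trials$trial_seed))
})

test_that("unknown behaviour modes are rejected", {
  expect_error(design_cohort(2, mode_assignment = c(P01 = "similar",
                                                    P02 = "hovering")),
               "unknown behaviour mode")
  expect_error(design_cohort(2, mode_assignment = c(P01 = "similar")),
               "no behaviour mode")
  expect_error(behavior_profile("nope"), "unknown behaviour mode")
})

test_that("headset viewing distance follows the right-triangle geometry", {
  expect_equal(headset_view_distance(1.75, 0.2, 1.2),
               sqrt(1.2^2 + 1.55^2))
  expect_lt(abs(headset_view_distance(1.75, 0.2, 1.2) - 2.0), 0.05)
  expect_equal(headset_view_distance(1.3, 1.3, 0.7), 0.7)
  expect_equal(headset_view_distance(2.0, 0.0, 0.0), 2.0)
})

test_that("planted crossing heights are obstacle height plus clearance", {
  spec <- obstacle_spec("holographic", 0.3, 0.02)
  b <- simulate_trial(spec, behavior_profile("similar"), noise = noise_off,
                      seed = 3, planted = list(lead_cross = 0.40))
  expect_equal(b$ground_truth$lead$crossing_height, 0.40)
  expect_equal(b$ground_truth$lead$clearance, 0.10)
  expect_false(b$ground_truth$lead$collision)
})

test_that("no_trail_raise trails collide with 3D holographic obstacles", {
  b <- simulate_trial(obstacle_spec("holographic", 0.1, 0.02),
                      behavior_profile("no_trail_raise"),
                      noise = noise_off, seed = 2)
  expect_lt(b$ground_truth$trail$clearance, 0)
  expect_true(b$ground_truth$trail$collision)
})

test_that("ground-truth collision flags equal negative planted clearance exactly", {
  for (seed in 1:20) {
    mode <- c("similar", "extreme_lead", "no_trail_raise")[seed %% 3 + 1]
    h <- c(0, 0.1, 0.2, 0.3, 0.4)[seed %% 5 + 1]
    b <- simulate_trial(obstacle_spec("holographic", h, 0.30),
                        behavior_profile(mode), noise = noise_off, seed = seed)
    for (role in c("lead", "trail"))
      expect_identical(b$ground_truth[[role]]$collision,
                       b$ground_truth[[role]]$clearance < 0)
  }
})

test_that("bundles are bit-identical for a fixed seed and distinct across seeds", {
  args <- list(obstacle_spec("real", 0.2, 0.30), behavior_profile("similar"),
               noise = noise_default)
  b1 <- do.call(simulate_trial, c(args, seed = 9))
  b2 <- do.call(simulate_trial, c(args, seed = 9))
  expect_identical(b1, b2)
  b3 <- do.call(simulate_trial, c(args, seed = 10))
  expect_false(identical(b1$clouds, b3$clouds))
})

test_that("trial geometry invariants hold", {
  b <- quiet_trial(seed = 4)
  sp <- b$skeleton[b$skeleton$point == "SpineShoulder", ]
  expect_true(all(diff(sp$x) > 0))            # monotone advance
  expect_lt(sp$x[1], 0.1)
  expect_gt(sp$x[nrow(sp)], 1.8)
  expect_true(all(diff(b$times) > 0))
  expect_equal(unique(round(diff(b$times), 10)), 1 / 30)
  expect_gte(min(b$clouds$z), -1e-9)          # floor is z = 0
})

test_that("feedback schedules implement the planted adaptation dynamics", {
  spec <- obstacle_spec("holographic", 0.3, 0.02)

  prof <- behavior_profile("no_trail_raise",
                           adaptation = list(onset_trial = 8, time_constant = 4,
                                             retention_fraction = 1.0))
  s <- plant_exp2_schedule(spec, prof, seed = 5)
  expect_true(all(s$trail_cross[1:7] < 0.1))
  expect_true(all(s$trail_cross[8:30] > 0.3))

  # infinite time constant: no adaptation at all for extreme lead profiles
  prof_inf <- behavior_profile("extreme_lead",
                               adaptation = list(onset_trial = 8,
                                                 time_constant = Inf,
                                                 retention_fraction = 1.0))
  s_inf <- plant_exp2_schedule(spec, prof_inf, seed = 5)
  raw <- vapply(s_inf$trial_seed, function(sd)
    plant_trial_params(spec, prof_inf, sd)$lead_cross, numeric(1))
  expect_equal(s_inf$lead_cross, raw)

  # similar profiles are stationary by construction
  s_sim <- plant_exp2_schedule(spec, behavior_profile("similar"), seed = 5)
  raw_sim <- vapply(s_sim$trial_seed, function(sd)
    plant_trial_params(spec, behavior_profile("similar"), sd)$lead_cross,
    numeric(1))
  expect_equal(s_sim$lead_cross, raw_sim)
  expect_equal(s_sim$trail_cross[1:7],
               vapply(s_sim$trial_seed[1:7], function(sd)
                 plant_trial_params(spec, behavior_profile("similar"),
                                    sd)$trail_cross, numeric(1)))

  expect_error(plant_exp2_schedule(spec, behavior_profile(
    "no_trail_raise", adaptation = list(onset_trial = 31, time_constant = 4,
                                        retention_fraction = 1))),
    "onset_trial")
})

test_that("exp2 bundles follow the schedule and carry phases", {
  prof <- behavior_profile("no_trail_raise")
  series <- simulate_exp2_series(prof, seed = 3, noise = noise_off)
  expect_length(series, 30)
  sched <- attr(series, "schedule")
  expect_equal(sched$phase, exp2_phase(1:30))
  expect_equal(exp2_phase(c(1, 2, 3, 7, 8, 25, 26, 30)),
               c("familiarization", "familiarization", "baseline", "baseline",
                 "feedback", "feedback", "followup", "followup"))
  got <- vapply(series, function(b) b$ground_truth$trail$crossing_height[1],
                numeric(1))
  expect_equal(got, sched$trail_cross)
})
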