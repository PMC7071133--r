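# Outcome-level synthesis: planted per-trial parameters plus a small
# measurement error emulating the sensing-and-kinematics chain. Cohort-scale
# analyses (feature vectors, MDS, subgroup flags, ANOVA) run on this
# generator; the sensor-level generator is exercised per trial where the
# point-cloud pipeline itself is under test. Both share plant_trial_params(),
# so planted values agree for the same trial seed.

#' Simulate trial-level outcomes for a whole cohort
#'
#' Produces the per-trial outcome table the kinematics stage would deliver
#' when run over every recorded trial of a cohort: maximum step heights,
#' per-hurdle crossing heights, clearances and collision flags for the lead
#' and trail foot, and forward velocity. Values are the planted per-trial
#' parameters of [plant_trial_params()] plus independent Gaussian measurement
#' error of standard deviation `meas_sd`; clearances are derived from the
#' measured crossing heights so the clearance/collision identity holds
#' exactly. Real-obstacle collisions are taken from the planted bar-fall
#' flag, not from the sign of the measured clearance.
#'
#' @param design a [design_cohort()] object.
#' @param meas_sd measurement error on heights (m) and velocity (m/s).
#' @param profiles optional named list of [behavior_profile()]s per
#'   participant; defaults to profiles built from the design's modes.
#' @return data.frame, one row per trial, with condition columns and outcome
#'   columns `lead_step`, `trail_step`, `lead_cross_h1` ... `trail_coll_h2`,
#'   `velocity`, `excluded`, `exclude_reason`.
#' @examples
#' d <- design_cohort(2, seed = 1)
#' out <- simulate_cohort_outcomes(d)
#' nrow(out)  # 240
#' @export
simulate_cohort_outcomes <- function(design, meas_sd = 0.003, profiles = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(profiles)) {
    profiles <- lapply(stats::setNames(design$participants$mode,
                                       design$participants$participant),
                       behavior_profile)
  }
  tr <- design$trials
  n <- nrow(tr)
  m <- matrix(NA_real_, n, 9,
              dimnames = list(NULL, c("lead_step", "trail_step",
                                      "lead_cross_h1", "trail_cross_h1",
                                      "lead_cross_h2", "trail_cross_h2",
                                      "velocity", "planted_lead_clear",
                                      "planted_trail_clear")))
  holo <- tr$obstacle_type == "holographic"
  two <- tr$depth >= 0.1
  for (i in seq_len(n)) {
    spec <- obstacle_spec(tr$obstacle_type[i], tr$height[i], tr$depth[i])
    par <- plant_trial_params(spec, profiles[[tr$participant[i]]],
                              tr$trial_seed[i])
    e <- with_seed(child_seed(tr$trial_seed[i], 2L),
                   stats::rnorm(7, 0, meas_sd))
    m[i, ] <- c(par$lead_cross + e[5], par$trail_cross + e[6],
                par$lead_cross + e[1], par$trail_cross + e[2],
                if (two[i]) par$lead_cross + e[3] else NA_real_,
                if (two[i]) par$trail_cross + e[4] else NA_real_,
                par$velocity + e[7],
                par$lead_clearance, par$trail_clearance)
  }
  h <- tr$height
  coll <- function(measured_clear, planted_clear)
    ifelse(holo, measured_clear < 0, planted_clear < 0)
  out <- data.frame(
    tr[, c("participant", "obstacle_type", "height", "depth",
           "block", "repetition")],
    lead_step = m[, "lead_step"], trail_step = m[, "trail_step"],
    lead_cross_h1 = m[, "lead_cross_h1"], trail_cross_h1 = m[, "trail_cross_h1"],
    lead_clear_h1 = m[, "lead_cross_h1"] - h,
    trail_clear_h1 = m[, "trail_cross_h1"] - h,
    lead_coll_h1 = coll(m[, "lead_cross_h1"] - h, m[, "planted_lead_clear"]),
    trail_coll_h1 = coll(m[, "trail_cross_h1"] - h, m[, "planted_trail_clear"]),
    lead_cross_h2 = m[, "lead_cross_h2"], trail_cross_h2 = m[, "trail_cross_h2"],
    lead_clear_h2 = m[, "lead_cross_h2"] - h,
    trail_clear_h2 = m[, "trail_cross_h2"] - h,
    lead_coll_h2 = ifelse(two, coll(m[, "lead_cross_h2"] - h,
                                    m[, "planted_lead_clear"]), NA),
    trail_coll_h2 = ifelse(two, coll(m[, "trail_cross_h2"] - h,
                                     m[, "planted_trail_clear"]), NA),
    velocity = m[, "velocity"], excluded = FALSE,
    exclude_reason = NA_character_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate measured outcomes for a 30-trial feedback series
#'
#' Outcome-level counterpart of [simulate_exp2_series()]: the planted
#' schedule of [plant_exp2_schedule()] plus measurement error, in the long
#' per-trial format consumed by the feedback-analysis functions.
#'
#' @inheritParams plant_exp2_schedule
#' @param meas_sd measurement error on heights (m).
#' @param participant participant id recorded in the output.
#' @return data.frame with columns `participant`, `obstacle_type`, `trial`,
#'   `phase`, `lead_cross`, `trail_cross`, `lead_clear`, `trail_clear`,
#'   `lead_step`, `trail_step`, `lead_coll`, `trail_coll`.
#' @export
simulate_exp2_outcomes <- function(profile,
                                   spec = obstacle_spec("holographic", 0.3, 0.02),
                                   seed = 1, meas_sd = 0.01,
                                   participant = "P01") {
  sched <- plant_exp2_schedule(spec, profile, seed)
  n <- nrow(sched)
  with_seed(child_seed(seed, 999L), {
    lead_cross <- sched$lead_cross + stats::rnorm(n, 0, meas_sd)
    trail_cross <- sched$trail_cross + stats::rnorm(n, 0, meas_sd)
    lead_step <- sched$lead_cross + stats::rnorm(n, 0, meas_sd)
    trail_step <- sched$trail_cross + stats::rnorm(n, 0, meas_sd)
    holo <- spec$obstacle_type == "holographic"
    data.frame(participant = participant,
               obstacle_type = spec$obstacle_type,
               trial = sched$trial, phase = sched$phase,
               lead_cross = lead_cross, trail_cross = trail_cross,
               lead_clear = lead_cross - spec$height,
               trail_clear = trail_cross - spec$height,
               lead_step = lead_step, trail_step = trail_step,
               lead_coll = if (holo) lead_cross - spec$height < 0
                           else sched$lead_clearance < 0,
               trail_coll = if (holo) trail_cross - spec$height < 0
                            else sched$trail_clearance < 0,
               stringsAsFactors = FALSE)
  })
}
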