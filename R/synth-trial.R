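# Synthetic trial generation.
#
# The swing trajectory is a raised-cosine ramp up to a flat plateau whose
# height equals the planted crossing height, the plateau spanning every
# hurdle position by at least half a sole length. Because the sole is rigid
# and (optionally) pitched toe-up, the heel is the lowest sole point and
# every sole part passes each hurdle while the foot centre is on the
# plateau, so the planted crossing height, maximum step height and forward
# velocity are exact by construction rather than by simulation accident.

KINECT_POINTS <- c(
  "SpineBase", "SpineMid", "Neck", "Head",
  "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
  "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
  "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
  "HipRight", "KneeRight", "AnkleRight", "FootRight",
  "SpineShoulder", "HandTipLeft", "ThumbLeft", "HandTipRight", "ThumbRight")

#' Plant the per-trial crossing parameters for a behaviour profile
#'
#' Draws the planted lead/trail crossing heights, walking speed, lead side
#' and sole pitch for one trial. Both the sensor-level simulator
#' ([simulate_trial()]) and the outcome-level cohort generator
#' ([simulate_cohort_outcomes()]) use this function, so planted values agree
#' between the two paths for the same trial seed.
#'
#' The three behaviour modes act only on holographic obstacles: real-obstacle
#' crossings always follow the `similar` draws.
#'
#' @param spec an [obstacle_spec()].
#' @param profile a [behavior_profile()].
#' @param seed integer trial seed.
#' @return list with `lead_cross`, `trail_cross` (planted crossing heights,
#'   m), `lead_clearance`, `trail_clearance`, `velocity` (m/s), `lead_side`,
#'   `pitch_max` (rad).
#' @export
plant_trial_params <- function(spec, profile, seed) {
  with_seed(seed, {
    holo <- spec$obstacle_type == "holographic"
    lead_clear <- stats::rnorm(1, profile$lead_clearance_mean,
                               profile$lead_clearance_sd)
    if (holo && profile$mode == "extreme_lead")
      lead_clear <- lead_clear + profile$lead_excess
    lead_clear <- max(lead_clear, 0.02)
    lead_cross <- spec$height + lead_clear

    if (holo && profile$mode == "no_trail_raise") {
      trail_cross <- max(profile$trail_apex_cap + stats::rnorm(1, 0, 0.01), 0.01)
    } else {
      trail_cross <- spec$height +
        max(stats::rnorm(1, profile$trail_clearance_mean,
                         profile$trail_clearance_sd), 0.02)
    }
    trail_clear <- trail_cross - spec$height

    # comfortable pace, mildly slower for higher and faster for deeper
    # obstacles (qualitative pattern of the study conditions)
    velocity <- profile$approach_speed - 0.06 * spec$height +
      0.02 * (spec$depth >= 0.1) + stats::rnorm(1, 0, 0.02)
    velocity <- max(velocity, 0.4)

    list(lead_cross = lead_cross, trail_cross = trail_cross,
         lead_clearance = lead_clear, trail_clearance = trail_clear,
         velocity = velocity,
         lead_side = sample(c("left", "right"), 1),
         pitch_max = stats::runif(1, 0, 0.2))
  })
}

# Vertical swing profile: raised-cosine ramps around a plateau of height
# `apex` covering [x_lo, x_hi]; zero elsewhere.
swing_profile <- function(x, apex, x_lo, x_hi, ramp = 0.35) {
  z <- numeric(length(x))
  up <- x > (x_lo - ramp) & x < x_lo
  dn <- x > x_hi & x < (x_hi + ramp)
  z[x >= x_lo & x <= x_hi] <- apex
  z[up] <- apex * 0.5 * (1 - cos(pi * (x[up] - (x_lo - ramp)) / ramp))
  z[dn] <- apex * 0.5 * (1 + cos(pi * (x[dn] - x_hi) / ramp))
  z
}

# Plateau extent for a given hurdle set and sole length: the foot centre is
# at plateau height whenever any sole point is above a hurdle.
plateau_bounds <- function(hurdles, sole_length, margin = 0.05) {
  c(min(hurdles) - sole_length / 2 - margin,
    max(hurdles) + sole_length / 2 + margin)
}

# Lower-edge sole points of one foot at one instant (noise-free).
# Returns matrix [n x 3] of world points; heel is the lowest point.
sole_points <- function(center_x, y, zc, pitch, sole_length, n_points) {
  d <- seq(-sole_length / 2, sole_length / 2, length.out = n_points)
  cbind(x = center_x + d * cos(pitch),
        y = rep(y, n_points),
        z = zc + (d + sole_length / 2) * sin(pitch))
}

#' Simulate one obstacle-crossing trial
#'
#' Generates a full trial bundle: a 25-point skeleton stream at the sensor
#' frame rate, per-foot 3D point clouds (a rigid sole polyline plus instep
#' points), and exact planted ground truth. The spine-shoulder point advances
#' at constant speed along the path; each foot performs one plateau-topped
#' swing over the hurdle region with its planted crossing height, the lead
#' foot first.
#'
#' Noise is applied after the ground truth is fixed: isotropic Gaussian
#' position noise on cloud points, per-frame per-foot dropout, and per-frame
#' left/right label swaps (to exercise label correction downstream).
#'
#' @param spec an [obstacle_spec()].
#' @param profile a [behavior_profile()].
#' @param noise list with `point_sd` (m), `dropout_prob`, `label_swap_prob`.
#' @param seed integer trial seed.
#' @param fps sampling rate (Hz).
#' @param sole_length rigid sole length (m), at least 0.2.
#' @param sole_n lower-edge samples along the sole (>= 60).
#' @param metadata optional list merged into the bundle metadata (e.g.
#'   participant id, repetition).
#' @param planted optional list overriding the drawn per-trial parameters
#'   (any of `lead_cross`, `trail_cross`, `velocity`, `lead_side`,
#'   `pitch_max`); used by the feedback-series simulator to impose its
#'   adaptation schedule.
#' @return a `trial_bundle` list with `metadata`, `spec`, `times`,
#'   `skeleton` (data.frame frame/time/point/x/y/z), `clouds` (data.frame
#'   frame/time/foot/x/y/z, labels possibly swapped), `swapped_frames`,
#'   `dropped_frames` and `ground_truth`.
#' @examples
#' b <- simulate_trial(obstacle_spec("holographic", 0.3, 0.02),
#'                     behavior_profile("similar"), seed = 1)
#' b$ground_truth$lead$crossing_height
#' @export
simulate_trial <- function(spec, profile,
                           noise = list(point_sd = 0.005, dropout_prob = 0.02,
                                        label_swap_prob = 0.02),
                           seed = 1, fps = 30,
                           sole_length = 0.25, sole_n = 60,
                           metadata = list(), planted = NULL) {
  stopifnot(inherits(spec, "obstacle_spec"), inherits(profile, "behavior_profile"),
            sole_length >= 0.2, sole_n >= 60)
  par <- plant_trial_params(spec, profile, seed)
  if (!is.null(planted)) {
    par <- utils::modifyList(par, planted)
    par$lead_clearance <- par$lead_cross - spec$height
    par$trail_clearance <- par$trail_cross - spec$height
  }
  if (par$lead_cross < 0 || par$trail_cross < 0)
    stop("invalid profile: planted crossing height below floor")
  noise <- utils::modifyList(list(point_sd = 0, dropout_prob = 0,
                                  label_swap_prob = 0), as.list(noise))

  v <- par$velocity
  x_start <- -0.15; x_end <- 2.25
  duration <- (x_end - x_start) / v
  n_frames <- floor(duration * fps) + 1L
  times <- (seq_len(n_frames) - 1L) / fps
  spine_x <- x_start + v * times

  half_step <- profile$step_length / 2
  lead_x <- spine_x + half_step
  trail_x <- spine_x - half_step
  pb <- plateau_bounds(spec$hurdles, sole_length)
  lead_z <- swing_profile(lead_x, par$lead_cross, pb[1], pb[2])
  trail_z <- swing_profile(trail_x, par$trail_cross, pb[1], pb[2])
  # pitch follows the swing (toe up), zero when the foot is flat on the floor
  pitch_lead <- par$pitch_max * (lead_z / max(par$lead_cross, 1e-9))
  pitch_trail <- par$pitch_max * (trail_z / max(par$trail_cross, 1e-9))

  lead_side <- par$lead_side
  trail_side <- setdiff(c("left", "right"), lead_side)
  y_of <- function(side) if (side == "left") 0.12 else -0.12

  foot_cloud <- function(center_x, zc, pitch, side) {
    sole <- sole_points(center_x, y_of(side), zc, pitch, sole_length, sole_n)
    # instep points above the sole: never part of the lower edge
    d <- seq(-sole_length / 3, sole_length / 3, length.out = 20)
    instep <- cbind(x = center_x + rep(d, 2),
                    y = y_of(side) + rep(c(-0.02, 0.02), each = 20),
                    z = zc + 0.04 + (rep(d, 2) + sole_length / 3) * sin(pitch))
    rbind(sole, instep)
  }

  clouds <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    lead_pts <- foot_cloud(lead_x[f], lead_z[f], pitch_lead[f], lead_side)
    trail_pts <- foot_cloud(trail_x[f], trail_z[f], pitch_trail[f], trail_side)
    clouds[[f]] <- data.frame(
      frame = f, time = times[f],
      foot = c(rep(lead_side, nrow(lead_pts)), rep(trail_side, nrow(trail_pts))),
      rbind(lead_pts, trail_pts))
  }
  clouds <- do.call(rbind, clouds)

  # skeleton: spine shoulder drives velocity; ankle/foot points track the feet
  ankle_foot <- function(side) {
    cx <- if (side == lead_side) lead_x else trail_x
    cz <- if (side == lead_side) lead_z else trail_z
    list(ankle = cbind(cx - 0.05, y_of(side), cz + 0.09),
         foot = cbind(cx + sole_length / 2, y_of(side), cz + 0.02))
  }
  lf <- ankle_foot("left"); rf <- ankle_foot("right")
  skel_point <- function(name, xyz) {
    data.frame(frame = seq_len(n_frames), time = times, point = name,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  fixed_offset <- list(
    SpineBase = c(0, 0, 0.95), SpineMid = c(0, 0, 1.2), Neck = c(0, 0, 1.5),
    Head = c(0, 0, 1.65), ShoulderLeft = c(0, 0.2, 1.45),
    ElbowLeft = c(0, 0.25, 1.15), WristLeft = c(0, 0.25, 0.95),
    HandLeft = c(0, 0.25, 0.9), ShoulderRight = c(0, -0.2, 1.45),
    ElbowRight = c(0, -0.25, 1.15), WristRight = c(0, -0.25, 0.95),
    HandRight = c(0, -0.25, 0.9), HipLeft = c(0, 0.12, 0.95),
    KneeLeft = c(0.05, 0.12, 0.5), HipRight = c(0, -0.12, 0.95),
    KneeRight = c(0.05, -0.12, 0.5), SpineShoulder = c(0, 0, 1.4),
    HandTipLeft = c(0, 0.25, 0.85), ThumbLeft = c(0, 0.22, 0.9),
    HandTipRight = c(0, -0.25, 0.85), ThumbRight = c(0, -0.22, 0.9))
  skeleton <- do.call(rbind, c(
    lapply(names(fixed_offset), function(nm) {
      o <- fixed_offset[[nm]]
      skel_point(nm, cbind(spine_x + o[1], rep(o[2], n_frames), rep(o[3], n_frames)))
    }),
    list(skel_point("AnkleLeft", lf$ankle), skel_point("FootLeft", lf$foot),
         skel_point("AnkleRight", rf$ankle), skel_point("FootRight", rf$foot))))
  skeleton <- skeleton[order(skeleton$frame, match(skeleton$point, KINECT_POINTS)), ]
  rownames(skeleton) <- NULL

  n_hurdles <- length(spec$hurdles)
  truth_foot <- function(cross, clear) {
    list(crossing_height = rep(cross, n_hurdles),
         clearance = rep(clear, n_hurdles),
         collision = rep(clear < 0, n_hurdles),
         max_step_height = cross)
  }
  ground_truth <- list(
    lead = truth_foot(par$lead_cross, par$lead_clearance),
    trail = truth_foot(par$trail_cross, par$trail_clearance),
    lead_side = lead_side, trail_side = trail_side,
    velocity = v)

  swapped <- integer(0); dropped <- list(left = integer(0), right = integer(0))
  clouds <- with_seed(child_seed(seed, 1L), {
    if (noise$point_sd > 0) {
      n <- nrow(clouds)
      clouds$x <- clouds$x + stats::rnorm(n, 0, noise$point_sd)
      clouds$y <- clouds$y + stats::rnorm(n, 0, noise$point_sd)
      clouds$z <- clouds$z + stats::rnorm(n, 0, noise$point_sd)
    }
    if (noise$dropout_prob > 0) {
      for (side in c("left", "right")) {
        drop_f <- which(stats::runif(n_frames) < noise$dropout_prob)
        dropped[[side]] <- drop_f
        if (length(drop_f))
          clouds <- clouds[!(clouds$foot == side & clouds$frame %in% drop_f), ]
      }
    }
    if (noise$label_swap_prob > 0) {
      swapped <- which(stats::runif(n_frames) < noise$label_swap_prob)
      if (length(swapped)) {
        sel <- clouds$frame %in% swapped
        clouds$foot[sel] <- ifelse(clouds$foot[sel] == "left", "right", "left")
      }
    }
    clouds
  })
  rownames(clouds) <- NULL

  structure(list(
    metadata = utils::modifyList(
      list(participant = NA_character_, repetition = NA_integer_,
           lead_side = lead_side, seed = seed, fps = fps,
           sole_length = sole_length), metadata),
    spec = spec, times = times, skeleton = skeleton, clouds = clouds,
    swapped_frames = swapped, dropped_frames = dropped,
    ground_truth = ground_truth, params = par, noise = noise),
    class = "trial_bundle")
}

#' @export
print.trial_bundle <- function(x, ...) {
  cat(sprintf("<trial_bundle> %s %.1f x %.2f m, %d frames at %g Hz, %d cloud points\n",
              x$spec$obstacle_type, x$spec$height, x$spec$depth,
              length(x$times), x$metadata$fps, nrow(x$clouds)))
  invisible(x)
}

#' Phase label of a feedback-experiment trial
#'
#' Trials 1-2 are familiarization, 3-7 baseline, 8-25 feedback, 26-30
#' follow-up.
#'
#' @param trial trial index 1..30.
#' @return character vector of phase labels.
#' @export
exp2_phase <- function(trial) {
  cut(trial, breaks = c(0, 2, 7, 25, 30),
      labels = c("familiarization", "baseline", "feedback", "followup")) |>
    as.character()
}

#' Plant the crossing-height schedule for a 30-trial feedback series
#'
#' Defines, per trial, the planted lead and trail crossing heights under the
#' profile's adaptation dynamics: `no_trail_raise` profiles apply a step
#' change of the trail crossing height at the adaptation onset trial;
#' `extreme_lead` profiles decay the excess lead margin exponentially with
#' the profile time constant from the onset trial; `similar` profiles are
#' stationary. Follow-up trials retain `retention_fraction` of the adaptation
#' reached by the last feedback trial. Real-obstacle series are always
#' stationary.
#'
#' @inheritParams plant_trial_params
#' @return data.frame with one row per trial 1..30: `trial`, `phase`,
#'   `lead_cross`, `trail_cross`, `lead_clearance`, `trail_clearance`,
#'   `velocity`, `trial_seed`.
#' @export
plant_exp2_schedule <- function(spec, profile, seed) {
  ad <- profile$adaptation
  if (ad$onset_trial < 8 || ad$onset_trial > 25)
    stop("adaptation onset_trial must lie in the feedback block (trials 8-25)")
  n_trials <- 30L
  trial_seeds <- vapply(seq_len(n_trials),
                        function(k) child_seed(seed, 100L + k), integer(1))
  holo <- spec$obstacle_type == "holographic"
  base <- lapply(seq_len(n_trials), function(t)
    plant_trial_params(spec, profile, trial_seeds[t]))
  lead <- vapply(base, `[[`, numeric(1), "lead_cross")
  trail <- vapply(base, `[[`, numeric(1), "trail_cross")
  velocity <- vapply(base, `[[`, numeric(1), "velocity")

  if (holo && profile$mode == "no_trail_raise") {
    # what the trail crossing would look like once raised (real-like draws)
    raised <- spec$height + pmax(vapply(seq_len(n_trials), function(t)
      with_seed(child_seed(seed, 200L + t),
                stats::rnorm(1, profile$trail_clearance_mean,
                             profile$trail_clearance_sd)), numeric(1)), 0.02)
    fb <- seq(ad$onset_trial, 25L)
    trail[fb] <- raised[fb]
    adaptation <- mean(raised[fb]) - profile$trail_apex_cap
    trail[26:30] <- profile$trail_apex_cap +
      ad$retention_fraction * adaptation +
      (raised[26:30] - mean(raised[fb]))  # keep trial-to-trial variation
  }
  if (holo && profile$mode == "extreme_lead") {
    fb <- seq(ad$onset_trial, 25L)
    decay <- exp(-(fb - ad$onset_trial + 1) / ad$time_constant)
    lead[fb] <- lead[fb] - profile$lead_excess * (1 - decay)
    adaptation <- profile$lead_excess * (1 - decay[length(decay)])
    lead[26:30] <- lead[26:30] - ad$retention_fraction * adaptation
  }
  data.frame(trial = seq_len(n_trials), phase = exp2_phase(seq_len(n_trials)),
             lead_cross = lead, trail_cross = trail,
             lead_clearance = lead - spec$height,
             trail_clearance = trail - spec$height,
             velocity = velocity, trial_seed = trial_seeds,
             stringsAsFactors = FALSE)
}

#' Simulate a 30-trial mixed-reality feedback series
#'
#' Generates the ordered trial bundles of one feedback-experiment block
#' (familiarization, baseline, feedback, follow-up) for one participant and
#' obstacle type, following the planted schedule of [plant_exp2_schedule()].
#'
#' @inheritParams simulate_trial
#' @param spec obstacle; the feedback experiment uses a 0.3 m high, 0.02 m
#'   deep obstacle.
#' @return list of 30 `trial_bundle`s, each carrying `metadata$trial` and
#'   `metadata$phase`, with the schedule attached as attribute `"schedule"`.
#' @export
simulate_exp2_series <- function(profile,
                                 spec = obstacle_spec("holographic", 0.3, 0.02),
                                 noise = list(point_sd = 0.005,
                                              dropout_prob = 0.02,
                                              label_swap_prob = 0.02),
                                 seed = 1, metadata = list()) {
  sched <- plant_exp2_schedule(spec, profile, seed)
  bundles <- lapply(seq_len(nrow(sched)), function(t) {
    simulate_trial(spec, profile, noise = noise,
                   seed = sched$trial_seed[t],
                   metadata = utils::modifyList(
                     list(trial = t, phase = sched$phase[t]), metadata),
                   planted = list(lead_cross = sched$lead_cross[t],
                                  trail_cross = sched$trail_cross[t],
                                  velocity = sched$velocity[t]))
  })
  attr(bundles, "schedule") <- sched
  bundles
}
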