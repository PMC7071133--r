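# Per-trial outcome measures from lower-edge series and the spine-shoulder
# stream: maximum step height, 30-part crossing height, clearance/collision,
# and mean forward velocity.

# Missing-outcome marker: NA with a reason attribute.
missing_outcome <- function(reason) structure(NA_real_, reason = reason)

#' Reason attached to a missing outcome value
#' @param x a value returned by a kinematics function.
#' @return the reason string, or NA if the value is not missing.
#' @export
outcome_reason <- function(x) {
  r <- attr(x, "reason")
  if (is.null(r)) NA_character_ else r
}

#' Maximum step height of a foot
#'
#' Per frame, takes the minimum vertical value of the foot's lower edge;
#' the frame qualifies when the along-path position at which that minimum is
#' attained lies inside `window`. Returns the peak of the qualifying
#' per-frame minima.
#'
#' @param series a [lower_edge_series()].
#' @param window along-path window in metres (default 0.8 to 1.6).
#' @return maximum step height (m), or NA with a reason attribute when no
#'   frame qualifies.
#' @export
max_step_height <- function(series, window = c(0.8, 1.6)) {
  best <- -Inf
  for (e in series$edges) {
    if (is.null(e)) next
    i <- which.min(e$z)
    if (e$x[i] >= window[1] && e$x[i] <= window[2])
      best <- max(best, e$z[i])
  }
  if (!is.finite(best)) return(missing_outcome("no_frame_in_window"))
  best
}

# Per-frame part representatives: the edge's x extent divided into n_parts
# contiguous parts of equal x-length; representative = (mean x, min z) of
# the edge samples in the part. Returns n_parts x 2 matrix (x, z), NA rows
# for empty parts.
part_representatives <- function(edge, n_parts) {
  x0 <- min(edge$x); x1 <- max(edge$x)
  if (x1 - x0 < 1e-9) {
    out <- matrix(NA_real_, n_parts, 2)
    out[1, ] <- c(edge$x[1], min(edge$z))
    return(out)
  }
  idx <- pmin(n_parts, floor((edge$x - x0) / (x1 - x0) * n_parts) + 1L)
  out <- matrix(NA_real_, n_parts, 2)
  for (p in unique(idx)) {
    sel <- idx == p
    out[p, ] <- c(mean(edge$x[sel]), min(edge$z[sel]))
  }
  out
}

#' Crossing height of a foot above a hurdle
#'
#' Divides each frame's lower edge into `n_parts` parts of equal along-path
#' length and follows each part index over time. Whenever a part's
#' representative position brackets the hurdle position between consecutive
#' available frames (in either travel direction), its vertical value at the
#' hurdle is obtained by linear interpolation in x; parts bracketing more
#' than once keep their minimum. The crossing height is the minimum of the
#' per-part interpolated values over all parts that crossed.
#'
#' @param series a [lower_edge_series()].
#' @param hurdle_x along-path hurdle position (m).
#' @param n_parts number of equal-length edge parts.
#' @param fit_window half-width (m) of the local window around the hurdle:
#'   when two or more of a part's samples fall within it on both sides of
#'   the hurdle, the part's value at the hurdle comes from a local
#'   least-squares line through those samples (linear in x), which averages
#'   sensor noise; otherwise plain linear interpolation between the
#'   bracketing pair is used. Both estimators coincide on noise-free
#'   locally-linear trajectories.
#' @param max_gap largest frame-index gap across which a part's trajectory
#'   is interpolated; sparser parts (empty in too many frames) are skipped
#'   rather than interpolated across long gaps.
#' @return crossing height (m), or NA with reason `"no_crossing"` when no
#'   part ever brackets the hurdle (distinct from reason `"missing_data"`
#'   when the series has no usable frames).
#' @export
crossing_height <- function(series, hurdle_x, n_parts = 30,
                            fit_window = 0.05, max_gap = 3) {
  avail <- which(!vapply(series$edges, is.null, logical(1)))
  if (length(avail) < 2) return(missing_outcome("missing_data"))
  reps <- lapply(series$edges[avail], part_representatives, n_parts = n_parts)
  px <- vapply(reps, function(r) r[, 1], numeric(n_parts))
  pz <- vapply(reps, function(r) r[, 2], numeric(n_parts))
  if (n_parts == 1) { px <- matrix(px, 1); pz <- matrix(pz, 1) }
  part_min <- rep(Inf, n_parts)
  crossed <- rep(FALSE, n_parts)
  for (p in seq_len(n_parts)) {
    ok <- !is.na(px[p, ])
    x <- px[p, ok]; z <- pz[p, ok]
    frame_idx <- avail[ok]
    if (length(x) < 2) next
    s <- x - hurdle_x
    close_pair <- diff(frame_idx) <= max_gap
    brk <- which(s[-length(s)] * s[-1] <= 0 & close_pair)
    if (!length(brk)) next
    crossed[p] <- TRUE
    near <- abs(s) <= fit_window
    if (any(near & s <= 0) && any(near & s >= 0) && sum(near) >= 2 &&
        stats::sd(x[near]) > 1e-9) {
      fit <- stats::lm.fit(cbind(1, x[near]), z[near])
      part_min[p] <- sum(fit$coefficients * c(1, hurdle_x))
    } else {
      for (i in brk) {
        zi <- if (abs(x[i + 1] - x[i]) < 1e-12) min(z[i], z[i + 1]) else
          z[i] + (hurdle_x - x[i]) / (x[i + 1] - x[i]) * (z[i + 1] - z[i])
        part_min[p] <- min(part_min[p], zi)
      }
    }
  }
  if (!any(crossed)) return(missing_outcome("no_crossing"))
  min(part_min[crossed])
}

#' Foot clearance and collision from a crossing height
#'
#' Clearance is the crossing height minus the obstacle height; a negative
#' clearance indicates a (virtual) collision for holographic obstacles. For
#' real obstacles the collision is whatever the trial metadata recorded (the
#' bar fell), not the sign of the clearance.
#'
#' @param crossing_height crossing height (m).
#' @param spec an [obstacle_spec()].
#' @param bar_fell logical from trial metadata; used for real obstacles.
#' @return list with `clearance` (m) and `collision` (logical).
#' @export
foot_clearance <- function(crossing_height, spec, bar_fell = NA) {
  clearance <- crossing_height - spec$height
  collision <- if (spec$obstacle_type == "holographic") {
    !is.na(clearance) && clearance < 0
  } else {
    isTRUE(bar_fell)
  }
  list(clearance = clearance, collision = collision)
}

#' Mean forward velocity from the spine-shoulder stream
#'
#' Distance travelled along the walking path between the two span positions
#' divided by the time between the first upward crossings of those
#' positions (crossing times found by linear interpolation).
#'
#' @param ts data.frame with columns `time` and `x` (spine-shoulder
#'   along-path position).
#' @param span along-path interval (m), default 0.1 to 1.8.
#' @return velocity (m/s), or NA with reason `"truncated"` when the
#'   trajectory never reaches the far end (trial excluded).
#' @export
forward_velocity <- function(ts, span = c(0.1, 1.8)) {
  upcross <- function(s) {
    i <- which(ts$x[-nrow(ts)] < s & ts$x[-1] >= s)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    w <- (s - ts$x[i]) / (ts$x[i + 1] - ts$x[i])
    ts$time[i] + w * (ts$time[i + 1] - ts$time[i])
  }
  if (max(ts$x) < span[2]) return(missing_outcome("truncated"))
  t1 <- upcross(span[1]); t2 <- upcross(span[2])
  if (is.na(t1) || is.na(t2)) return(missing_outcome("truncated"))
  (span[2] - span[1]) / (t2 - t1)
}

# Time at which a foot's centroid first passes x (linear interpolation);
# used for lead/trail role assignment.
first_pass_time <- function(series, x) {
  cx <- vapply(series$edges, function(e) if (is.null(e)) NA_real_ else mean(e$x),
               numeric(1))
  ok <- which(!is.na(cx))
  for (k in seq_len(length(ok) - 1)) {
    i <- ok[k]; j <- ok[k + 1]
    if (cx[i] < x && cx[j] >= x) {
      w <- (x - cx[i]) / (cx[j] - cx[i])
      return(series$times[i] + w * (series$times[j] - series$times[i]))
    }
  }
  NA_real_
}

#' Full per-trial outcomes from a trial bundle
#'
#' Runs the sensing-and-kinematics chain on one simulated or recorded trial:
#' per-foot lower edges (with label correction), lead/trail role assignment
#' by temporal order of the first hurdle crossing, maximum step heights,
#' per-hurdle crossing heights, clearances and collision flags, and forward
#' velocity from the spine-shoulder stream.
#'
#' @param bundle a `trial_bundle`.
#' @param n_parts parts for [crossing_height()].
#' @param bin_width lower-edge bin width (m).
#' @return one-row data.frame in the trial-outcome layout of
#'   [simulate_cohort_outcomes()].
#' @export
trial_outcomes <- function(bundle, n_parts = 30, bin_width = 0.01) {
  ed <- bundle_edges(bundle, bin_width = bin_width)
  spec <- bundle$spec
  h1 <- spec$hurdles[1]
  t_left <- first_pass_time(ed$left, h1)
  t_right <- first_pass_time(ed$right, h1)
  lead_side <- if (is.na(t_left) || is.na(t_right)) {
    bundle$metadata$lead_side
  } else if (t_left <= t_right) "left" else "right"
  series <- list(lead = ed[[lead_side]],
                 trail = ed[[setdiff(c("left", "right"), lead_side)]])

  res <- list()
  for (role in c("lead", "trail")) {
    s <- series[[role]]
    res[[paste0(role, "_step")]] <- as.numeric(max_step_height(s))
    for (h in seq_along(spec$hurdles)) {
      ch <- crossing_height(s, spec$hurdles[h], n_parts = n_parts)
      planted_coll <- bundle$ground_truth[[role]]$collision[h]
      fc <- foot_clearance(as.numeric(ch), spec, bar_fell = planted_coll)
      res[[sprintf("%s_cross_h%d", role, h)]] <- as.numeric(ch)
      res[[sprintf("%s_clear_h%d", role, h)]] <- fc$clearance
      res[[sprintf("%s_coll_h%d", role, h)]] <- fc$collision
    }
    if (length(spec$hurdles) == 1) {
      res[[sprintf("%s_cross_h2", role)]] <- NA_real_
      res[[sprintf("%s_clear_h2", role)]] <- NA_real_
      res[[sprintf("%s_coll_h2", role)]] <- NA
    }
  }
  sp <- bundle$skeleton[bundle$skeleton$point == "SpineShoulder", c("time", "x")]
  vel <- forward_velocity(sp)
  excluded <- is.na(vel)
  data.frame(participant = bundle$metadata$participant,
             obstacle_type = spec$obstacle_type,
             height = spec$height, depth = spec$depth,
             repetition = bundle$metadata$repetition,
             lead_step = res$lead_step, trail_step = res$trail_step,
             lead_cross_h1 = res$lead_cross_h1, trail_cross_h1 = res$trail_cross_h1,
             lead_clear_h1 = res$lead_clear_h1, trail_clear_h1 = res$trail_clear_h1,
             lead_coll_h1 = res$lead_coll_h1, trail_coll_h1 = res$trail_coll_h1,
             lead_cross_h2 = res$lead_cross_h2, trail_cross_h2 = res$trail_cross_h2,
             lead_clear_h2 = res$lead_clear_h2, trail_clear_h2 = res$trail_clear_h2,
             lead_coll_h2 = res$lead_coll_h2, trail_coll_h2 = res$trail_coll_h2,
             velocity = as.numeric(vel), excluded = excluded,
             exclude_reason = if (excluded) outcome_reason(vel) else NA_character_,
             stringsAsFactors = FALSE)
}

#' Condition summaries over repetitions 2 to 6
#'
#' The first repetition of each condition is excluded to avoid first-trial
#' effects; per condition and outcome the median of the available values
#' over repetitions 2-6 is reported, together with the number of
#' contributing trials. Cells with no available repetitions stay missing
#' (never imputed here).
#'
#' @param outcomes trial-level outcome data.frame (layout of
#'   [simulate_cohort_outcomes()] / [trial_outcomes()]).
#' @param measures outcome columns to summarise.
#' @return long data.frame: participant, obstacle_type, height, depth,
#'   outcome, median, n_used.
#' @export
summarize_trials <- function(outcomes,
                             measures = c("lead_step", "trail_step",
                                          "lead_cross_h1", "trail_cross_h1",
                                          "lead_clear_h1", "trail_clear_h1",
                                          "lead_cross_h2", "trail_cross_h2",
                                          "lead_clear_h2", "trail_clear_h2",
                                          "velocity")) {
  keep <- outcomes$repetition >= 2 & outcomes$repetition <= 6 &
    !isTRUE_vec(outcomes$excluded)
  dat <- outcomes[keep, , drop = FALSE]
  key <- interaction(dat$participant, dat$obstacle_type, dat$height, dat$depth,
                     drop = TRUE)
  rows <- lapply(split(dat, key), function(cell) {
    do.call(rbind, lapply(measures, function(m) {
      v <- cell[[m]][!is.na(cell[[m]])]
      data.frame(participant = cell$participant[1],
                 obstacle_type = cell$obstacle_type[1],
                 height = cell$height[1], depth = cell$depth[1],
                 outcome = m,
                 median = if (length(v)) stats::median(v) else NA_real_,
                 n_used = length(v), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Trial-level collision tallies
#'
#' Counts collisions per participant, obstacle type, hurdle and foot role
#' over the analysed repetitions (2-6 by default, matching the trials that
#' enter all other analyses).
#'
#' @param outcomes trial-level outcome data.frame.
#' @param repetitions repetitions counted.
#' @return data.frame with participant, obstacle_type, hurdle, foot,
#'   collisions, trials.
#' @export
collision_table <- function(outcomes, repetitions = 2:6) {
  dat <- outcomes[outcomes$repetition %in% repetitions &
                    !isTRUE_vec(outcomes$excluded), , drop = FALSE]
  grid <- expand.grid(foot = c("lead", "trail"), hurdle = 1:2,
                      obstacle_type = unique(dat$obstacle_type),
                      participant = unique(dat$participant),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    col <- sprintf("%s_coll_h%d", g$foot, g$hurdle)
    sel <- dat$participant == g$participant &
      dat$obstacle_type == g$obstacle_type & !is.na(dat[[col]])
    data.frame(g, collisions = sum(dat[[col]][sel]), trials = sum(sel))
  })
  out <- do.call(rbind, rows)
  out[out$trials > 0, ]
}

#' Collision rates over analysed-trial denominators
#'
#' Expresses collision counts as percentages of the analysed trials implied
#' by a cohort design: with 12 participants, 5 heights, 2 depths and
#' repetitions 2-6 there are 600 analysed hurdle-1 trials per obstacle type
#' and 300 hurdle-2 trials (hurdle 2 exists only for deep obstacles).
#'
#' @param counts named numeric vector of collision counts.
#' @param design a [design_cohort()] object supplying the denominators.
#' @param hurdle hurdle index per count (1 or 2), recycled.
#' @param obstacle_type obstacle type of the counted trials.
#' @param repetitions analysed repetitions.
#' @return data.frame with count, denominator and percentage per entry.
#' @export
collision_rates <- function(counts, design, hurdle = 1,
                            obstacle_type = "holographic",
                            repetitions = 2:6) {
  tr <- design$trials
  tr <- tr[tr$obstacle_type == obstacle_type & tr$repetition %in% repetitions, ]
  denom_h1 <- nrow(tr)
  denom_h2 <- sum(tr$depth >= 0.1)
  hurdle <- rep_len(hurdle, length(counts))
  denom <- ifelse(hurdle == 1, denom_h1, denom_h2)
  data.frame(name = names(counts) %||% seq_along(counts),
             count = as.numeric(counts), hurdle = hurdle,
             denominator = denom,
             percent = 100 * as.numeric(counts) / denom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
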