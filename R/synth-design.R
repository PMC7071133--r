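#' Obstacle specification
#'
#' Describes one obstacle condition: real or holographic, a height, and a
#' depth. Shallow obstacles (depth 0.02 m) consist of a single hurdle at
#' 1.2 m along the walking path; deep obstacles (depth 0.30 m) add a second
#' hurdle at the rear edge, 1.2 + 0.30 = 1.5 m.
#'
#' @param obstacle_type `"real"` or `"holographic"`.
#' @param height hurdle height in metres (the study grid uses 0.0, 0.1, 0.2,
#'   0.3, 0.4).
#' @param depth obstacle depth in metres (0.02 or 0.30 in the study grid).
#' @param first_hurdle along-path position of the front hurdle in metres.
#' @return an `obstacle_spec` list with fields `obstacle_type`, `height`,
#'   `depth`, and `hurdles` (along-path hurdle positions).
#' @examples
#' obstacle_spec("holographic", 0.3, 0.30)$hurdles  # 1.2 1.5
#' @export
obstacle_spec <- function(obstacle_type = c("real", "holographic"),
                          height, depth, first_hurdle = 1.2) {
  obstacle_type <- match.arg(obstacle_type)
  stopifnot(is.numeric(height), length(height) == 1, height >= 0,
            is.numeric(depth), length(depth) == 1, depth > 0)
  hurdles <- if (depth >= 0.1) c(first_hurdle, first_hurdle + depth) else first_hurdle
  structure(list(obstacle_type = obstacle_type, height = height,
                 depth = depth, hurdles = hurdles),
            class = "obstacle_spec")
}

#' @export
print.obstacle_spec <- function(x, ...) {
  cat(sprintf("<obstacle_spec> %s, height %.2f m, depth %.2f m, hurdle(s) at %s m\n",
              x$obstacle_type, x$height, x$depth,
              paste(format(x$hurdles), collapse = ", ")))
  invisible(x)
}

#' Behavioural profile of a simulated participant
#'
#' Encodes one of the three avoidance styles observed in holographic-obstacle
#' crossing: `"similar"` (holographic crossings resemble real ones),
#' `"extreme_lead"` (exceptionally large lead-foot margins over holographic
#' obstacles), and `"no_trail_raise"` (the trail foot is not raised over
#' holographic obstacles, so its apex stays near ground level and 3D
#' obstacles are virtually struck).
#'
#' Clearance draws are Gaussian per trial. The defaults (lead N(0.13, 0.03) m,
#' trail N(0.15, 0.04) m, +0.25 m lead excess for `extreme_lead`, 0.05 m trail
#' apex cap for `no_trail_raise`) are configurable assumptions chosen to
#' reproduce the qualitative subgroup separations, not estimates from data.
#'
#' @param mode one of `"similar"`, `"extreme_lead"`, `"no_trail_raise"`.
#' @param lead_clearance_mean,lead_clearance_sd lead-foot clearance
#'   distribution (m).
#' @param trail_clearance_mean,trail_clearance_sd trail-foot clearance
#'   distribution (m).
#' @param lead_excess extra lead clearance for `extreme_lead` holographic
#'   crossings (m).
#' @param trail_apex_cap swing apex of the unraised trail foot for
#'   `no_trail_raise` holographic crossings (m above floor).
#' @param approach_speed mean forward walking speed (m/s).
#' @param step_length nominal step length (m); sets the lead/trail foot
#'   phase offset.
#' @param adaptation list with `onset_trial`, `time_constant` (trials) and
#'   `retention_fraction` in `[0, 1]`; used only by feedback-series
#'   simulation.
#' @return a `behavior_profile` list.
#' @export
behavior_profile <- function(mode = c("similar", "extreme_lead", "no_trail_raise"),
                             lead_clearance_mean = 0.13, lead_clearance_sd = 0.03,
                             trail_clearance_mean = 0.15, trail_clearance_sd = 0.04,
                             lead_excess = 0.25, trail_apex_cap = 0.05,
                             approach_speed = 0.9, step_length = 0.6,
                             adaptation = list(onset_trial = 8,
                                               time_constant = 4,
                                               retention_fraction = 0.8)) {
  if (length(mode) != 1 || !mode %in% c("similar", "extreme_lead", "no_trail_raise"))
    stop("unknown behaviour mode: ", paste(mode, collapse = ", "))
  stopifnot(lead_clearance_sd >= 0, trail_clearance_sd >= 0,
            approach_speed > 0, step_length > 0,
            adaptation$retention_fraction >= 0, adaptation$retention_fraction <= 1)
  structure(list(mode = mode,
                 lead_clearance_mean = lead_clearance_mean,
                 lead_clearance_sd = lead_clearance_sd,
                 trail_clearance_mean = trail_clearance_mean,
                 trail_clearance_sd = trail_clearance_sd,
                 lead_excess = lead_excess,
                 trail_apex_cap = trail_apex_cap,
                 approach_speed = approach_speed,
                 step_length = step_length,
                 adaptation = adaptation),
            class = "behavior_profile")
}

#' Default behaviour-mode assignment for a cohort
#'
#' For 12 participants this reproduces the canonical 6/3/3 split with the
#' `no_trail_raise` style at participants 1, 8, 11 and `extreme_lead` at
#' 4, 7, 10; other cohort sizes recycle a similar/similar/extreme/no-trail
#' pattern.
#'
#' @param n_participants cohort size.
#' @return named character vector of modes, one per participant id.
#' @export
default_mode_assignment <- function(n_participants) {
  ids <- sprintf("P%02d", seq_len(n_participants))
  if (n_participants == 12) {
    modes <- rep("similar", 12)
    modes[c(1, 8, 11)] <- "no_trail_raise"
    modes[c(4, 7, 10)] <- "extreme_lead"
  } else {
    modes <- rep_len(c("similar", "similar", "extreme_lead", "no_trail_raise"),
                     n_participants)
  }
  stats::setNames(modes, ids)
}

#' Design a complete crossing-experiment cohort
#'
#' Builds the full factorial trial grid: per participant, two obstacle-type
#' blocks of 60 trials (5 heights x 2 depths x 6 repetitions). Obstacle-type
#' block order and depth order are counterbalanced over participants;
#' height-by-depth conditions are block-randomised within each repetition
#' round. Every trial receives its own derived seed so downstream simulation
#' is reproducible trial by trial.
#'
#' @param n_participants number of participants (>= 1).
#' @param mode_assignment named character vector mapping participant id to a
#'   behaviour mode; defaults to [default_mode_assignment()].
#' @param seed integer root seed.
#' @param heights,depths,n_reps condition grid.
#' @return a `cohort_design` list with `participants` (id, height, mode) and
#'   `trials` (one row per trial with condition, repetition, order and seed).
#' @examples
#' d <- design_cohort(12, seed = 1)
#' nrow(d$trials)  # 1440
#' @export
design_cohort <- function(n_participants = 12,
                          mode_assignment = default_mode_assignment(n_participants),
                          seed = 1,
                          heights = c(0, 0.1, 0.2, 0.3, 0.4),
                          depths = c(0.02, 0.30),
                          n_reps = 6) {
  stopifnot(n_participants >= 1)
  ids <- sprintf("P%02d", seq_len(n_participants))
  if (is.null(names(mode_assignment)))
    names(mode_assignment) <- ids[seq_along(mode_assignment)]
  missing_ids <- setdiff(ids, names(mode_assignment))
  if (length(missing_ids))
    stop("no behaviour mode assigned for: ", paste(missing_ids, collapse = ", "))
  bad <- setdiff(unique(mode_assignment),
                 c("similar", "extreme_lead", "no_trail_raise"))
  if (length(bad))
    stop("unknown behaviour mode: ", paste(bad, collapse = ", "))

  with_seed(seed, {
    participants <- data.frame(
      participant = ids,
      body_height = round(stats::runif(n_participants, 1.55, 1.95), 2),
      mode = unname(mode_assignment[ids]),
      # counterbalancing: alternate starting obstacle type and depth order
      first_type = rep_len(c("real", "holographic"), n_participants),
      depth_order = rep_len(c("shallow_first", "deep_first"), n_participants),
      stringsAsFactors = FALSE
    )

    rows <- vector("list", n_participants * 2L)
    i <- 0L
    for (p in seq_len(n_participants)) {
      types <- if (participants$first_type[p] == "real")
        c("real", "holographic") else c("holographic", "real")
      dd <- if (participants$depth_order[p] == "shallow_first")
        depths else rev(depths)
      for (b in 1:2) {
        conds <- expand.grid(depth = dd, height = heights,
                             KEEP.OUT.ATTRS = FALSE)
        block <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
          ord <- sample.int(nrow(conds))  # block-randomised within round
          data.frame(participant = ids[p], obstacle_type = types[b],
                     block = b, repetition = r,
                     height = conds$height[ord], depth = conds$depth[ord],
                     order_in_round = seq_len(nrow(conds)),
                     stringsAsFactors = FALSE)
        }))
        i <- i + 1L
        rows[[i]] <- block
      }
    }
    trials <- do.call(rbind, rows)
    trials <- trials[order(trials$participant, trials$block,
                           trials$repetition, trials$order_in_round), ]
    rownames(trials) <- NULL
    trials$trial_seed <- vapply(seq_len(nrow(trials)),
                                function(k) child_seed(seed, k), integer(1))
    structure(list(participants = participants, trials = trials, seed = seed),
              class = "cohort_design")
  })
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %d participants, %d trials (seed %d)\n",
              nrow(x$participants), nrow(x$trials), x$seed))
  print(table(x$participants$mode))
  invisible(x)
}

#' Profile lookup for a cohort participant
#'
#' @param design a `cohort_design`.
#' @param participant participant id.
#' @param ... overrides passed to [behavior_profile()].
#' @return a `behavior_profile`.
#' @export
cohort_profile <- function(design, participant, ...) {
  row <- design$participants[design$participants$participant == participant, ]
  if (nrow(row) != 1) stop("unknown participant: ", participant)
  behavior_profile(mode = row$mode, ...)
}

#' Headset-to-hurdle-top viewing distance
#'
#' Straight-line distance between a head-mounted display and the top of an
#' obstacle: `sqrt(horizontal^2 + (headset_height - obstacle_height)^2)`.
#' For a 1.75 m headset height, a 0.2 m obstacle and a 1.2 m horizontal
#' distance this is about 2.0 m, matching the fixed focal distance of the
#' display used to place the front hurdle.
#'
#' @param headset_height headset height above the floor (m).
#' @param obstacle_height obstacle height (m).
#' @param horizontal_distance along-floor distance (m).
#' @return distance in metres.
#' @examples
#' headset_view_distance(1.75, 0.2, 1.2)
#' @export
headset_view_distance <- function(headset_height, obstacle_height,
                                  horizontal_distance) {
  stopifnot(headset_height >= 0, obstacle_height >= 0, horizontal_distance >= 0)
  sqrt(horizontal_distance^2 + (headset_height - obstacle_height)^2)
}
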