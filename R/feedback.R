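# Feedback-experiment analysis: per-block 95% confidence intervals of
# crossing heights, first-deviating-block detection in the feedback phase,
# and trial-level MDS against the real-obstacle average.

#' t-based 95% confidence interval of a sample mean
#'
#' @param x numeric values (NAs dropped).
#' @param level confidence level.
#' @return list with `n`, `mean`, `lower`, `upper`; bounds are NA when
#'   fewer than two values are available.
#' @export
mean_ci <- function(x, level = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2)
    return(list(n = n, mean = if (n) mean(x) else NA_real_,
                lower = NA_real_, upper = NA_real_))
  m <- mean(x)
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(x) / sqrt(n)
  list(n = n, mean = m, lower = m - half, upper = m + half)
}

# Two intervals deviate iff they are disjoint (order-free).
ci_disjoint <- function(a, b) {
  if (anyNA(c(a$lower, a$upper, b$lower, b$upper))) return(NA)
  a$upper < b$lower || b$upper < a$lower
}

#' Per-block confidence intervals of a feedback series
#'
#' Computes the 95% confidence interval of `measure` for the standard
#' blocks of a 30-trial feedback series: all 30 trials, the baseline
#' (trials 3-7), the feedback block (8-25) and the follow-up block
#' (26-30). For a real-obstacle series the all-trials interval is the one
#' a deviation analysis compares against; for holographic series the three
#' phase blocks are the objects of interest. Blocks with fewer than two
#' non-missing trials get undefined (NA) bounds.
#'
#' @param series feedback-series data.frame (layout of
#'   [simulate_exp2_outcomes()]).
#' @param measure outcome column, e.g. `"trail_cross"`.
#' @param level confidence level.
#' @return data.frame with block, trials, n, mean, lower, upper.
#' @export
block_confidence_intervals <- function(series, measure = "trail_cross",
                                       level = 0.95) {
  stopifnot(measure %in% names(series))
  blocks <- list(all_trials = 1:30, baseline = 3:7,
                 feedback = 8:25, followup = 26:30)
  rows <- lapply(names(blocks), function(b) {
    v <- series[[measure]][series$trial %in% blocks[[b]]]
    ci <- mean_ci(v, level)
    data.frame(block = b,
               trials = paste(range(blocks[[b]]), collapse = "-"),
               n = ci$n, mean = ci$mean, lower = ci$lower, upper = ci$upper,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' First feedback block deviating from baseline
#'
#' Slides a window of five consecutive feedback trials (window k covers
#' trials 7+k to 11+k, k = 1..14) and returns the smallest k whose 95%
#' confidence interval is disjoint from the baseline (trials 3-7)
#' interval, or NA when no window deviates. Windows with fewer than two
#' available values are skipped and noted.
#'
#' @inheritParams block_confidence_intervals
#' @return list with `first_block` (k or NA), `baseline` interval, and
#'   `windows` data.frame (k, trials, n, mean, lower, upper, deviates).
#' @export
first_deviating_block <- function(series, measure = "trail_cross",
                                  level = 0.95) {
  base <- mean_ci(series[[measure]][series$trial %in% 3:7], level)
  if (is.na(base$lower)) stop("baseline confidence interval undefined")
  rows <- lapply(1:14, function(k) {
    idx <- (7 + k):(11 + k)
    ci <- mean_ci(series[[measure]][series$trial %in% idx], level)
    data.frame(k = k, trials = paste(range(idx), collapse = "-"),
               n = ci$n, mean = ci$mean, lower = ci$lower, upper = ci$upper,
               deviates = isTRUE(ci_disjoint(ci, base)),
               skipped = ci$n < 2, stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, rows)
  hit <- which(windows$deviates)
  list(first_block = if (length(hit)) windows$k[hit[1]] else NA_integer_,
       baseline = base, windows = windows)
}

#' Per-participant feedback report (deviation table)
#'
#' Assembles, for one participant, the table-style report of a feedback
#' experiment: the real-obstacle all-trials interval, the holographic
#' baseline, feedback and follow-up intervals, whether the baseline
#' deviates from the real interval, whether the feedback and follow-up
#' intervals deviate from the baseline, and the first deviating feedback
#' block.
#'
#' @param real_series,holo_series feedback-series data.frames for the real
#'   and holographic blocks of one participant.
#' @param measure outcome column.
#' @return one-row data.frame of interval bounds and deviation flags.
#' @export
feedback_report <- function(real_series, holo_series, measure = "trail_cross") {
  real_ci <- mean_ci(real_series[[measure]][real_series$trial %in% 1:30])
  ci <- block_confidence_intervals(holo_series, measure)
  get <- function(b) as.list(ci[ci$block == b, c("n", "mean", "lower", "upper")])
  base <- get("baseline"); fb <- get("feedback"); fu <- get("followup")
  fd <- first_deviating_block(holo_series, measure)
  data.frame(participant = holo_series$participant[1],
             measure = measure,
             real_lower = real_ci$lower, real_upper = real_ci$upper,
             baseline_lower = base$lower, baseline_upper = base$upper,
             feedback_lower = fb$lower, feedback_upper = fb$upper,
             followup_lower = fu$lower, followup_upper = fu$upper,
             baseline_vs_real = isTRUE(ci_disjoint(base, real_ci)),
             feedback_vs_baseline = isTRUE(ci_disjoint(fb, base)),
             followup_vs_baseline = isTRUE(ci_disjoint(fu, base)),
             first_deviating_block = fd$first_block,
             stringsAsFactors = FALSE)
}

#' Trial-level MDS of a participant subgroup and distances to the real
#' average
#'
#' Builds one object per obstacle type and trial (trials 3-30 of both
#' blocks: 56 objects). Each object's feature vector concatenates, over the
#' subgroup participants, the lead and trail clearances and lead and trail
#' maximum step heights of that trial. Objects are embedded with classical
#' MDS of their Euclidean distances, and every holographic trial's distance
#' to the mean feature vector of the 28 real trials is reported. Missing
#' trial values are imputed with the participant x type x measure mean.
#'
#' @param series_list list of feedback-series data.frames covering both
#'   obstacle types for each subgroup participant.
#' @return list with `embedding` (an `mds_embedding` over the trial
#'   objects), `objects` data.frame, and `dist_to_real` data.frame (trial,
#'   distance) for holographic trials.
#' @export
trial_mds_distances <- function(series_list) {
  all_series <- do.call(rbind, series_list)
  participants <- sort(unique(all_series$participant))
  types <- c("real", "holographic")
  trials <- 3:30
  measures <- c("lead_clear", "trail_clear", "lead_step", "trail_step")
  stopifnot(all(types %in% all_series$obstacle_type))

  objects <- expand.grid(trial = trials, obstacle_type = types,
                         stringsAsFactors = FALSE)
  vec_of <- function(type, trial) {
    unlist(lapply(participants, function(p) {
      row <- all_series[all_series$participant == p &
                          all_series$obstacle_type == type &
                          all_series$trial == trial, measures]
      vapply(measures, function(m) {
        v <- if (nrow(row)) row[[m]][1] else NA_real_
        if (is.na(v)) {
          pool <- all_series[[m]][all_series$participant == p &
                                    all_series$obstacle_type == type]
          v <- mean(pool, na.rm = TRUE)
        }
        v
      }, numeric(1))
    }))
  }
  V <- t(vapply(seq_len(nrow(objects)),
                function(i) vec_of(objects$obstacle_type[i], objects$trial[i]),
                numeric(4 * length(participants))))
  rownames(V) <- paste(objects$obstacle_type, objects$trial, sep = ".")
  D <- distance_matrix(V)
  emb <- mds_embed(D, dims = 2)
  real_mean <- colMeans(V[objects$obstacle_type == "real", , drop = FALSE])
  holo_idx <- which(objects$obstacle_type == "holographic")
  dist_to_real <- data.frame(
    trial = objects$trial[holo_idx],
    phase = exp2_phase(objects$trial[holo_idx]),
    distance = apply(V[holo_idx, , drop = FALSE], 1,
                     function(v) sqrt(sum((v - real_mean)^2))))
  rownames(dist_to_real) <- NULL
  list(embedding = emb, objects = objects, dist_to_real = dist_to_real)
}
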