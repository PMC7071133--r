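# Obstacle-type dissimilarity screening: 250-element outcome vectors per
# participant x obstacle type, Euclidean distance matrix, classical MDS,
# and rule-based subgroup flags.

#' Build per-object outcome feature vectors
#'
#' One object per participant x obstacle type. The canonical element
#' ordering is: hurdle-1 block — for each height (ascending), depth (0.02
#' then 0.30) and repetition (2..6): lead step height, trail step height,
#' lead clearance at hurdle 1, trail clearance at hurdle 1 (5 x 2 x 5 x 4 =
#' 200 elements); then hurdle-2 block — for each height and repetition:
#' lead clearance at hurdle 2, trail clearance at hurdle 2 (5 x 5 x 2 = 50
#' elements; hurdle 2 exists only for deep obstacles). Total 250. Any fixed
#' ordering yields the same Euclidean distances; this one is documented for
#' reproducibility.
#'
#' Missing entries are imputed with the participant x condition x outcome
#' median of the available repetitions (falling back to the participant x
#' outcome median) and recorded in the availability mask.
#'
#' @param outcomes trial-level outcome data.frame (layout of
#'   [simulate_cohort_outcomes()]).
#' @param heights,depths,repetitions the condition grid the vectors cover.
#' @return a `feature_vectors` object: list with `values` (objects x 250
#'   matrix), `mask` (TRUE = observed), and `objects` (participant, type).
#' @export
build_feature_vectors <- function(outcomes,
                                  heights = c(0, 0.1, 0.2, 0.3, 0.4),
                                  depths = c(0.02, 0.30),
                                  repetitions = 2:6) {
  outcomes <- outcomes[!isTRUE_vec(outcomes$excluded), , drop = FALSE]
  participants <- sort(unique(outcomes$participant))
  types <- c("real", "holographic")
  h1_out <- c("lead_step", "trail_step", "lead_clear_h1", "trail_clear_h1")
  h2_out <- c("lead_clear_h2", "trail_clear_h2")
  n_elem <- length(heights) * length(depths) * length(repetitions) * length(h1_out) +
    length(heights) * length(repetitions) * length(h2_out)

  labels <- character(0)
  for (h in heights) for (d in depths) for (r in repetitions) for (o in h1_out)
    labels <- c(labels, sprintf("h%.1f_d%.2f_r%d_%s", h, d, r, o))
  deep <- max(depths)
  for (h in heights) for (r in repetitions) for (o in h2_out)
    labels <- c(labels, sprintf("h%.1f_d%.2f_r%d_%s", h, deep, r, o))

  objects <- expand.grid(obstacle_type = types, participant = participants,
                         stringsAsFactors = FALSE)[, c(2, 1)]
  values <- matrix(NA_real_, nrow(objects), n_elem,
                   dimnames = list(paste(objects$participant,
                                         objects$obstacle_type, sep = "."),
                                   labels))
  mask <- matrix(TRUE, nrow(objects), n_elem,
                 dimnames = dimnames(values))
  n_warn <- 0L

  for (i in seq_len(nrow(objects))) {
    sub <- outcomes[outcomes$participant == objects$participant[i] &
                      outcomes$obstacle_type == objects$obstacle_type[i], ]
    vec <- numeric(0); obs <- logical(0)
    cell_value <- function(h, d, r, o) {
      rows <- sub[abs(sub$height - h) < 1e-9 & abs(sub$depth - d) < 1e-9, ]
      v <- rows[[o]][rows$repetition == r]
      if (length(v) == 1 && !is.na(v)) return(c(v, TRUE))
      # impute: condition median over available reps, then object median
      cond <- rows[[o]][rows$repetition %in% repetitions]
      cond <- cond[!is.na(cond)]
      imp <- if (length(cond)) stats::median(cond) else {
        allv <- sub[[o]][!is.na(sub[[o]])]
        if (length(allv)) stats::median(allv) else 0
      }
      c(imp, FALSE)
    }
    for (h in heights) for (d in depths) for (r in repetitions) for (o in h1_out) {
      cv <- cell_value(h, d, r, o); vec <- c(vec, cv[1]); obs <- c(obs, cv[2] > 0)
    }
    for (h in heights) for (r in repetitions) for (o in h2_out) {
      cv <- cell_value(h, deep, r, o); vec <- c(vec, cv[1]); obs <- c(obs, cv[2] > 0)
    }
    values[i, ] <- vec
    mask[i, ] <- obs
    if (!all(obs)) n_warn <- n_warn + 1L
  }
  if (n_warn)
    warning(n_warn, " object vector(s) contain imputed (masked) entries")
  structure(list(values = values, mask = mask, objects = objects),
            class = "feature_vectors")
}

#' @export
print.feature_vectors <- function(x, ...) {
  cat(sprintf("<feature_vectors> %d objects x %d elements (%d masked entries)\n",
              nrow(x$values), ncol(x$values), sum(!x$mask)))
  invisible(x)
}

#' Pairwise Euclidean distance matrix between feature vectors
#'
#' When two vectors have differently masked entries, the distance is
#' computed over the mutually available elements and rescaled by
#' `sqrt(p / m)` (p = vector length, m = mutually available count) so that
#' partially observed pairs remain comparable to fully observed ones.
#'
#' @param fv a [build_feature_vectors()] object, or a plain numeric matrix
#'   (rows = objects).
#' @return symmetric distance matrix with zero diagonal; object labels as
#'   dimnames and the object table as attribute `"objects"`.
#' @export
distance_matrix <- function(fv) {
  if (is.matrix(fv)) fv <- list(values = fv,
                                mask = matrix(TRUE, nrow(fv), ncol(fv)),
                                objects = NULL)
  n <- nrow(fv$values)
  if (n < 2) stop("need at least two feature vectors")
  p <- ncol(fv$values)
  D <- matrix(0, n, n, dimnames = list(rownames(fv$values), rownames(fv$values)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- fv$mask[i, ] & fv$mask[j, ]
    m <- sum(ok)
    d <- if (m == 0) NA_real_ else
      sqrt(sum((fv$values[i, ok] - fv$values[j, ok])^2) * p / m)
    D[i, j] <- D[j, i] <- d
  }
  structure(D, objects = fv$objects)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared-distance matrix (`-0.5 * J D^2 J`),
#' eigendecomposes it, and takes coordinates from the leading eigenvectors
#' scaled by the square roots of their (non-negative) eigenvalues. The
#' embedding is deterministic up to reflections; signs are fixed so the
#' largest-magnitude loading of each axis is positive.
#'
#' @param D symmetric distance matrix.
#' @param dims embedding dimension.
#' @return an `mds_embedding` list: `points` (n x dims), `eigenvalues`
#'   (all n), and `stress` (relative distance-reconstruction error).
#' @export
mds_embed <- function(D, dims = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n == ncol(D), all(abs(D - t(D)) < 1e-8), all(diag(D) == 0))
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lambda <- e$values
  k <- seq_len(dims)
  lpos <- pmax(lambda[k], 0)
  pts <- e$vectors[, k, drop = FALSE] %*% diag(sqrt(lpos), dims)
  # sign convention: largest-|loading| coordinate positive per axis
  for (d in seq_len(dims)) {
    i <- which.max(abs(pts[, d]))
    if (length(i) && pts[i, d] < 0) pts[, d] <- -pts[, d]
  }
  rownames(pts) <- rownames(D)
  Dhat <- as.matrix(stats::dist(pts))
  denom <- sum(D^2)
  stress <- if (denom > 0) sqrt(sum((Dhat - D)^2) / denom) else 0
  structure(list(points = pts, eigenvalues = lambda, stress = stress,
                 objects = attr(D, "objects")),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d objects in %d dims, stress %.4f\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

#' Real-to-holographic distance per participant
#'
#' Extracts, for every participant present with both obstacle-type objects,
#' the entry of the distance matrix between that participant's real and
#' holographic vectors. Large values signal dissimilar holographic
#' avoidance.
#'
#' @param D distance matrix from [distance_matrix()] with row names of the
#'   form `"<participant>.<obstacle_type>"`.
#' @return named numeric vector of distances (one per participant).
#' @export
holo_real_distance <- function(D) {
  labels <- rownames(as.matrix(D))
  parts <- sub("\\.(real|holographic)$", "", labels)
  types <- sub("^.*\\.", "", labels)
  out <- c()
  for (p in unique(parts)) {
    i <- which(parts == p & types == "real")
    j <- which(parts == p & types == "holographic")
    if (length(i) != 1 || length(j) != 1) {
      warning("participant ", p, " lacks one obstacle-type object; skipped")
      next
    }
    out[p] <- D[i, j]
  }
  out
}

#' Rule-based subgroup flags from trial-level outcomes
#'
#' Operationalises the two dissimilar avoidance styles:
#' `no_trail_raise` — the trail foot collides in at least
#' `collision_fraction` of the analysed holographic 3D-obstacle trials
#' (height >= 0.1 m);
#' `extreme_lead` — the participant's mean holographic-minus-real lead-foot
#' step-height difference lies above the cohort's upper 95% bound for that
#' difference for at least `min_heights` of the four 3D obstacle heights.
#' The bound for participant i is a leave-one-out robust prediction bound,
#' `median(d[-i]) + t(0.975, n-2) * 1.4826 * mad(d[-i]) * sqrt(1 + 1/(n-1))`:
#' robust against the flagged participants themselves inflating the spread,
#' and calibrated so that unremarkable participants are practically never
#' flagged. `no_trail_raise` takes precedence when both rules trigger; all
#' other participants are labelled `similar`.
#'
#' @param outcomes trial-level outcome data.frame for the whole cohort.
#' @param collision_fraction trail-collision fraction threshold.
#' @param min_heights number of 3D heights that must exceed the CI bound.
#' @param repetitions analysed repetitions.
#' @return data.frame per participant: `label`, `trail_coll_frac`,
#'   `n_heights_above`.
#' @export
flag_subgroups <- function(outcomes, collision_fraction = 0.9,
                           min_heights = 3, repetitions = 2:6) {
  participants <- sort(unique(outcomes$participant))
  if (length(participants) < 3)
    stop("cohort confidence-interval rule needs at least 3 participants")
  dat <- outcomes[outcomes$repetition %in% repetitions &
                    !isTRUE_vec(outcomes$excluded), ]
  heights3d <- sort(unique(dat$height[dat$height >= 0.1]))

  # per participant x height mean lead step-height difference (holo - real)
  diff_mat <- matrix(NA_real_, length(participants), length(heights3d),
                     dimnames = list(participants, heights3d))
  coll_frac <- stats::setNames(numeric(length(participants)), participants)
  for (p in participants) {
    sub <- dat[dat$participant == p, ]
    holo3d <- sub[sub$obstacle_type == "holographic" & sub$height >= 0.1, ]
    colls <- c(holo3d$trail_coll_h1, holo3d$trail_coll_h2)
    colls <- colls[!is.na(colls)]
    coll_frac[p] <- if (length(colls)) mean(colls) else NA_real_
    for (h in heights3d) {
      hs <- sub[abs(sub$height - h) < 1e-9, ]
      mh <- mean(hs$lead_step[hs$obstacle_type == "holographic"], na.rm = TRUE)
      mr <- mean(hs$lead_step[hs$obstacle_type == "real"], na.rm = TRUE)
      diff_mat[as.character(p), as.character(h)] <- mh - mr
    }
  }
  n <- length(participants)
  above <- matrix(FALSE, n, ncol(diff_mat), dimnames = dimnames(diff_mat))
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(diff_mat))) {
      d_i <- diff_mat[i, j]
      d_rest <- diff_mat[-i, j]
      d_rest <- d_rest[!is.na(d_rest)]
      if (is.na(d_i) || length(d_rest) < 2) next
      m <- length(d_rest)
      bound <- stats::median(d_rest) +
        stats::qt(0.975, m - 1) * stats::mad(d_rest) * sqrt(1 + 1 / m)
      above[i, j] <- d_i > bound
    }
  }
  n_above <- rowSums(above)

  label <- ifelse(!is.na(coll_frac) & coll_frac >= collision_fraction,
                  "no_trail_raise",
                  ifelse(n_above >= min_heights, "extreme_lead", "similar"))
  data.frame(participant = participants, label = unname(label),
             trail_coll_frac = unname(coll_frac),
             n_heights_above = unname(n_above),
             stringsAsFactors = FALSE)
}
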