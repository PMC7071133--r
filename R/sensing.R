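# Pre-processing: body point clouds -> per-foot clouds -> per-frame
# heel-to-toe lower edges, with multi-sensor fallback and left/right label
# correction.

#' Split a body point cloud into left and right foot clouds
#'
#' Skeleton-guided capture: a point belongs to a foot if it lies within
#' `radius` of the segment from that side's ankle point to its foot-tip
#' point; points near both feet are assigned to the nearer segment.
#'
#' @param points matrix/data.frame of world points (columns x, y, z).
#' @param skeleton_frame data.frame of one skeleton frame with columns
#'   `point`, `x`, `y`, `z` containing `AnkleLeft`, `FootLeft`,
#'   `AnkleRight`, `FootRight`.
#' @param radius capture radius around the ankle-to-foot-tip segment (m).
#' @return list with `left` and `right` point matrices (possibly 0-row) and
#'   `labels` noting sides marked `"unknown"` (no captured points).
#' @export
extract_foot_clouds <- function(points, skeleton_frame, radius = 0.20) {
  need <- c("AnkleLeft", "FootLeft", "AnkleRight", "FootRight")
  sk <- skeleton_frame[match(need, skeleton_frame$point), c("x", "y", "z")]
  if (anyNA(sk))
    stop("skeleton frame is missing ankle/foot points; frame marked missing")
  pts <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  if (!nrow(pts))
    return(list(left = pts, right = pts,
                labels = c(left = "unknown", right = "unknown")))
  d_left <- point_segment_distance(pts, unlist(sk[1, ]), unlist(sk[2, ]))
  d_right <- point_segment_distance(pts, unlist(sk[3, ]), unlist(sk[4, ]))
  in_left <- d_left <= radius
  in_right <- d_right <= radius
  both <- in_left & in_right
  in_left[both] <- d_left[both] <= d_right[both]
  in_right[both] <- !in_left[both]
  labels <- c(left = if (any(in_left)) "left" else "unknown",
              right = if (any(in_right)) "right" else "unknown")
  list(left = pts[in_left, , drop = FALSE],
       right = pts[in_right, , drop = FALSE],
       labels = labels)
}

# Distance from each row of `pts` to the segment a-b.
point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(pts, 2, a)
  t <- if (len2 < 1e-12) rep(0, nrow(pts)) else
    pmin(1, pmax(0, as.numeric(rel %*% ab) / len2))
  proj <- outer(t, ab)
  sqrt(rowSums((rel - proj)^2))
}

#' Lower edge of a foot point cloud
#'
#' Partitions the cloud by along-path position into bins of `bin_width` and
#' emits, per occupied bin, the bin-centre x and the minimum vertical value:
#' the heel-to-toe profile of lowest points. Output is ordered by x.
#'
#' @param points matrix/data.frame of foot points (columns x, z at least).
#' @param bin_width along-path bin width (m).
#' @return data.frame with columns `x`, `z`, ordered by `x`; attribute
#'   `low_support` is TRUE when the cloud spans fewer than two bins.
#' @export
foot_lower_edge <- function(points, bin_width = 0.01) {
  pts <- as.data.frame(points)
  stopifnot(nrow(pts) > 0, all(c("x", "z") %in% names(pts)))
  bin <- floor(pts$x / bin_width)
  z_min <- tapply(pts$z, bin, min)
  ubin <- as.numeric(names(z_min))
  edge <- data.frame(x = (ubin + 0.5) * bin_width, z = as.numeric(z_min))
  edge <- edge[order(edge$x), ]
  rownames(edge) <- NULL
  attr(edge, "low_support") <- nrow(edge) < 2
  edge
}

#' Fuse per-sensor foot-cloud streams into labelled lower-edge series
#'
#' Per frame and foot, uses the primary sensor's cloud if its lower part is
#' visible (at least `min_points` points within 0.10 m of the cloud's lowest
#' point); otherwise substitutes the next sensor in priority order,
#' preferring `occlusion_sensor` while the foot's along-path position lies
#' inside `occlusion_window` (the region hidden behind the obstacle for the
#' frontal sensor). Left/right labels are then corrected by centroid
#' continuity: per frame the assignment (keep or swap) minimising the summed
#' centroid displacement from the previous labelled frame is chosen; when
#' the two assignments differ by less than `ambiguity` metres the frame's
#' labels are marked unknown and the frame becomes missing.
#'
#' @param streams named list of sensor streams; each stream is a data.frame
#'   with columns `frame`, `time`, `foot` ("left"/"right"), `x`, `y`, `z`.
#' @param priority character vector of sensor names, primary first.
#' @param occlusion_window x-interval `c(lo, hi)` occluded for the primary
#'   sensor.
#' @param occlusion_sensor sensor preferred inside the occlusion window;
#'   defaults to the second sensor in `priority`.
#' @param min_points minimum visible lower-part point count.
#' @param ambiguity label-correction deadband (m).
#' @param bin_width lower-edge bin width (m).
#' @return list with `left` and `right` [lower_edge_series()] and a `report`
#'   data.frame (frame, foot, source sensor, substituted, labels_swapped,
#'   missing).
#' @export
fuse_streams <- function(streams, priority = names(streams),
                         occlusion_window = c(1.15, 1.25),
                         occlusion_sensor = if (length(priority) > 1) priority[2] else priority[1],
                         min_points = 20, ambiguity = 0.02,
                         bin_width = 0.01) {
  stopifnot(length(streams) >= 1, all(priority %in% names(streams)))
  frames <- sort(unique(unlist(lapply(streams, function(s) s$frame))))
  times <- rep(NA_real_, length(frames))
  pick <- function(stream, f, foot) {
    s <- stream[stream$frame == f & stream$foot == foot, , drop = FALSE]
    if (!nrow(s)) NULL else s
  }
  lower_visible <- function(cloud) {
    !is.null(cloud) && sum(cloud$z <= min(cloud$z) + 0.10) >= min_points
  }

  chosen <- list(left = vector("list", length(frames)),
                 right = vector("list", length(frames)))
  report <- vector("list", length(frames))
  prev_centroid <- NULL
  for (i in seq_along(frames)) {
    f <- frames[i]
    sel <- list(); src <- c(left = NA_character_, right = NA_character_)
    for (foot in c("left", "right")) {
      cand <- pick(streams[[priority[1]]], f, foot)
      source <- priority[1]
      if (!lower_visible(cand)) {
        # in the occlusion window, prefer the designated side sensor
        cx <- if (!is.null(cand)) stats::median(cand$x) else
          centroid_x_any(streams, f, foot)
        order_try <- priority[-1]
        if (!is.na(cx) && cx >= occlusion_window[1] && cx <= occlusion_window[2])
          order_try <- unique(c(occlusion_sensor, order_try))
        cand <- NULL
        for (s in order_try) {
          alt <- pick(streams[[s]], f, foot)
          if (lower_visible(alt)) { cand <- alt; source <- s; break }
        }
        if (is.null(cand)) source <- NA_character_
      }
      sel[[foot]] <- cand
      src[foot] <- source
    }
    if (!is.null(sel$left)) times[i] <- sel$left$time[1]
    else if (!is.null(sel$right)) times[i] <- sel$right$time[1]

    # label correction by centroid continuity
    swapped <- FALSE; unknown <- FALSE
    if (!is.null(sel$left) && !is.null(sel$right) && !is.null(prev_centroid)) {
      cl <- colMeans(sel$left[, c("x", "y", "z")])
      cr <- colMeans(sel$right[, c("x", "y", "z")])
      cost_keep <- sqrt(sum((cl - prev_centroid$left)^2)) +
        sqrt(sum((cr - prev_centroid$right)^2))
      cost_swap <- sqrt(sum((cl - prev_centroid$right)^2)) +
        sqrt(sum((cr - prev_centroid$left)^2))
      if (abs(cost_keep - cost_swap) < ambiguity) {
        unknown <- TRUE
        sel$left <- NULL; sel$right <- NULL
        src[] <- NA_character_
      } else if (cost_swap < cost_keep) {
        swapped <- TRUE
        tmp <- sel$left; sel$left <- sel$right; sel$right <- tmp
        src <- src[c("right", "left")]; names(src) <- c("left", "right")
      }
    }
    if (xor(is.null(sel$left), is.null(sel$right)) && !is.null(prev_centroid)) {
      # single visible foot: relabel to the nearer previous centroid
      present <- if (!is.null(sel$left)) "left" else "right"
      cen <- colMeans(sel[[present]][, c("x", "y", "z")])
      dl <- sqrt(sum((cen - prev_centroid$left)^2))
      dr <- sqrt(sum((cen - prev_centroid$right)^2))
      if (abs(dl - dr) < ambiguity) {
        unknown <- TRUE
        sel[present] <- list(NULL)
        src[] <- NA_character_
      } else {
        correct <- if (dl < dr) "left" else "right"
        if (correct != present) {
          swapped <- TRUE
          sel[[correct]] <- sel[[present]]
          sel[present] <- list(NULL)
          src[correct] <- src[present]
          src[present] <- NA_character_
          prev_centroid[[correct]] <- cen
        } else {
          prev_centroid[[correct]] <- cen
        }
      }
    } else if (!is.null(sel$left) && !is.null(sel$right)) {
      prev_centroid <- list(left = colMeans(sel$left[, c("x", "y", "z")]),
                            right = colMeans(sel$right[, c("x", "y", "z")]))
    }
    chosen$left[i] <- list(sel$left)
    chosen$right[i] <- list(sel$right)
    report[[i]] <- data.frame(
      frame = f, foot = c("left", "right"), source = unname(src),
      substituted = !is.na(src) & src != priority[1],
      labels_swapped = swapped, labels_unknown = unknown,
      missing = c(is.null(sel$left), is.null(sel$right)))
  }
  report <- do.call(rbind, report)

  edge_series <- function(side) {
    edges <- lapply(chosen[[side]], function(cl) {
      if (is.null(cl)) NULL else foot_lower_edge(cl, bin_width)
    })
    lower_edge_series(edges, times, side)
  }
  list(left = edge_series("left"), right = edge_series("right"),
       report = report)
}

centroid_x_any <- function(streams, f, foot) {
  for (s in streams) {
    sub <- s[s$frame == f & s$foot == foot, , drop = FALSE]
    if (nrow(sub)) return(stats::median(sub$x))
  }
  NA_real_
}

#' Per-frame lower-edge series of one foot
#'
#' Container for the heel-to-toe lower boundary of one foot over time.
#' Missing frames are kept as explicit NULL entries, never dropped.
#'
#' @param edges list of per-frame edge data.frames (columns `x`, `z`,
#'   x strictly increasing) or NULL for missing frames.
#' @param times frame times (s).
#' @param foot `"left"`, `"right"` or a role label.
#' @return a `lower_edge_series` object.
#' @export
lower_edge_series <- function(edges, times, foot = "unknown") {
  stopifnot(length(edges) == length(times))
  for (e in edges) {
    if (is.null(e)) next
    stopifnot(all(c("x", "z") %in% names(e)))
    if (nrow(e) > 1 && any(diff(e$x) <= 0))
      stop("edge x values must be strictly increasing within a frame")
  }
  structure(list(edges = edges, times = as.numeric(times), foot = foot),
            class = "lower_edge_series")
}

#' @export
print.lower_edge_series <- function(x, ...) {
  n_missing <- sum(vapply(x$edges, is.null, logical(1)))
  cat(sprintf("<lower_edge_series> foot %s, %d frames (%d missing)\n",
              x$foot, length(x$edges), n_missing))
  invisible(x)
}

#' Lower-edge series of a simulated trial bundle
#'
#' Convenience single-sensor path from a `trial_bundle`'s labelled cloud
#' stream to left/right lower-edge series, including centroid-continuity
#' label correction (the generator may plant label swaps).
#'
#' @param bundle a `trial_bundle`.
#' @param bin_width lower-edge bin width (m).
#' @param correct_labels apply centroid-continuity label correction.
#' @return list with `left`, `right` series and the fusion `report`.
#' @export
bundle_edges <- function(bundle, bin_width = 0.01, correct_labels = TRUE) {
  streams <- list(main = bundle$clouds)
  fuse_streams(streams, priority = "main",
               min_points = if (correct_labels) 20 else 1,
               bin_width = bin_width)
}
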