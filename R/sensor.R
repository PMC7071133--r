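# Pinhole depth-sensor model and depth-image handling. Depth images are
# integer matrices in millimetres (rows = image rows v, cols = columns u),
# 0 marking invalid pixels, as produced by time-of-flight RGB-D sensors.

#' Depth-sensor model
#'
#' Pinhole intrinsics plus a rigid camera-to-world pose
#' (`world = R %*% camera + t`). The camera frame follows the usual computer
#' vision convention: `+z` along the optical axis, `+x` right in the image,
#' `+y` down.
#'
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point in pixels.
#' @param width,height image size in pixels.
#' @param rotation 3x3 rotation matrix (columns = camera axes in world
#'   coordinates); must be a proper rotation (determinant +1).
#' @param translation camera position in world coordinates (m).
#' @param depth_noise_sd depth noise standard deviation in millimetres.
#' @param background background depth map (height x width matrix, mm);
#'   defaults to a constant far plane.
#' @param background_depth_mm far-plane depth used when `background` is NULL.
#' @param id sensor identifier.
#' @return a `sensor_model` list.
#' @export
sensor_model <- function(fx = 365, fy = 365, cx = 255.5, cy = 211.5,
                         width = 512, height = 424,
                         rotation = diag(3), translation = c(0, 0, 0),
                         depth_noise_sd = 0, background = NULL,
                         background_depth_mm = 8000, id = "sensor1") {
  stopifnot(fx > 0, fy > 0, width >= 1, height >= 1,
            is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be a proper rigid rotation (det = +1)")
  if (is.null(background))
    background <- matrix(as.integer(background_depth_mm), height, width)
  stopifnot(all(dim(background) == c(height, width)))
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height),
                 rotation = rotation, translation = as.numeric(translation),
                 depth_noise_sd = depth_noise_sd, background = background,
                 id = id),
            class = "sensor_model")
}

#' A sensor posed at the side of the walking path
#'
#' Convenience pose: camera at `(x, y, z)` looking along `-y` (from the
#' right-hand side of the path towards it) with the image x axis along the
#' walking direction.
#'
#' @param x,y,z camera position in world coordinates (m).
#' @param ... passed to [sensor_model()].
#' @return a `sensor_model`.
#' @export
side_sensor <- function(x = 1.1, y = -2.5, z = 0.6, ...) {
  # camera axes in world coords: x_cam = +x (path), y_cam = -z (down),
  # z_cam = +y (towards the path); det = +1
  rot <- cbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  sensor_model(rotation = rot, translation = c(x, y, z), ...)
}

# world -> camera coordinates
world_to_camera <- function(points, sensor) {
  sweep(points, 2, sensor$translation) %*% sensor$rotation
}

# camera -> world coordinates
camera_to_world <- function(points, sensor) {
  sweep(points %*% t(sensor$rotation), 2, sensor$translation, `+`)
}

#' Render a trial bundle into a depth-frame sequence
#'
#' Projects the bundle's cloud and skeleton points through the sensor's
#' pinhole model onto the background depth map, keeping the nearest surface
#' per pixel. Depth values are rounded to integer millimetres (16-bit
#' range). Points behind the camera (or closer than 5 cm) are skipped and
#' counted in the render report.
#'
#' @param bundle a `trial_bundle`.
#' @param sensor a [sensor_model()].
#' @param seed seed for depth noise (used only if `depth_noise_sd > 0`).
#' @return list of depth frames (integer matrices, mm) with attributes
#'   `times` and `report` (per-frame skipped-point counts).
#' @export
render_depth_sequence <- function(bundle, sensor, seed = 1) {
  n_frames <- length(bundle$times)
  frames <- vector("list", n_frames)
  skipped <- integer(n_frames)
  for (f in seq_len(n_frames)) {
    pts <- as.matrix(bundle$clouds[bundle$clouds$frame == f, c("x", "y", "z")])
    sk <- bundle$skeleton[bundle$skeleton$frame == f, c("x", "y", "z")]
    pts <- rbind(pts, as.matrix(sk))
    rendered <- render_points(pts, sensor)
    frames[[f]] <- rendered$depth
    skipped[f] <- rendered$skipped
  }
  if (sensor$depth_noise_sd > 0) {
    frames <- with_seed(seed, lapply(frames, function(d) {
      fg <- d != sensor$background & d > 0
      d[fg] <- pmax(1L, as.integer(round(
        d[fg] + stats::rnorm(sum(fg), 0, sensor$depth_noise_sd))))
      d
    }))
  }
  structure(frames, times = bundle$times,
            report = data.frame(frame = seq_len(n_frames), skipped = skipped))
}

#' Render a set of world points into one depth frame
#'
#' @param points matrix of world points (n x 3, metres); may be empty.
#' @param sensor a [sensor_model()].
#' @return list with `depth` (integer matrix, mm) and `skipped` (points
#'   behind the camera).
#' @export
render_points <- function(points, sensor) {
  depth <- sensor$background
  skipped <- 0L
  if (length(points) && nrow(points)) {
    cam <- world_to_camera(points, sensor)
    behind <- cam[, 3] < 0.05
    skipped <- sum(behind)
    cam <- cam[!behind, , drop = FALSE]
    if (nrow(cam)) {
      u <- round(sensor$fx * cam[, 1] / cam[, 3] + sensor$cx)
      v <- round(sensor$fy * cam[, 2] / cam[, 3] + sensor$cy)
      z_mm <- pmax(1L, as.integer(round(cam[, 3] * 1000)))
      ok <- u >= 0 & u < sensor$width & v >= 0 & v < sensor$height
      u <- u[ok]; v <- v[ok]; z_mm <- z_mm[ok]
      if (length(u)) {
        idx <- v + 1 + u * sensor$height  # column-major [v+1, u+1]
        ord <- order(z_mm, decreasing = TRUE)  # nearest written last
        depth[idx[ord]] <- z_mm[ord]
      }
    }
  }
  list(depth = depth, skipped = skipped)
}

#' Back-project a depth frame to world 3D points
#'
#' Inverts the pinhole projection: pixel `(u, v)` with depth `Z` maps to
#' camera coordinates `((u - cx) Z / fx, (v - cy) Z / fy, Z)` and then
#' through the rigid pose to world coordinates. Invalid pixels (depth 0)
#' and pixels within `background_tol_mm` of the sensor's background model
#' are discarded before mapping.
#'
#' @param frame integer depth matrix (mm), dimensions matching the sensor.
#' @param sensor a [sensor_model()].
#' @param background_tol_mm background-subtraction threshold (mm).
#' @return matrix of world points (n x 3, metres) with columns x, y, z.
#' @export
depth_to_points <- function(frame, sensor, background_tol_mm = 50) {
  if (!all(dim(frame) == c(sensor$height, sensor$width)))
    stop(sprintf("depth frame is %dx%d but sensor expects %dx%d",
                 nrow(frame), ncol(frame), sensor$height, sensor$width))
  fg <- frame > 0 & abs(frame - sensor$background) > background_tol_mm
  if (!any(fg)) return(matrix(numeric(0), 0, 3,
                              dimnames = list(NULL, c("x", "y", "z"))))
  idx <- which(fg)
  v <- (idx - 1) %% sensor$height      # row - 1
  u <- (idx - 1) %/% sensor$height     # col - 1
  Z <- frame[idx] / 1000
  cam <- cbind((u - sensor$cx) * Z / sensor$fx,
               (v - sensor$cy) * Z / sensor$fy,
               Z)
  pts <- camera_to_world(cam, sensor)
  colnames(pts) <- c("x", "y", "z")
  pts
}
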