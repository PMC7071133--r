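# Foot extraction, lower edges, stream fusion and label correction.

test_that("foot clouds are split by ankle-segment proximity", {
  b <- quiet_trial(seed = 6)
  f <- 40
  pts <- b$clouds[b$clouds$frame == f, c("x", "y", "z")]
  truth <- b$clouds$foot[b$clouds$frame == f]
  sk <- b$skeleton[b$skeleton$frame == f, ]
  fc <- extract_foot_clouds(pts, sk)
  expect_equal(nrow(fc$left) + nrow(fc$right), nrow(pts))
  expect_equal(nrow(fc$left), sum(truth == "left"))
  # zero cross-assignments: all left points have the left y sign
  expect_true(all(fc$left[, "y"] > 0))
  expect_true(all(fc$right[, "y"] < 0))
})

test_that("points near both feet go to the nearer segment", {
  sk <- data.frame(point = c("AnkleLeft", "FootLeft", "AnkleRight", "FootRight"),
                   x = c(1.0, 1.1, 1.0, 1.1),
                   y = c(0.05, 0.05, -0.05, -0.05),
                   z = c(0.1, 0.05, 0.1, 0.05))
  pts <- rbind(c(1.05, 0.01, 0.05),   # nearer left
               c(1.05, -0.01, 0.05))  # nearer right
  colnames(pts) <- c("x", "y", "z")
  fc <- extract_foot_clouds(pts, sk)
  expect_equal(nrow(fc$left), 1)
  expect_equal(nrow(fc$right), 1)
  expect_gt(fc$left[1, "y"], 0)
})

test_that("clouds far from both ankles leave both feet unknown", {
  sk <- data.frame(point = c("AnkleLeft", "FootLeft", "AnkleRight", "FootRight"),
                   x = 0, y = c(0.1, 0.1, -0.1, -0.1), z = 0.1)
  pts <- matrix(c(5, 0, 0), 1, dimnames = list(NULL, c("x", "y", "z")))
  fc <- extract_foot_clouds(pts, sk)
  expect_equal(unname(fc$labels), c("unknown", "unknown"))
  sk_missing <- sk[-1, ]
  expect_error(extract_foot_clouds(pts, sk_missing), "missing ankle")
})

test_that("lower edges are per-bin minima ordered by x", {
  # flat sole at z = 0.1 spanning [1.0, 1.25], one point per cm bin
  x <- (100:124 + 0.5) / 100
  edge <- foot_lower_edge(data.frame(x = x, z = 0.1))
  expect_equal(nrow(edge), 25)
  expect_true(all(edge$z == 0.1))
  expect_true(all(diff(edge$x) > 0))

  # pitched sole: edge z linear in the reported x within 1e-9
  zs <- 0.05 + 0.17 * x  # 10ish degrees
  edge2 <- foot_lower_edge(data.frame(x = x, z = zs))
  fit <- lm(z ~ x, data = edge2)
  expect_lt(max(abs(residuals(fit))), 1e-9)

  # a single outlier only affects its own bin
  out <- rbind(data.frame(x = x, z = 0.1),
               data.frame(x = 1.105, z = 0.05))
  edge3 <- foot_lower_edge(out)
  expect_equal(sum(edge3$z < 0.1), 1)
  expect_equal(edge3$z[abs(edge3$x - 1.105) < 0.005], 0.05)

  expect_true(attr(foot_lower_edge(data.frame(x = 1.001, z = 0)), "low_support"))
})

test_that("edge series reject unordered frames and keep missing markers", {
  bad <- data.frame(x = c(1.2, 1.1), z = c(0, 0))
  expect_error(lower_edge_series(list(bad), times = 0), "strictly increasing")
  s <- lower_edge_series(list(pt_frame(1, 0), NULL, pt_frame(1.1, 0)),
                         times = c(0, 1, 2) / 30)
  expect_length(s$edges, 3)
  expect_null(s$edges[[2]])
})

test_that("fusion falls back to the primary sensor identity when visible", {
  b <- quiet_trial(seed = 8)
  fused <- fuse_streams(list(main = b$clouds), priority = "main")
  direct <- lapply(split(b$clouds[b$clouds$foot == "left", ],
                         b$clouds$frame[b$clouds$foot == "left"]),
                   foot_lower_edge)
  got <- Filter(Negate(is.null), fused$left$edges)
  expect_equal(length(got), length(direct))
  expect_equal(got[[10]], direct[[10]], ignore_attr = TRUE)
  expect_true(all(fused$report$source == "main", na.rm = TRUE))
  expect_false(any(fused$report$substituted, na.rm = TRUE))
})

test_that("occluded primary frames are substituted from the side sensor", {
  b <- quiet_trial(seed = 9)
  truth <- b$clouds
  # primary loses every frame where the left foot is over the occlusion window
  occl <- c(1.15, 1.25)
  cx <- tapply(truth$x[truth$foot == "left"], truth$frame[truth$foot == "left"],
               median)
  blank <- as.integer(names(cx))[cx >= occl[1] & cx <= occl[2]]
  primary <- truth[!(truth$foot == "left" & truth$frame %in% blank), ]
  fused <- fuse_streams(list(front = primary, side = truth),
                        priority = c("front", "side"),
                        occlusion_window = occl)
  rep_left <- fused$report[fused$report$foot == "left", ]
  expect_setequal(rep_left$frame[rep_left$substituted %in% TRUE], blank)
  expect_true(all(rep_left$source[rep_left$frame %in% blank] == "side"))
  # no frames invented: all output frames exist in the inputs
  expect_true(all(rep_left$frame %in% truth$frame))
  expect_false(any(vapply(fused$left$edges[blank], is.null, logical(1))))
})

test_that("centroid continuity restores planted label swaps", {
  n_frames_ok <- 0; n_frames <- 0
  for (seed in 1:8) {
    b <- simulate_trial(obstacle_spec("holographic", 0.2, 0.02),
                        behavior_profile("similar"),
                        noise = list(point_sd = 0.005, dropout_prob = 0.02,
                                     label_swap_prob = 0.02), seed = seed)
    truth <- true_labeled_clouds(b)
    fused <- fuse_streams(list(main = b$clouds), priority = "main")
    for (f in seq_along(fused$left$edges)) {
      e <- fused$left$edges[[f]]
      if (is.null(e)) next
      tl <- truth[truth$frame == f & truth$foot == "left", ]
      tr <- truth[truth$frame == f & truth$foot == "right", ]
      if (!nrow(tl) || !nrow(tr)) next
      n_frames <- n_frames + 1
      d_left <- abs(mean(e$x) - median(tl$x))
      d_right <- abs(mean(e$x) - median(tr$x))
      if (d_left <= d_right) n_frames_ok <- n_frames_ok + 1
    }
  }
  expect_gt(n_frames, 400)
  expect_gte(n_frames_ok / n_frames, 0.99)
})

test_that("depth round trip reproduces the analytic lower edge", {
  b <- quiet_trial(seed = 12)
  s <- side_sensor(x = 1.1, y = -2.0, z = 0.5, fx = 500, fy = 500)
  frames <- render_depth_sequence(b, s)
  f <- which.min(abs(vapply(seq_along(b$times), function(i) {
    cl <- b$clouds[b$clouds$frame == i & b$clouds$foot ==
                     b$ground_truth$lead_side, ]
    median(cl$x)
  }, numeric(1)) - 1.2))  # lead foot over the hurdle
  pts <- depth_to_points(frames[[f]], s)
  sk <- b$skeleton[b$skeleton$frame == f, ]
  fc <- extract_foot_clouds(pts, sk)
  lead <- if (b$ground_truth$lead_side == "left") fc$left else fc$right
  edge <- foot_lower_edge(lead)
  planted <- b$ground_truth$lead$crossing_height[1]
  # the foot is on its plateau: the edge must sit at the planted height
  # within rendering quantization (pixel + 1 mm depth rounding)
  expect_lt(abs(min(edge$z) - planted), 0.02)
  expect_lt(abs(median(edge$z) - planted), 0.02)
})
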