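# Shared fixtures and independent oracles.

noise_off <- list(point_sd = 0, dropout_prob = 0, label_swap_prob = 0)
noise_default <- list(point_sd = 0.005, dropout_prob = 0.02,
                      label_swap_prob = 0.02)

quiet_trial <- function(spec = obstacle_spec("holographic", 0.3, 0.02),
                        profile = behavior_profile("similar"), seed = 1, ...) {
  simulate_trial(spec, profile, noise = noise_off, seed = seed, ...)
}

# Dense-time brute-force crossing-height oracle: re-simulate the trial
# noise-free at a high frame rate and take the minimum vertical value of any
# cloud point while within `tol` of the hurdle position. Independent of the
# lower-edge / 30-part / interpolation pipeline.
dense_crossing_oracle <- function(spec, profile, seed, hurdle_x, side,
                                  fps = 300, tol = 0.003, ...) {
  b <- simulate_trial(spec, profile, noise = noise_off, seed = seed,
                      fps = fps, ...)
  pts <- b$clouds[b$clouds$foot == side, ]
  near <- abs(pts$x - hurdle_x) <= tol
  stopifnot(any(near))
  min(pts$z[near])
}

# Build a lower_edge_series from a list of data.frame(x, z) frames at 30 Hz.
edges_series <- function(frames, foot = "left") {
  lower_edge_series(frames, times = (seq_along(frames) - 1) / 30, foot = foot)
}

# Single-point edge frame helper.
pt_frame <- function(x, z) data.frame(x = x, z = z)

# Restore the generator's true foot labels of a bundle cloud stream
# (label swapping is an involution on the planted swap frames).
true_labeled_clouds <- function(bundle) {
  cl <- bundle$clouds
  sel <- cl$frame %in% bundle$swapped_frames
  cl$foot[sel] <- ifelse(cl$foot[sel] == "left", "right", "left")
  cl
}
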