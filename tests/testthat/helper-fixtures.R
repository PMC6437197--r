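# Shared helpers for building small in-memory fixtures.

# A single frame-annotation row from raw point coordinates.
make_frame <- function(frame, unit, A, B, C, D, E, G) {
  frame_annotation(frame, unit, A, B, C, D, E, G)
}

# Apply one similarity transform (rotation rad, uniform scale, translation)
# to every point of a frame table -- used to probe ratio invariance.
transform_frames <- function(frames, rot = 0, scl = 1, tx = 0, ty = 0) {
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  for (pt in c("A", "B", "C", "D", "E", "G")) {
    xy <- as.matrix(frames[, paste0(pt, c("x", "y"))])
    out <- scl * (xy %*% t(R))
    frames[[paste0(pt, "x")]] <- out[, 1] + tx
    frames[[paste0(pt, "y")]] <- out[, 2] + ty
  }
  frames
}

# Independent closed-form OLS slope: sum((x-xbar)(y-ybar)) / sum((x-xbar)^2).
closed_form_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Reconstruct-and-fit shortcut used by recovery checks.
recover_stiffness <- function(meas, threshold = 80) {
  cal <- default_calibration(meas$frames$unit[1])
  rec <- reconstruct_curve(cal, meas$frames)
  fit_stiffness(select_linear_region(rec, threshold), force_threshold = threshold)
}
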