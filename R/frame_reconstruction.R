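# Per-frame scale geometry and curve assembly.
#
# Each analysed video frame carries six digitized points per measuring unit:
# A, B, C on the joint-force scale (start, reference endpoint, pointer) and
# D, E, G on the extension-gap scale (reference start, reference end, gap
# pointer). Coordinates are continuous pixels, origin at the image's
# bottom-left corner, y increasing upward. All derived quantities are ratios
# of Euclidean lengths, which cancels camera magnification and in-plane tilt
# frame by frame.

FRAME_CSV_HEADER <- c("frame", "unit",
                      "Ax", "Ay", "Bx", "By", "Cx", "Cy",
                      "Dx", "Dy", "Ex", "Ey", "Gx", "Gy")

#' Relativity factor of the force-scale pointer
#'
#' The relativity factor m is the proportion of the pointer distance AC to the
#' scale reference distance AB. It is a pure length ratio, so any similarity
#' transform of the image (rotation, uniform zoom, translation) leaves it
#' unchanged.
#'
#' @param A,B,C Numeric length-2 vectors `c(x, y)` in pixels: scale start,
#'   scale reference endpoint, pointer.
#' @return Dimensionless m = |AC| / |AB|, always >= 0.
#' @export
relativity_factor <- function(A, B, C) {
  ab <- point_distance(A, B)
  if (!is.finite(ab) || ab <= 0) {
    abort_ls("degenerate force scale: |AB| must be > 0", "ligastiff_degenerate_scale")
  }
  point_distance(A, C) / ab
}

# Vectorized pointer-position -> force map shared by the scalar operation and
# curve assembly. Linear interpolation between the bench forces at A and B,
# linearly extrapolated above B up to `extrapolation_bound` (in vivo pulls
# reach 170 N, beyond F_B on both units).
force_from_m <- function(cal, m, extrapolation_bound = 1.6, warn = FALSE) {
  if (any(m < 0)) abort_ls("relativity factor m must be non-negative", "ligastiff_invalid_input")
  if (any(m > extrapolation_bound)) {
    abort_ls(sprintf("relativity factor %.3f beyond extrapolation bound %.2f",
                     max(m), extrapolation_bound), "ligastiff_out_of_range")
  }
  if (warn && any(m > 1)) {
    warning(sprintf("pointer beyond scale endpoint B (m = %.3f); force linearly extrapolated",
                    max(m)), call. = FALSE)
  }
  cal$force_at_A + m * (cal$force_at_B - cal$force_at_A)
}

#' Force from the relativity factor
#'
#' Linear interpolation between the calibrated endpoint forces:
#' F_C = F_A + m (F_B - F_A). Values of m above 1 (pointer past endpoint B)
#' are linearly extrapolated with a warning, up to `extrapolation_bound`.
#'
#' @param cal A [measuring_unit_calibration()] object.
#' @param m Relativity factor, >= 0.
#' @param extrapolation_bound Largest admissible m. The default 1.6
#'   corresponds to roughly the 170 N maximum applied in vivo on the softer
#'   (right) unit: (170 - 18.1) / (116.9 - 18.1) ~ 1.54.
#' @return Force in N, strictly increasing in m.
#' @export
force_from_relativity <- function(cal, m, extrapolation_bound = 1.6) {
  stopifnot(inherits(cal, "balancer_calibration"))
  if (!is.numeric(m) || anyNA(m)) abort_ls("m must be numeric", "ligastiff_invalid_input")
  force_from_m(cal, m, extrapolation_bound, warn = TRUE)
}

#' Perspective-corrected extension-gap reading
#'
#' The reference segment DE spans 20 mm on the physical gap scale; dividing
#' the pixel distance EG by the pixel distance DE converts the gap pointer
#' position to millimetres and cancels per-frame magnification and tilt.
#'
#' @param D,E,G Numeric length-2 vectors `c(x, y)` in pixels: reference start,
#'   reference end, gap pointer.
#' @return Gap reading EG_real in mm: 20 * |EG| / |DE|.
#' @export
gap_length_real <- function(D, E, G) {
  de <- point_distance(D, E)
  if (!is.finite(de) || de <= 0) {
    abort_ls("degenerate gap scale: |DE| must be > 0", "ligastiff_degenerate_scale")
  }
  20 * point_distance(E, G) / de
}

#' Assemble a frame-annotation table
#'
#' @param frame_index Non-negative integer frame numbers.
#' @param unit_id `"left"` or `"right"`, recycled.
#' @param A,B,C,D,E,G Two-column matrices (or length-2 vectors for a single
#'   frame) of pixel coordinates.
#' @return A `data.frame` in the frame-annotation dialect with columns
#'   `frame, unit, Ax, Ay, ..., Gx, Gy`.
#' @export
frame_annotation <- function(frame_index, unit_id, A, B, C, D, E, G) {
  as_mat <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 2, byrow = TRUE)
    p
  }
  A <- as_mat(A); B <- as_mat(B); C <- as_mat(C)
  D <- as_mat(D); E <- as_mat(E); G <- as_mat(G)
  df <- data.frame(
    frame = as.integer(frame_index),
    unit = match.arg(unit_id, c("left", "right")),
    Ax = A[, 1], Ay = A[, 2], Bx = B[, 1], By = B[, 2], Cx = C[, 1], Cy = C[, 2],
    Dx = D[, 1], Dy = D[, 2], Ex = E[, 1], Ey = E[, 2], Gx = G[, 1], Gy = G[, 2]
  )
  validate_frames(df)
}

validate_frames <- function(frames) {
  if (!is.data.frame(frames) || !all(FRAME_CSV_HEADER %in% names(frames))) {
    abort_ls(sprintf("frame table must have columns: %s",
                     paste(FRAME_CSV_HEADER, collapse = ",")), "ligastiff_io_error")
  }
  coords <- as.matrix(frames[, FRAME_CSV_HEADER[-(1:2)]])
  if (!is.numeric(coords) || any(!is.finite(coords))) {
    abort_ls("frame coordinates must be finite numbers", "ligastiff_invalid_input")
  }
  if (!all(frames$unit %in% c("left", "right"))) {
    abort_ls("unit column must be 'left' or 'right'", "ligastiff_invalid_input")
  }
  frames <- frames[, FRAME_CSV_HEADER]
  rownames(frames) <- NULL
  frames
}

#' Reconstruct a force-displacement curve from frame annotations
#'
#' For every frame the relativity factor m maps the force pointer to a force
#' in N, and the gap pointer is converted to millimetres via the 20 mm DE
#' reference. Displacement is the drop of the gap reading relative to frame 1:
#' p_i = EG_real(frame 1) - EG_real(frame i), so the first sample has p = 0
#' exactly and extension of the ligament complex gives positive p. Negative
#' displacements are kept (not clamped) so that orientation mistakes in the
#' annotations stay visible; their count is attached as the
#' `n_negative_displacement` attribute.
#'
#' @param cal A [measuring_unit_calibration()] matching the frames' unit.
#' @param frames Frame-annotation `data.frame` (see [frame_annotation()] or
#'   [read_frame_csv()]), at least two rows, strictly increasing `frame`,
#'   single `unit`.
#' @param extrapolation_bound Passed to the force map; see
#'   [force_from_relativity()].
#' @return A `data.frame` of class `fd_curve` with columns
#'   `frame, m, force_N, gap_mm, displacement_mm`, attributes `unit_id`,
#'   `n_extrapolated`, `n_negative_displacement`.
#' @export
reconstruct_curve <- function(cal, frames, extrapolation_bound = 1.6) {
  stopifnot(inherits(cal, "balancer_calibration"))
  frames <- validate_frames(frames)
  if (nrow(frames) < 2L) {
    abort_ls("curve reconstruction needs at least two frames", "ligastiff_insufficient_data")
  }
  if (any(diff(frames$frame) <= 0)) {
    abort_ls("frame indices must be strictly increasing", "ligastiff_invalid_input")
  }
  units <- unique(frames$unit)
  if (length(units) != 1L) {
    abort_ls("frames mix measuring units; reconstruct each unit separately", "ligastiff_invalid_input")
  }
  if (units != cal$unit_id) {
    abort_ls(sprintf("frames are from the %s unit but calibration is for the %s unit",
                     units, cal$unit_id), "ligastiff_invalid_input")
  }

  n <- nrow(frames)
  m <- numeric(n)
  gap <- numeric(n)
  for (i in seq_len(n)) {
    r <- frames[i, ]
    m[i] <- relativity_factor(c(r$Ax, r$Ay), c(r$Bx, r$By), c(r$Cx, r$Cy))
    gap[i] <- gap_length_real(c(r$Dx, r$Dy), c(r$Ex, r$Ey), c(r$Gx, r$Gy))
  }
  force <- force_from_m(cal, m, extrapolation_bound, warn = FALSE)
  displacement <- gap[1] - gap

  n_extra <- sum(m > 1)
  n_neg <- sum(displacement < 0)
  if (n_extra > 0) {
    verbose_message(sprintf("%d frame(s) beyond scale endpoint B; force extrapolated (max m = %.3f)",
                            n_extra, max(m)))
  }
  if (n_neg > 0) {
    verbose_message(sprintf("%d frame(s) with negative displacement (gap reading grew after frame 1)",
                            n_neg))
  }

  structure(
    data.frame(frame = frames$frame, m = m, force_N = force,
               gap_mm = gap, displacement_mm = displacement),
    unit_id = units,
    n_extrapolated = n_extra,
    n_negative_displacement = n_neg,
    class = c("fd_curve", "data.frame")
  )
}

#' @export
plot.fd_curve <- function(x, ...) {
  graphics::plot(x$displacement_mm, x$force_N,
                 xlab = "displacement p [mm]", ylab = "force F [N]",
                 main = sprintf("Force-displacement curve (%s unit)", attr(x, "unit_id")),
                 pch = 19, ...)
  graphics::lines(x$displacement_mm, x$force_N, col = "grey50")
  invisible(x)
}

#' Frame-annotation CSV I/O
#'
#' One CSV per measurement, header exactly
#' `frame,unit,Ax,Ay,Bx,By,Cx,Cy,Dx,Dy,Ex,Ey,Gx,Gy`; `unit` in
#' `{left, right}`; decimal point, UTF-8, comma separated.
#'
#' @param path File path.
#' @return `read_frame_csv()` returns a validated frame `data.frame`;
#'   `write_frame_csv()` returns `path` invisibly.
#' @export
read_frame_csv <- function(path) {
  if (!file.exists(path)) abort_ls(sprintf("frame CSV not found: %s", path), "ligastiff_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(FRAME_CSV_HEADER, names(df))
  if (length(missing)) {
    abort_ls(sprintf("frame CSV %s missing column(s): %s", path,
                     paste(missing, collapse = ", ")), "ligastiff_io_error")
  }
  validate_frames(df)
}

#' @rdname read_frame_csv
#' @param frames Frame-annotation `data.frame`.
#' @export
write_frame_csv <- function(frames, path) {
  frames <- validate_frames(frames)
  utils::write.csv(frames, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reconstructed curve as CSV
#'
#' Header: `frame,m,force_N,gap_mm,displacement_mm`.
#'
#' @param curve An `fd_curve` from [reconstruct_curve()].
#' @param path File path.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "fd_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
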