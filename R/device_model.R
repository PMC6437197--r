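#' Measuring-unit calibration for the knee balancer
#'
#' The knee balancer carries two independent spring-loaded measuring units
#' (left and right paddle), each with a joint-force scale and an extension-gap
#' scale. Bench calibration against a universal testing machine fixes, per
#' unit, the forces at the force scale's start point A and reference endpoint
#' B, the spring constant of the paddle drive, and the paddle feed per quarter
#' turn of the knob. Forces read off a video frame are linear interpolations
#' between `force_at_A` and `force_at_B`.
#'
#' @param unit_id `"left"` or `"right"`.
#' @param force_at_A Force in N at the scale start point A.
#' @param force_at_B Force in N at the scale reference endpoint B.
#' @param spring_constant Spring constant of the paddle drive, N/mm.
#' @param feed_per_quarter_turn Axial paddle feed per quarter knob turn, mm.
#' @param measurement_point_means Mean bench forces (N) at scale lines 1-4,
#'   strictly increasing; points 1 and 4 coincide with `force_at_A` and
#'   `force_at_B`.
#' @param measurement_point_sds Optional bench standard deviations (N) at the
#'   four measurement points; stored as metadata only, never used in
#'   reconstruction.
#'
#' @return An object of class `balancer_calibration`.
#' @seealso [default_calibration()] for the shipped bench constants.
#' @export
measuring_unit_calibration <- function(unit_id,
                                       force_at_A,
                                       force_at_B,
                                       spring_constant,
                                       feed_per_quarter_turn,
                                       measurement_point_means,
                                       measurement_point_sds = NULL) {
  unit_id <- match.arg(unit_id, c("left", "right"))
  for (v in list(force_at_A, force_at_B, spring_constant, feed_per_quarter_turn)) {
    if (!is_scalar_number(v)) abort_ls("calibration fields must be single finite numbers", "ligastiff_invalid_input")
  }
  if (!(force_at_B > force_at_A && force_at_A > 0)) {
    abort_ls("calibration requires force_at_B > force_at_A > 0", "ligastiff_invalid_input")
  }
  if (spring_constant <= 0 || feed_per_quarter_turn <= 0) {
    abort_ls("spring_constant and feed_per_quarter_turn must be positive", "ligastiff_invalid_input")
  }
  mpm <- as.numeric(measurement_point_means)
  if (length(mpm) != 4L || anyNA(mpm) || any(diff(mpm) <= 0)) {
    abort_ls("measurement_point_means must be four strictly increasing forces", "ligastiff_invalid_input")
  }
  structure(
    list(
      unit_id = unit_id,
      force_at_A = force_at_A,
      force_at_B = force_at_B,
      spring_constant = spring_constant,
      feed_per_quarter_turn = feed_per_quarter_turn,
      measurement_point_means = mpm,
      measurement_point_sds = if (is.null(measurement_point_sds)) NULL else as.numeric(measurement_point_sds)
    ),
    class = "balancer_calibration"
  )
}

#' Shipped bench calibration of the two measuring units
#'
#' Returns the calibration constants obtained on a universal testing machine
#' for the left and right paddle of the balancer. The two units differ in
#' every force field, so the unit used for each compartment must be tracked
#' through the analysis.
#'
#' @param unit_id `"left"` or `"right"`.
#' @return A [measuring_unit_calibration()] object.
#' @examples
#' default_calibration("left")$force_at_A   # 21.2 N
#' default_calibration("right")$force_at_B  # 116.9 N
#' @export
default_calibration <- function(unit_id = c("left", "right")) {
  unit_id <- match.arg(unit_id)
  if (unit_id == "left") {
    measuring_unit_calibration(
      unit_id = "left",
      force_at_A = 21.2, force_at_B = 123.3,
      spring_constant = 12.0,
      feed_per_quarter_turn = 0.7,
      measurement_point_means = c(21.2, 53.6, 87.6, 123.3),
      measurement_point_sds = c(1.8, 3.3, 3.5, 5.0)
    )
  } else {
    measuring_unit_calibration(
      unit_id = "right",
      force_at_A = 18.1, force_at_B = 116.9,
      spring_constant = 11.8,
      feed_per_quarter_turn = 0.7,
      measurement_point_means = c(18.1, 51.3, 83.4, 116.9),
      measurement_point_sds = c(1.8, 3.5, 3.6, 4.8)
    )
  }
}

#' Spring force from paddle feed
#'
#' The paddle drive behaves as a simple linear spring: constant feed gives a
#' constant increase in force once the femoral paddle is in contact.
#'
#' @param cal A [measuring_unit_calibration()] object.
#' @param feed Paddle feed beyond first contact, mm (non-negative).
#' @return Force above the contact force, in N.
#' @export
spring_force_from_feed <- function(cal, feed) {
  stopifnot(inherits(cal, "balancer_calibration"))
  if (!is.numeric(feed) || anyNA(feed) || any(feed < 0)) {
    abort_ls("feed must be non-negative", "ligastiff_invalid_input")
  }
  cal$spring_constant * feed
}

#' @export
print.balancer_calibration <- function(x, ...) {
  cat(sprintf("Knee balancer calibration (%s unit)\n", x$unit_id))
  cat(sprintf("  force scale: F_A = %.1f N, F_B = %.1f N\n", x$force_at_A, x$force_at_B))
  cat(sprintf("  spring constant: %.1f N/mm; feed %.1f mm per quarter turn\n",
              x$spring_constant, x$feed_per_quarter_turn))
  cat(sprintf("  bench measurement points: %s N\n",
              paste(format(x$measurement_point_means), collapse = ", ")))
  invisible(x)
}

#' Read or write a calibration config file
#'
#' Re-calibrated devices can be described in a flat YAML or JSON file with
#' keys `unit_id`, `force_at_A_N`, `force_at_B_N`, `spring_constant_N_per_mm`,
#' `feed_per_quarter_turn_mm`, `measurement_point_means_N`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return `read_calibration()` returns a `balancer_calibration`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort_ls(sprintf("calibration file not found: %s", path), "ligastiff_io_error")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  needed <- c("unit_id", "force_at_A_N", "force_at_B_N", "spring_constant_N_per_mm",
              "feed_per_quarter_turn_mm", "measurement_point_means_N")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    abort_ls(sprintf("calibration file missing keys: %s", paste(missing, collapse = ", ")),
             "ligastiff_io_error")
  }
  measuring_unit_calibration(
    unit_id = raw$unit_id,
    force_at_A = as.numeric(raw$force_at_A_N),
    force_at_B = as.numeric(raw$force_at_B_N),
    spring_constant = as.numeric(raw$spring_constant_N_per_mm),
    feed_per_quarter_turn = as.numeric(raw$feed_per_quarter_turn_mm),
    measurement_point_means = as.numeric(unlist(raw$measurement_point_means_N))
  )
}

#' @rdname read_calibration
#' @param cal A `balancer_calibration` to serialize.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "balancer_calibration"))
  rec <- list(
    unit_id = cal$unit_id,
    force_at_A_N = cal$force_at_A,
    force_at_B_N = cal$force_at_B,
    spring_constant_N_per_mm = cal$spring_constant,
    feed_per_quarter_turn_mm = cal$feed_per_quarter_turn,
    measurement_point_means_N = cal$measurement_point_means
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(rec, path)
  }
  invisible(path)
}
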