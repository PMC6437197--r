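# Forward model of the whole measurement chain:
# ground-truth ligament curve -> balancer scale pointer positions -> camera
# projection to pixel coordinates with annotation noise. Because the ground
# truth (true stiffness, preload, toe shape, camera pose, noise level, seed)
# is known for every emitted measurement, the reconstruction-and-fit pipeline
# can be scored by parameter recovery.

#' Ground-truth ligament force-displacement curve
#'
#' Piecewise model of a ligament complex under extension: an exponential toe
#' region (progressive recruitment of crimped collagen fibres) joined C1-
#' continuously to a linear region of slope `linear_stiffness`. For
#' displacement p below the transition point p*,
#' F(p) = preload + a (exp(lambda p) - 1); above it,
#' F(p) = transition_force + k (p - p*). The amplitude a and the transition
#' displacement p* are solved from value- and slope-continuity at
#' `transition_force`, so the linear branch's slope is exactly k and recovery
#' has an unambiguous truth. Setting `transition_force = preload` collapses
#' the toe to nothing and yields a pure line of slope k.
#'
#' @param preload Seating force at p = 0, N (in vivo about 10-20 N).
#' @param linear_stiffness True stiffness k of the linear region, N/mm.
#' @param transition_force Force at the toe-to-linear boundary, N; must be
#'   below the 80 N selection threshold and at least the preload.
#' @param toe_rate Exponential rate lambda of the toe, per mm.
#' @param max_force Largest force reached by a pull, N (capped at 170 N in
#'   vivo to protect the ligaments).
#' @return Object of class `ground_truth_curve` with the derived `toe_amplitude`
#'   (a) and `transition_displacement` (p*).
#' @export
ground_truth_curve <- function(preload = 15,
                               linear_stiffness = 30,
                               transition_force = 60,
                               toe_rate = 0.3,
                               max_force = 170) {
  for (v in list(preload, linear_stiffness, transition_force, toe_rate, max_force)) {
    if (!is_scalar_number(v)) abort_ls("curve parameters must be single finite numbers", "ligastiff_invalid_input")
  }
  if (preload <= 0 || linear_stiffness <= 0 || toe_rate <= 0) {
    abort_ls("preload, linear_stiffness and toe_rate must be positive", "ligastiff_invalid_input")
  }
  if (transition_force < preload) {
    abort_ls("transition_force must be at least the preload", "ligastiff_invalid_input")
  }
  if (!(transition_force < 80 && 80 <= max_force && max_force <= 170)) {
    abort_ls("need transition_force < 80 <= max_force <= 170 (N)", "ligastiff_invalid_input")
  }
  # C1 matching: a*lambda*exp(lambda p*) = k and F(p*) = transition_force
  a <- preload + linear_stiffness / toe_rate - transition_force
  if (a <= 0) {
    abort_ls(paste("no C1-continuous toe exists for these parameters",
                   "(toe_rate too large for the preload-to-transition force span)"),
             "ligastiff_configuration_error")
  }
  p_star <- log(linear_stiffness / (toe_rate * a)) / toe_rate
  structure(
    list(
      preload = preload,
      linear_stiffness = linear_stiffness,
      transition_force = transition_force,
      toe_rate = toe_rate,
      max_force = max_force,
      toe_amplitude = a,
      transition_displacement = p_star
    ),
    class = "ground_truth_curve"
  )
}

#' True force at a displacement
#'
#' Evaluates the ground-truth curve; vectorized over `p`.
#'
#' @param curve A [ground_truth_curve()].
#' @param p Displacement(s) in mm, >= 0.
#' @return Force(s) in N.
#' @export
true_force <- function(curve, p) {
  stopifnot(inherits(curve, "ground_truth_curve"))
  if (!is.numeric(p) || anyNA(p) || any(p < 0)) {
    abort_ls("displacement p must be non-negative", "ligastiff_invalid_input")
  }
  toe <- curve$preload + curve$toe_amplitude * (exp(curve$toe_rate * p) - 1)
  lin <- curve$transition_force + curve$linear_stiffness * (p - curve$transition_displacement)
  ifelse(p < curve$transition_displacement, toe, lin)
}

# Inverse of true_force (displacement at which a force is reached).
displacement_at_force <- function(curve, f) {
  stopifnot(inherits(curve, "ground_truth_curve"))
  if (any(f < curve$preload)) abort_ls("force below preload has no displacement", "ligastiff_invalid_input")
  toe <- log((f - curve$preload) / curve$toe_amplitude + 1) / curve$toe_rate
  lin <- curve$transition_displacement + (f - curve$transition_force) / curve$linear_stiffness
  ifelse(f < curve$transition_force, toe, lin)
}

#' Camera model for the synthetic projection
#'
#' Each analysed frame gets its own camera pose: a similarity transform
#' (rotation, uniform scale, translation) drawn uniformly from the stated
#' ranges, an optional mild perspective distortion, and i.i.d. Gaussian pixel
#' noise (truncated at 4 SD) on every digitized coordinate, emulating hand-
#' held filming and manual point picking.
#'
#' @param rotation_range Half-width of the per-frame rotation, radians
#'   (drawn from U(-r, r)).
#' @param scale_range Length-2 range of the per-frame uniform scale factor.
#' @param translation_range Half-width of the per-frame translation, px.
#' @param perspective_strength Dimensionless >= 0; 0 means a pure similarity
#'   (length ratios exact). Positive values add a projective division
#'   w = 1 + h1 x + h2 y with |h| up to `perspective_strength / 1000` per px.
#' @param pixel_noise_sd SD of the annotation jitter per coordinate, px.
#' @param scale_bar_length Nominal pixel length of the reference segments AB
#'   and DE before the camera scale is applied.
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(rotation_range = 0.1,
                         scale_range = c(0.9, 1.1),
                         translation_range = 20,
                         perspective_strength = 0,
                         pixel_noise_sd = 0.5,
                         scale_bar_length = 200) {
  stopifnot(length(scale_range) == 2L)
  if (any(scale_range <= 0)) abort_ls("camera scale must be positive", "ligastiff_invalid_input")
  if (pixel_noise_sd < 0) abort_ls("pixel_noise_sd must be >= 0", "ligastiff_invalid_input")
  if (perspective_strength < 0) abort_ls("perspective_strength must be >= 0", "ligastiff_invalid_input")
  if (rotation_range < 0 || translation_range < 0 || scale_bar_length <= 0) {
    abort_ls("camera ranges must be non-negative and scale_bar_length positive", "ligastiff_invalid_input")
  }
  structure(
    list(
      rotation_range = rotation_range,
      scale_range = sort(as.numeric(scale_range)),
      translation_range = translation_range,
      perspective_strength = perspective_strength,
      pixel_noise_sd = pixel_noise_sd,
      scale_bar_length = scale_bar_length
    ),
    class = "camera_model"
  )
}

#' @rdname camera_model
#' @export
identity_camera <- function(pixel_noise_sd = 0, scale_bar_length = 200) {
  camera_model(rotation_range = 0, scale_range = c(1, 1), translation_range = 0,
               perspective_strength = 0, pixel_noise_sd = pixel_noise_sd,
               scale_bar_length = scale_bar_length)
}

# Apply similarity + optional perspective to a 6x2 coordinate matrix.
apply_frame_transform <- function(pts, rot, scl, tx, ty, h1, h2) {
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  out <- scl * (pts %*% t(R))
  out[, 1] <- out[, 1] + tx
  out[, 2] <- out[, 2] + ty
  if (h1 != 0 || h2 != 0) {
    w <- 1 + h1 * out[, 1] + h2 * out[, 2]
    out <- out / w
  }
  out
}

#' Project a ground-truth pull through the device and camera
#'
#' Builds the full synthetic measurement: displacements on a uniform grid
#' from the first frame where the force pointer has reached the scale start
#' (force >= F_A) up to the displacement where `max_force` is reached (the
#' manual pull is quasi-static at roughly constant speed), each mapped
#' through the
#' inverse of the force-scale interpolation (m = (F - F_A)/(F_B - F_A)) and
#' the gap-scale geometry (the gap reading shrinks by p from its first-frame
#' value). Scale points are laid out canonically -- force scale along x with
#' |AB| = `scale_bar_length` px and C at A + m (B - A); gap scale orthogonal
#' with |DE| = `scale_bar_length` px, E serving as the reading's zero mark
#' and D as its 20 mm mark, and the pointer G on the graduated stretch
#' between them at EG_real/20 of the reference length from E -- then pushed
#' through the frame's camera transform and jittered. Deterministic given
#' `seed`.
#'
#' @param cal A [measuring_unit_calibration()].
#' @param curve A [ground_truth_curve()].
#' @param camera A [camera_model()].
#' @param n_frames Number of analysed frames (>= 2; in vivo 15-20).
#' @param seed Integer seed for camera poses and pixel noise.
#' @param initial_gap_mm Gap-scale reading at frame 1 (mm); must exceed the
#'   total displacement of the pull.
#' @param extrapolation_bound Largest admissible m (see
#'   [force_from_relativity()]).
#' @return Object of class `synthetic_measurement`: `frames` (annotation
#'   table), `truth` (curve), `camera`, `seed`, `branch_labels`
#'   (`"toe"`/`"linear"` per frame), and `truth_samples` (`data.frame` of the
#'   exact per-frame force and displacement).
#' @export
project_measurement <- function(cal, curve, camera, n_frames = 17, seed = 1,
                                initial_gap_mm = 15, extrapolation_bound = 1.6) {
  stopifnot(inherits(cal, "balancer_calibration"),
            inherits(curve, "ground_truth_curve"),
            inherits(camera, "camera_model"))
  if (!is_scalar_number(n_frames) || n_frames < 2) {
    abort_ls("need at least 2 frames", "ligastiff_invalid_input")
  }
  n_frames <- as.integer(n_frames)

  # The force pointer only enters the scale at F_A; analysed frames start at
  # the first frame where the pointer is on the scale (m >= 0), mirroring the
  # annotator's choice of frame 1. Displacement is relative to that frame.
  f_start <- max(curve$preload, cal$force_at_A)
  if (f_start >= curve$max_force) {
    abort_ls("scale start force is at or above max_force; nothing to measure",
             "ligastiff_configuration_error")
  }
  p_abs <- seq(displacement_at_force(curve, f_start),
               displacement_at_force(curve, curve$max_force),
               length.out = n_frames)
  f <- true_force(curve, p_abs)
  f[1] <- f_start  # guard against round-off below F_A at the grid start
  p <- p_abs - p_abs[1]
  if (p[n_frames] >= initial_gap_mm) {
    abort_ls("pull displacement exceeds the initial gap reading; increase initial_gap_mm",
             "ligastiff_configuration_error")
  }
  m <- pmax(0, (f - cal$force_at_A) / (cal$force_at_B - cal$force_at_A))
  if (any(m > extrapolation_bound)) {
    abort_ls(sprintf("required m = %.3f exceeds the extrapolation bound %.2f",
                     max(m), extrapolation_bound), "ligastiff_out_of_range")
  }
  eg_real <- initial_gap_mm - p

  L <- camera$scale_bar_length
  frames <- with_local_seed(seed, {
    rows <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      # canonical layout: force scale along x, gap scale orthogonal to it
      pts <- rbind(
        A = c(0, 0),
        B = c(L, 0),
        C = c(m[i] * L, 0),
        # E is the gap scale's zero mark and D its 20 mm mark; the pointer G
        # sits on the graduated stretch between them at the current reading
        D = c(1.5 * L, L),
        E = c(1.5 * L, 0),
        G = c(1.5 * L, eg_real[i] * (L / 20))
      )
      rot <- stats::runif(1, -camera$rotation_range, camera$rotation_range)
      scl <- stats::runif(1, camera$scale_range[1], camera$scale_range[2])
      tx <- stats::runif(1, -camera$translation_range, camera$translation_range)
      ty <- stats::runif(1, -camera$translation_range, camera$translation_range)
      hmax <- camera$perspective_strength / 1000
      h1 <- if (hmax > 0) stats::runif(1, -hmax, hmax) else 0
      h2 <- if (hmax > 0) stats::runif(1, -hmax, hmax) else 0
      proj <- apply_frame_transform(pts, rot, scl, tx, ty, h1, h2)
      noisy <- proj + matrix(rtrunc_norm(12, camera$pixel_noise_sd), ncol = 2)
      rows[[i]] <- data.frame(
        frame = 1L + (i - 1L) * 10L,  # every 10th video frame is analysed
        unit = cal$unit_id,
        Ax = noisy[1, 1], Ay = noisy[1, 2], Bx = noisy[2, 1], By = noisy[2, 2],
        Cx = noisy[3, 1], Cy = noisy[3, 2], Dx = noisy[4, 1], Dy = noisy[4, 2],
        Ex = noisy[5, 1], Ey = noisy[5, 2], Gx = noisy[6, 1], Gy = noisy[6, 2]
      )
    }
    do.call(rbind, rows)
  })

  structure(
    list(
      frames = validate_frames(frames),
      truth = curve,
      camera = camera,
      seed = seed,
      branch_labels = ifelse(p_abs < curve$transition_displacement, "toe", "linear"),
      truth_samples = data.frame(frame = frames$frame, force_N = f, displacement_mm = p)
    ),
    class = "synthetic_measurement"
  )
}

#' @export
print.synthetic_measurement <- function(x, ...) {
  cat(sprintf(paste0("Synthetic balancer measurement: %d frames, true stiffness %.1f N/mm,\n",
                     "  preload %.1f N, transition %.1f N, noise %.2f px, seed %d\n"),
              nrow(x$frames), x$truth$linear_stiffness, x$truth$preload,
              x$truth$transition_force, x$camera$pixel_noise_sd, x$seed))
  invisible(x)
}

#' Generate a seeded suite of synthetic measurements for recovery scoring
#'
#' Draws true stiffness uniformly from `stiffness_range` (default 20-47 N/mm,
#' spanning the per-specimen cohort values), preload uniformly from
#' `preload_range`, and 15-20 analysed frames per pull, then emits one
#' measurement per (draw, noise level). The pairing of each measurement with
#' its generating truth is retained for scoring. Deterministic given `seed`.
#'
#' @param n_measurements Number of ground-truth draws (>= 1).
#' @param stiffness_range Length-2 range of true stiffness, N/mm.
#' @param noise_levels Pixel-noise SDs, px (>= 1 level).
#' @param seed Master seed.
#' @param preload_range Length-2 range of preload, N.
#' @param unit_ids Units to alternate through, `"left"`/`"right"`.
#' @param camera Base [camera_model()]; its `pixel_noise_sd` is overridden by
#'   each noise level.
#' @param transition_force,toe_rate,max_force Passed to
#'   [ground_truth_curve()].
#' @return List of `synthetic_measurement` objects; each carries a
#'   `noise_px` element recording its noise level.
#' @export
generate_recovery_suite <- function(n_measurements,
                                    stiffness_range = c(20, 47),
                                    noise_levels = 0.5,
                                    seed = 1,
                                    preload_range = c(10, 20),
                                    unit_ids = c("left", "right"),
                                    camera = camera_model(),
                                    transition_force = 60,
                                    toe_rate = 0.3,
                                    max_force = 170) {
  if (!is_scalar_number(n_measurements) || n_measurements < 1) {
    abort_ls("n_measurements must be >= 1", "ligastiff_invalid_input")
  }
  if (length(noise_levels) == 0L) abort_ls("need at least one noise level", "ligastiff_invalid_input")
  if (any(noise_levels < 0)) abort_ls("noise levels must be >= 0", "ligastiff_invalid_input")
  n_measurements <- as.integer(n_measurements)

  draws <- with_local_seed(seed, {
    data.frame(
      k = stats::runif(n_measurements, stiffness_range[1], stiffness_range[2]),
      preload = stats::runif(n_measurements, preload_range[1], preload_range[2]),
      n_frames = sample(15:20, n_measurements, replace = TRUE),
      unit = sample(unit_ids, n_measurements, replace = TRUE),
      meas_seed = sample.int(.Machine$integer.max - 1L, n_measurements)
    )
  })

  out <- list()
  for (noise in noise_levels) {
    cam <- camera
    cam$pixel_noise_sd <- noise
    for (i in seq_len(n_measurements)) {
      curve <- ground_truth_curve(
        preload = draws$preload[i],
        linear_stiffness = draws$k[i],
        transition_force = transition_force,
        toe_rate = toe_rate,
        max_force = max_force
      )
      meas <- project_measurement(
        cal = default_calibration(draws$unit[i]),
        curve = curve, camera = cam,
        n_frames = draws$n_frames[i],
        seed = draws$meas_seed[i]
      )
      meas$noise_px <- noise
      out[[length(out) + 1L]] <- meas
    }
  }
  out
}

#' Write a synthetic measurement to disk
#'
#' Emits the frame-annotation CSV plus a sidecar truth JSON
#' (`<stem>_truth.json`) recording seed, true stiffness, preload, transition
#' force, noise level and camera parameters.
#'
#' @param meas A `synthetic_measurement`.
#' @param dir Output directory (created if needed).
#' @param stem File stem (e.g. `"meas_001"`).
#' @return Invisibly, the paths written (`csv`, `truth`).
#' @export
write_measurement <- function(meas, dir, stem) {
  stopifnot(inherits(meas, "synthetic_measurement"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  truth <- file.path(dir, paste0(stem, "_truth.json"))
  write_frame_csv(meas$frames, csv)
  jsonlite::write_json(
    list(
      seed = meas$seed,
      unit_id = meas$frames$unit[1],
      true_stiffness_N_per_mm = meas$truth$linear_stiffness,
      preload_N = meas$truth$preload,
      transition_force_N = meas$truth$transition_force,
      toe_rate_per_mm = meas$truth$toe_rate,
      max_force_N = meas$truth$max_force,
      noise_px = meas$camera$pixel_noise_sd,
      camera = unclass(meas$camera)
    ),
    truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(csv = csv, truth = truth))
}

#' @rdname write_measurement
#' @param path Path of a truth sidecar JSON.
#' @export
read_truth_json <- function(path) {
  if (!file.exists(path)) abort_ls(sprintf("truth JSON not found: %s", path), "ligastiff_io_error")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
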