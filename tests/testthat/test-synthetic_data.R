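test_that("the ground-truth curve is C1-continuous with the stated branches", {
  curve <- ground_truth_curve(preload = 12, linear_stiffness = 30,
                              transition_force = 60, toe_rate = 0.3)
  expect_equal(true_force(curve, 0), 12)                       # preload at origin
  p_star <- curve$transition_displacement
  expect_equal(true_force(curve, p_star), 60)                  # value continuity
  h <- 1e-7
  expect_equal((true_force(curve, p_star + 2 * h) - true_force(curve, p_star + h)) / h,
               30, tolerance = 1e-4)                           # slope k above p*
  expect_equal((true_force(curve, p_star) - true_force(curve, p_star - h)) / h,
               30, tolerance = 1e-4)                           # slope k below p*
  # strictly increasing, slope never above k below the transition
  p <- seq(0, p_star + 3, length.out = 200)
  f <- true_force(curve, p)
  expect_true(all(diff(f) > 0))
  expect_true(all(diff(f) / diff(p) <= 30 + 1e-9))

  # transition at the preload collapses the toe to a pure line of slope k
  line <- ground_truth_curve(preload = 30, linear_stiffness = 25,
                             transition_force = 30, toe_rate = 0.3)
  expect_equal(line$transition_displacement, 0)
  p <- seq(0, 5, length.out = 7)
  expect_equal(true_force(line, p), 30 + 25 * p, tolerance = 1e-12)

  # no C1-continuous toe when the rate is too large for the force span
  expect_error(ground_truth_curve(preload = 10, linear_stiffness = 20,
                                  transition_force = 75, toe_rate = 0.5),
               class = "ligastiff_configuration_error")
  expect_error(ground_truth_curve(transition_force = 90),
               class = "ligastiff_invalid_input")
})

test_that("noise-free projection inverts exactly through reconstruction", {
  cal <- default_calibration("left")
  curve <- ground_truth_curve(preload = 14, linear_stiffness = 35)
  meas <- project_measurement(cal, curve, identity_camera(), n_frames = 17, seed = 2)
  rec <- reconstruct_curve(cal, meas$frames)
  expect_equal(rec$force_N, meas$truth_samples$force_N, tolerance = 1e-9)
  expect_equal(rec$displacement_mm, meas$truth_samples$displacement_mm,
               tolerance = 1e-9)
  expect_identical(rec$displacement_mm[1], 0)
  # extension shrinks the gap: displacement non-negative and non-decreasing
  expect_true(all(rec$displacement_mm >= 0))
  expect_true(all(diff(rec$displacement_mm) >= 0))
  # noise-free fit returns the true stiffness
  fit <- recover_stiffness(meas)
  expect_equal(fit$slope, 35, tolerance = 1e-6)
})

test_that("reconstruction is invariant under arbitrary per-frame similarity cameras", {
  cal <- default_calibration("right")
  curve <- ground_truth_curve(preload = 16, linear_stiffness = 22)
  wild <- camera_model(rotation_range = pi, scale_range = c(0.3, 3),
                       translation_range = 500, pixel_noise_sd = 0)
  for (seed in c(2, 23, 97)) {
    meas <- project_measurement(cal, curve, wild, n_frames = 15, seed = seed)
    rec <- reconstruct_curve(cal, meas$frames)
    expect_equal(rec$force_N, meas$truth_samples$force_N, tolerance = 1e-9)
    expect_equal(rec$displacement_mm, meas$truth_samples$displacement_mm,
                 tolerance = 1e-9)
  }
})

test_that("mild perspective bends ratios slightly; zero strength not at all", {
  cal <- default_calibration("left")
  curve <- ground_truth_curve()
  base <- camera_model(rotation_range = 0.2, scale_range = c(0.8, 1.2),
                       translation_range = 50, pixel_noise_sd = 0,
                       perspective_strength = 0)
  persp <- base; persp$perspective_strength <- 0.1
  class(persp) <- "camera_model"

  exact <- project_measurement(cal, curve, base, n_frames = 16, seed = 31)
  rec0 <- reconstruct_curve(cal, exact$frames)
  expect_equal(rec0$force_N, exact$truth_samples$force_N, tolerance = 1e-12)

  warped <- project_measurement(cal, curve, persp, n_frames = 16, seed = 31)
  rec1 <- reconstruct_curve(cal, warped$frames)
  err <- abs(rec1$force_N - warped$truth_samples$force_N) / warped$truth_samples$force_N
  expect_gt(max(err), 0)          # some distortion
  expect_lt(max(err), 0.05)       # but bounded for mild strength
})

test_that("projection is deterministic given a seed and respects its bounds", {
  cal <- default_calibration("left")
  curve <- ground_truth_curve()
  cam <- camera_model(pixel_noise_sd = 0.7)
  a <- project_measurement(cal, curve, cam, n_frames = 18, seed = 99)
  b <- project_measurement(cal, curve, cam, n_frames = 18, seed = 99)
  expect_identical(a$frames, b$frames)
  c <- project_measurement(cal, curve, cam, n_frames = 18, seed = 100)
  expect_false(identical(a$frames, c$frames))

  # frame files byte-identical for the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_measurement(a, d1, "m"); write_measurement(b, d2, "m")
  expect_identical(readLines(file.path(d1, "m.csv")), readLines(file.path(d2, "m.csv")))

  # a pull that would push the pointer past the extrapolation bound errors
  tight <- ground_truth_curve(preload = 14, linear_stiffness = 30)
  expect_error(project_measurement(cal, tight, cam, n_frames = 17, seed = 1,
                                   extrapolation_bound = 1.2),
               class = "ligastiff_out_of_range")
  expect_error(project_measurement(cal, tight, cam, n_frames = 1, seed = 1),
               class = "ligastiff_invalid_input")
})

test_that("recovery suites are seeded, labelled, and score cleanly at zero noise", {
  one <- generate_recovery_suite(1, noise_levels = 0, seed = 8)
  expect_length(one, 1L)
  fit <- recover_stiffness(one[[1]])
  expect_equal(fit$slope, one[[1]]$truth$linear_stiffness, tolerance = 1e-6)

  # same seed, same suite
  s1 <- generate_recovery_suite(3, noise_levels = c(0, 1), seed = 21)
  s2 <- generate_recovery_suite(3, noise_levels = c(0, 1), seed = 21)
  expect_length(s1, 6L)
  for (i in seq_along(s1)) expect_identical(s1[[i]]$frames, s2[[i]]$frames)

  # stiffness and preload drawn inside the requested ranges
  ks <- vapply(s1, function(m) m$truth$linear_stiffness, numeric(1))
  pre <- vapply(s1, function(m) m$truth$preload, numeric(1))
  nf <- vapply(s1, function(m) nrow(m$frames), numeric(1))
  expect_true(all(ks >= 20 & ks <= 47))
  expect_true(all(pre >= 10 & pre <= 20))
  expect_true(all(nf >= 15 & nf <= 20))

  expect_error(generate_recovery_suite(2, noise_levels = numeric(0), seed = 1),
               class = "ligastiff_invalid_input")
  expect_error(generate_recovery_suite(0, seed = 1), class = "ligastiff_invalid_input")
})

test_that("selected linear-region samples come from the generator's linear branch", {
  suite <- generate_recovery_suite(5, noise_levels = 0, seed = 77)
  for (meas in suite) {
    cal <- default_calibration(meas$frames$unit[1])
    rec <- reconstruct_curve(cal, meas$frames)
    sel <- select_linear_region(rec, 80)
    labels <- meas$branch_labels[rec$force_N >= 80]
    expect_true(all(labels == "linear"))
    expect_equal(nrow(sel), length(labels))
  }
})

test_that("truth sidecar JSON records the generating parameters", {
  meas <- generate_recovery_suite(1, noise_levels = 0.5, seed = 12)[[1]]
  dir <- withr::local_tempdir()
  paths <- write_measurement(meas, dir, "meas_001")
  truth <- read_truth_json(paths$truth)
  expect_equal(truth$true_stiffness_N_per_mm, meas$truth$linear_stiffness)
  expect_equal(truth$preload_N, meas$truth$preload)
  expect_equal(truth$transition_force_N, meas$truth$transition_force)
  expect_equal(truth$noise_px, 0.5)
  expect_equal(truth$seed, meas$seed)
  expect_equal(truth$unit_id, meas$frames$unit[1])
})
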