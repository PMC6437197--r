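# Linear-region selection and stiffness estimation.
#
# A ligament-complex force-displacement curve has a compliant non-linear toe
# region (straightening of crimped collagen fibres) followed by a linear
# region. Structural stiffness is the slope dF/dp of the linear region in
# N/mm. Across all in vivo measurements in the source data linearity holds
# from 80 N of applied force onward, which is the default selection
# threshold.

#' Select the linear region of a force-displacement curve
#'
#' Keeps exactly the samples whose force is at or above the threshold,
#' preserving order. The default 80 N is the force from which linearity is
#' certain across measurements; the toe-to-linear transition itself is
#' gradual and individual.
#'
#' @param curve An `fd_curve` or any `data.frame` with `force_N` and
#'   `displacement_mm` columns.
#' @param threshold Force threshold in N (> 0).
#' @return The selected subset, same columns, order preserved.
#' @export
select_linear_region <- function(curve, threshold = 80) {
  stopifnot(is.data.frame(curve), all(c("force_N", "displacement_mm") %in% names(curve)))
  if (!is_scalar_number(threshold) || threshold <= 0) {
    abort_ls("threshold must be a positive force in N", "ligastiff_invalid_input")
  }
  sel <- curve[curve$force_N >= threshold, , drop = FALSE]
  if (nrow(sel) < 3L) {
    abort_ls(sprintf("only %d sample(s) at or above %g N; need >= 3 for a stiffness fit",
                     nrow(sel), threshold), "ligastiff_insufficient_linear_data")
  }
  sel
}

#' Fit stiffness as the slope of the linear region
#'
#' Ordinary least-squares regression of force (N) on displacement (mm); the
#' slope is the structural stiffness in N/mm. Force is regressed on
#' displacement (not the reverse) because stiffness is defined as the
#' gradient dF/dp of the linear section.
#'
#' @param samples A `data.frame` with `force_N` and `displacement_mm`, at
#'   least 3 rows, displacements not all equal. Typically the output of
#'   [select_linear_region()].
#' @param force_threshold Threshold recorded in the fit metadata (N).
#' @return An object of class `stiffness_fit`: list with `slope` (N/mm),
#'   `intercept` (N), `slope_se` (N/mm), `r_squared`, `n_points`,
#'   `force_threshold`.
#' @export
fit_stiffness <- function(samples, force_threshold = NA_real_) {
  stopifnot(is.data.frame(samples), all(c("force_N", "displacement_mm") %in% names(samples)))
  if (nrow(samples) < 3L) {
    abort_ls("stiffness fit needs at least 3 samples", "ligastiff_insufficient_data")
  }
  p <- samples$displacement_mm
  f <- samples$force_N
  if (max(p) - min(p) <= 0) {
    abort_ls("all displacements identical; stiffness fit is singular", "ligastiff_singular_fit")
  }
  fit <- stats::lm(f ~ p)
  # noise-free validation curves fit exactly; silence summary.lm's
  # "essentially perfect fit" notice for that legitimate case
  sm <- suppressWarnings(summary(fit))
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      slope_se = unname(sm$coefficients[2, 2]),
      r_squared = sm$r.squared,
      n_points = length(p),
      force_threshold = force_threshold
    ),
    class = "stiffness_fit"
  )
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat(sprintf("Ligament stiffness fit: %.2f N/mm (SE %.3f), R^2 = %.4f, n = %d",
              x$slope, x$slope_se, x$r_squared, x$n_points))
  if (is.finite(x$force_threshold)) cat(sprintf(", force >= %g N", x$force_threshold))
  cat("\n")
  invisible(x)
}

#' Aggregate repeated measurements of one compartment
#'
#' Each compartment (medial or lateral) is measured in repeated pulls; the
#' per-compartment stiffness is the arithmetic mean of the repeat slopes with
#' a population (divide-by-n) standard deviation, the dispersion convention
#' the printed cohort summaries follow. A single repeat gets SD 0.
#'
#' @param fits List of `stiffness_fit` objects (>= 1).
#' @param compartment `"medial"` or `"lateral"`.
#' @return Object of class `compartment_stiffness`: `compartment`,
#'   `mean_stiffness` (N/mm), `sd_stiffness` (N/mm), `repeat_fits`.
#' @export
aggregate_repeats <- function(fits, compartment = c("medial", "lateral")) {
  compartment <- match.arg(compartment)
  if (inherits(fits, "stiffness_fit")) fits <- list(fits)
  if (length(fits) == 0L) abort_ls("need at least one repeat fit", "ligastiff_invalid_input")
  if (!all(vapply(fits, inherits, logical(1), "stiffness_fit"))) {
    abort_ls("fits must be stiffness_fit objects", "ligastiff_invalid_input")
  }
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  structure(
    list(
      compartment = compartment,
      mean_stiffness = mean(slopes),
      sd_stiffness = pop_sd(slopes),
      repeat_fits = fits
    ),
    class = "compartment_stiffness"
  )
}

#' @export
print.compartment_stiffness <- function(x, ...) {
  cat(sprintf("%s compartment: stiffness %.1f (SD %.1f) N/mm over %d repeat(s)\n",
              x$compartment, x$mean_stiffness, x$sd_stiffness, length(x$repeat_fits)))
  invisible(x)
}

#' Estimate the onset of linearity of a curve (QC helper)
#'
#' The toe-to-linear transition is gradual; this helper scans candidate
#' thresholds over the observed sample forces (ascending) and returns the
#' smallest one whose suffix -- all samples at or above it, at least
#' `min_points` of them -- fits a line with R^2 >= `r2_threshold`. If no
#' candidate qualifies, the conservative default threshold is returned with a
#' warning. Intended for QC of individual curves, not as a replacement for
#' the fixed default threshold.
#'
#' @param curve `data.frame` with `force_N` and `displacement_mm`, >= 6 rows.
#' @param r2_threshold Coefficient-of-determination cutoff for "linear".
#' @param min_points Minimum suffix size for a candidate.
#' @param default_threshold Fallback threshold in N.
#' @return Estimated onset force in N.
#' @export
detect_linearity_onset <- function(curve, r2_threshold = 0.995, min_points = 3,
                                   default_threshold = 80) {
  stopifnot(is.data.frame(curve), all(c("force_N", "displacement_mm") %in% names(curve)))
  if (nrow(curve) < 6L) {
    abort_ls("linearity-onset detection needs at least 6 samples spanning toe and linear regions",
             "ligastiff_insufficient_data")
  }
  for (cand in sort(unique(curve$force_N))) {
    suffix <- curve[curve$force_N >= cand, , drop = FALSE]
    if (nrow(suffix) < min_points) break
    if (max(suffix$displacement_mm) - min(suffix$displacement_mm) <= 0) next
    fit <- fit_stiffness(suffix, force_threshold = cand)
    if (fit$r_squared >= r2_threshold) return(cand)
  }
  warning(sprintf("no linear suffix with R^2 >= %.3f found; falling back to %g N",
                  r2_threshold, default_threshold), call. = FALSE)
  default_threshold
}

#' Serialize per-measurement stiffness results to JSON
#'
#' @param results List of per-(patient, compartment) result records as
#'   produced by [cmd_fit()].
#' @param path Output JSON path.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
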