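# Patient cohort handling and summary statistics.

COHORT_CSV_HEADER <- c("specimen", "sex", "age_y", "bmi_kg_m2", "leg_side",
                       "leg_axis_deg", "mlc_mean", "mlc_sd", "llc_mean", "llc_sd")

COHORT_SUMMARY_VARS <- c("age_y", "bmi_kg_m2", "leg_axis_deg", "mlc_mean", "llc_mean")

validate_cohort <- function(records) {
  if (!is.data.frame(records) || !all(COHORT_CSV_HEADER %in% names(records))) {
    abort_ls(sprintf("cohort table must have columns: %s",
                     paste(COHORT_CSV_HEADER, collapse = ",")), "ligastiff_io_error")
  }
  if (nrow(records) == 0L) abort_ls("cohort is empty", "ligastiff_invalid_input")
  if (!all(records$sex %in% c("M", "F"))) abort_ls("sex must be M or F", "ligastiff_invalid_input")
  if (!all(records$leg_side %in% c("left", "right"))) {
    abort_ls("leg_side must be left or right", "ligastiff_invalid_input")
  }
  num <- records[, c("age_y", "bmi_kg_m2", "mlc_mean", "llc_mean")]
  if (any(as.matrix(num) <= 0) || any(records$mlc_sd < 0) || any(records$llc_sd < 0)) {
    abort_ls("age, BMI and stiffness means must be positive; SDs non-negative",
             "ligastiff_invalid_input")
  }
  records[, COHORT_CSV_HEADER]
}

#' Read a cohort CSV
#'
#' Header: `specimen,sex,age_y,bmi_kg_m2,leg_side,leg_axis_deg,mlc_mean,
#' mlc_sd,llc_mean,llc_sd`. Stiffness columns are the per-specimen mean and
#' SD over repeated pulls, in N/mm, for the medial (MLC) and lateral (LLC)
#' ligament complexes.
#'
#' @param path CSV path.
#' @return Validated cohort `data.frame`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort_ls(sprintf("cohort CSV not found: %s", path), "ligastiff_io_error")
  validate_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort_csv
#' @param records Cohort `data.frame`.
#' @export
write_cohort_csv <- function(records, path) {
  records <- validate_cohort(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged five-patient study cohort
#'
#' Demographics and per-compartment stiffness (mean and SD over two repeated
#' pulls, N/mm) of the five patients whose force-displacement curves were
#' reconstructed in vivo during total knee arthroplasty. Shipped at
#' `system.file("extdata", "table1_cohort.csv", package = "ligastiff")`.
#'
#' @return Cohort `data.frame` with 5 records.
#' @examples
#' cohort <- load_table1_fixture()
#' summarize_cohort(cohort)
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_cohort.csv", package = "ligastiff")
  if (path == "") abort_ls("packaged cohort fixture not found", "ligastiff_io_error")
  read_cohort_csv(path)
}

#' Summarize a patient cohort
#'
#' Arithmetic mean, population (divide-by-n) SD, minimum and maximum for age,
#' BMI, leg axis, and the per-specimen medial/lateral stiffness means. Values
#' are kept unrounded; [round_cohort_summary()] renders them at the 1-decimal
#' display precision.
#'
#' @param records Cohort `data.frame` (see [read_cohort_csv()]), >= 1 record.
#' @return Object of class `cohort_summary`: `n` and a `stats` data.frame
#'   with one row per variable (`mean`, `sd`, `min`, `max`).
#' @export
summarize_cohort <- function(records) {
  records <- validate_cohort(records)
  stats_df <- do.call(rbind, lapply(COHORT_SUMMARY_VARS, function(v) {
    x <- as.numeric(records[[v]])
    data.frame(variable = v, mean = mean(x), sd = pop_sd(x),
               min = min(x), max = max(x))
  }))
  rownames(stats_df) <- stats_df$variable
  structure(list(n = nrow(records), stats = stats_df), class = "cohort_summary")
}

#' Round a cohort summary for display
#'
#' @param summary A `cohort_summary`.
#' @param digits Decimal places (default 1, the printed precision).
#' @return The summary with all statistics rounded.
#' @export
round_cohort_summary <- function(summary, digits = 1) {
  stopifnot(inherits(summary, "cohort_summary"))
  summary$stats[, c("mean", "sd", "min", "max")] <-
    round(summary$stats[, c("mean", "sd", "min", "max")], digits)
  summary
}

#' @export
print.cohort_summary <- function(x, digits = 1, ...) {
  cat(sprintf("Cohort summary (n = %d), mean +/- population SD [min, max]:\n", x$n))
  labs <- c(age_y = "age [a]", bmi_kg_m2 = "BMI [kg/m^2]",
            leg_axis_deg = "leg axis [deg]", mlc_mean = "MLC stiffness [N/mm]",
            llc_mean = "LLC stiffness [N/mm]")
  for (i in seq_len(nrow(x$stats))) {
    s <- x$stats[i, ]
    cat(sprintf("  %-22s %6.1f +/- %4.1f  [%.1f, %.1f]\n",
                labs[[s$variable]], s$mean, s$sd, s$min, s$max))
  }
  invisible(x)
}

#' Write a cohort summary as JSON
#'
#' @param summary A `cohort_summary`.
#' @param path Output path.
#' @export
write_cohort_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "cohort_summary"))
  display <- round_cohort_summary(summary)
  out <- list(
    n = summary$n,
    variables = lapply(seq_len(nrow(summary$stats)), function(i) {
      s <- summary$stats[i, ]
      d <- display$stats[i, ]
      list(variable = s$variable,
           mean = s$mean, sd = s$sd, min = s$min, max = s$max,
           display = sprintf("%.1f (%.1f)", d$mean, d$sd))
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
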