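# Internal helpers shared across modules.

# Signal a classed error so callers can discriminate failure modes
# programmatically (tryCatch on the subclass).
abort_ls <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ligastiff_error")))
}

# Population (divide-by-n) standard deviation. The cohort summaries printed in
# the source study follow this convention, not the sample (n-1) one.
pop_sd <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x)) abort_ls("pop_sd needs non-missing values", "ligastiff_invalid_input")
  sqrt(mean((x - mean(x))^2))
}

# Euclidean distance between two 2-D points given as c(x, y).
point_distance <- function(p, q) {
  sqrt((p[[1]] - q[[1]])^2 + (p[[2]] - q[[2]])^2)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!is_scalar_number(seed)) abort_ls("seed must be a single finite number", "ligastiff_invalid_input")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Zero-mean Gaussian noise truncated at +/- bound standard deviations
# (rejection sampling; the truncation keeps annotation jitter physically
# plausible -- a human picking a scale point is never tens of pixels off).
rtrunc_norm <- function(n, sd, bound = 4) {
  if (sd < 0) abort_ls("noise sd must be non-negative", "ligastiff_invalid_input")
  if (sd == 0) return(numeric(n))
  x <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(x) > bound * sd)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
  }
  x
}

verbose_message <- function(...) {
  if (isTRUE(getOption("ligastiff.verbose", FALSE))) message(...)
}
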