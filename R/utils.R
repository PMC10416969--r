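# internal helpers shared across modules

# Run `expr` under a fixed RNG seed and restore the caller's RNG state.
# Keeps cohort generation / model fitting reproducible without clobbering
# the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

#' Column names of a paired-readings table
#'
#' Fixed column order used by [write_cohort()] / [read_cohort()] and expected
#' by the calibration pipeline: patient id, ISO-8601 timestamp, measured CGM
#' glucose `g_m`, reference glucose `g_r`, and the seven personalized
#' covariates `x2` (physical activity, g), `x3` (peak acceleration, g),
#' `x4` (posture, degrees), `x5` (heart rate, BPM), `x6` (breath rate, BPM),
#' `x7` (skin temperature, deg C), `x8` (food intake, calories).
#'
#' @return Character vector of the 11 column names.
#' @export
reading_columns <- function() {
  c("patient_id", "timestamp", "g_m", "g_r",
    "x2", "x3", "x4", "x5", "x6", "x7", "x8")
}

covariate_columns <- function() c("x2", "x3", "x4", "x5", "x6", "x7", "x8")

# Feature matrix for the error regressors: measured glucose (x1) plus the
# seven covariates, in the fixed x1..x8 order.
feature_matrix <- function(readings) {
  m <- cbind(x1 = readings$g_m,
             as.matrix(readings[, covariate_columns(), drop = FALSE]))
  storage.mode(m) <- "double"
  m
}

validate_readings <- function(readings, require_reference = TRUE) {
  if (!is.data.frame(readings))
    stop("readings must be a data.frame", call. = FALSE)
  need <- reading_columns()
  if (!require_reference) need <- setdiff(need, "g_r")
  missing <- setdiff(need, names(readings))
  if (length(missing))
    stop("readings is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(readings)) {
    if (any(!is.finite(readings$g_m)) || any(readings$g_m <= 0))
      stop("g_m must be finite and > 0", call. = FALSE)
    if (require_reference &&
        (any(!is.finite(readings$g_r)) || any(readings$g_r <= 0)))
      stop("g_r must be finite and > 0", call. = FALSE)
    cov <- as.matrix(readings[, covariate_columns(), drop = FALSE])
    if (any(!is.finite(cov)))
      stop("covariates must all be finite", call. = FALSE)
    if (any(readings$x5 <= 0) || any(readings$x6 <= 0))
      stop("heart rate (x5) and breath rate (x6) must be > 0", call. = FALSE)
  }
  invisible(readings)
}
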