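#' Sensor error model for synthetic cohorts
#'
#' Describes how the measured CGM value deviates from the reference value.
#' The error of a reading with reference glucose `g_r` in cluster `c` is
#'
#'   error = bias\[c\] + slope\[c\] * g_r + sum(coef\[j\] * x_j) +
#'           patient_offset + noise
#'
#' where `x_j` are the seven personalized covariates, `patient_offset` is a
#' per-patient draw from N(0, patient_offset_sd) (between-patient variation)
#' and `noise` is an i.i.d. N(0, noise_sd) draw (within-patient variation).
#' Every component is recorded, so the ground-truth error of every reading
#' is recomputable in closed form.
#'
#' The defaults produce cluster-dependent proportional sensor error with an
#' uncorrected MARD in the mid-teens percent, comparable to uncalibrated
#' interstitial-fluid sensors.
#'
#' @param per_cluster_bias Additive bias per cluster, mg/dL (length 6).
#' @param per_cluster_slope Dimensionless gain applied to reference glucose,
#'   per cluster (length 6).
#' @param covariate_coefficients Error contribution per unit of each of the
#'   seven covariates x2..x8 (mg/dL per unit; length 7).
#' @param noise_sd Within-patient i.i.d. noise SD, mg/dL.
#' @param patient_offset_sd Between-patient offset SD, mg/dL.
#' @return An object of class `error_model_spec`.
#' @export
error_model_spec <- function(per_cluster_bias = c(10, -14, 12, -18, 14, -24),
                             per_cluster_slope = c(0.04, -0.04, 0.04,
                                                   -0.05, 0.04, -0.04),
                             covariate_coefficients = c(3, 1.5, 0.02, 0.02,
                                                        0.05, 0.1, 0.004),
                             noise_sd = 6,
                             patient_offset_sd = 4) {
  if (length(per_cluster_bias) != 6L || any(!is.finite(per_cluster_bias)))
    stop("per_cluster_bias must be 6 finite values", call. = FALSE)
  if (length(per_cluster_slope) != 6L || any(!is.finite(per_cluster_slope)))
    stop("per_cluster_slope must be 6 finite values", call. = FALSE)
  if (length(covariate_coefficients) != 7L ||
      any(!is.finite(covariate_coefficients)))
    stop("covariate_coefficients must be 7 finite values", call. = FALSE)
  stop_if_not_scalar_number(noise_sd, "noise_sd")
  stop_if_not_scalar_number(patient_offset_sd, "patient_offset_sd")
  if (noise_sd < 0 || patient_offset_sd < 0)
    stop("noise_sd and patient_offset_sd must be >= 0", call. = FALSE)
  structure(list(per_cluster_bias = as.numeric(per_cluster_bias),
                 per_cluster_slope = as.numeric(per_cluster_slope),
                 covariate_coefficients =
                   stats::setNames(as.numeric(covariate_coefficients),
                                   covariate_columns()),
                 noise_sd = as.numeric(noise_sd),
                 patient_offset_sd = as.numeric(patient_offset_sd)),
            class = "error_model_spec")
}

#' Configuration of a synthetic CGM cohort
#'
#' Emulates the structure of a multi-day free-living type-1-diabetes cohort:
#' a CGM sensor sampling every few minutes, sparse fingerstick references
#' taken around meals, and wearable covariates recorded alongside. The
#' reference glucose trajectory is a mean-reverting (Ornstein-Uhlenbeck)
#' process plus exponentially decaying meal spikes, clipped to 40--400
#' mg/dL, so that with the default variability all six glucose clusters are
#' populated.
#'
#' @param n_patients Number of patients (default 9).
#' @param duration_days Days of wear per patient.
#' @param cgm_interval CGM sampling interval, minutes (default 5).
#' @param references_per_day Fingerstick references per day (default 6,
#'   emulating one before and one two hours after each of three meals).
#' @param glucose_process List with `mean` and `variability` (mg/dL) of the
#'   mean-reverting component and `meal_spike` amplitude (mg/dL) and
#'   `spike_decay` time constant (minutes) of the meal pulses.
#' @param error_model An [error_model_spec()].
#' @param seed Integer seed; identical seed and config give a bit-identical
#'   cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 9,
                          duration_days = 4,
                          cgm_interval = 5,
                          references_per_day = 6,
                          glucose_process = list(mean = 140, variability = 45,
                                                 meal_spike = 70,
                                                 spike_decay = 90),
                          error_model = error_model_spec(),
                          seed = 1) {
  stop_if_not_scalar_number(n_patients, "n_patients")
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  stop_if_not_scalar_number(duration_days, "duration_days", positive = TRUE)
  stop_if_not_scalar_number(cgm_interval, "cgm_interval", positive = TRUE)
  stop_if_not_scalar_number(references_per_day, "references_per_day")
  if (references_per_day < 1)
    stop("references_per_day must be >= 1", call. = FALSE)
  gp <- glucose_process
  for (f in c("mean", "variability", "meal_spike", "spike_decay")) {
    if (is.null(gp[[f]]))
      stop(sprintf("glucose_process$%s is missing", f), call. = FALSE)
    stop_if_not_scalar_number(gp[[f]], paste0("glucose_process$", f))
  }
  if (!inherits(error_model, "error_model_spec"))
    stop("error_model must be an error_model_spec", call. = FALSE)
  stop_if_not_scalar_number(seed, "seed")
  structure(list(n_patients = as.integer(n_patients),
                 duration_days = as.integer(duration_days),
                 cgm_interval = as.numeric(cgm_interval),
                 references_per_day = as.integer(references_per_day),
                 glucose_process = gp,
                 error_model = error_model,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# AR(1) process with given stationary mean/sd, clipped to [lo, hi]
ar1_series <- function(n, mean, sd, phi = 0.9, lo = -Inf, hi = Inf) {
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, mean, sd)
  for (t in seq_len(n - 1L)) x[t + 1L] <- mean + phi * (x[t] - mean) + e[t + 1L]
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic paired-readings cohort
#'
#' Simulates each patient's reference glucose trajectory and wearable
#' covariates on the CGM sampling grid, draws sparse fingerstick reference
#' times around meals (snapped to the grid so the sensor error is exactly
#' recoverable), applies the sensor [error_model_spec()] to obtain measured
#' values, and returns the paired readings together with the ground-truth
#' error decomposition of every reading.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cgm_cohort` with elements
#'   \describe{
#'     \item{readings}{data.frame in [reading_columns()] order.}
#'     \item{truth}{data.frame with per-reading `cluster`, `bias`,
#'       `slope_term`, `covariate_term`, `patient_offset`, `noise` and total
#'       `error` (= `g_m - g_r`).}
#'     \item{config}{the generating config.}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 2, duration_days = 2))
#' head(coh$readings)
#' all.equal(coh$readings$g_m - coh$readings$g_r, coh$truth$error)
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config"))
    stop("config must be a cohort_config", call. = FALSE)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  gp <- config$glucose_process
  em <- config$error_model
  origin <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  step_min <- config$cgm_interval
  steps_per_day <- floor(24 * 60 / step_min)
  n_steps <- steps_per_day * config$duration_days
  phi <- exp(-0.02 * step_min)  # OU mean reversion, time constant 50 min

  readings <- vector("list", config$n_patients)
  truths <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("patient_%02d", p)
    times <- origin + (seq_len(n_steps) - 1L) * step_min * 60

    # meals: ~3/day at 8h, 13h, 19h with +/- 45 min jitter
    meal_hours <- as.vector(outer(c(8, 13, 19),
                                  24 * (seq_len(config$duration_days) - 1L),
                                  "+")) + stats::runif(3 * config$duration_days,
                                                       -0.75, 0.75)
    meal_min <- sort(meal_hours * 60)
    meal_cal <- stats::runif(length(meal_min), 300, 900)

    # reference trajectory: OU + meal spikes, clipped to [40, 400]
    t_min <- (seq_len(n_steps) - 1L) * step_min
    base <- ar1_series(n_steps, gp$mean, gp$variability, phi = phi)
    spikes <- rep(0, n_steps)
    for (i in seq_along(meal_min)) {
      dt <- t_min - meal_min[i]
      on <- dt >= 0
      spikes[on] <- spikes[on] +
        gp$meal_spike * stats::runif(1, 0.6, 1.4) * exp(-dt[on] / gp$spike_decay)
    }
    g_true <- pmin(pmax(base + spikes, 40), 400)

    # wearable covariates on the same grid, within-patient autocorrelated
    x2 <- pmax(ar1_series(n_steps, stats::runif(1, 0.1, 0.4), 0.15), 0)
    x3 <- pmax(ar1_series(n_steps, stats::runif(1, 0.3, 0.8), 0.25), 0)
    x4 <- ar1_series(n_steps, stats::runif(1, -20, 40), 20, lo = -90, hi = 90)
    x5 <- ar1_series(n_steps, stats::runif(1, 60, 90), 8, lo = 50, hi = 160)
    x6 <- ar1_series(n_steps, stats::runif(1, 12, 20), 2, lo = 8, hi = 30)
    x7 <- ar1_series(n_steps, stats::runif(1, 31, 36), 0.5, lo = 30, hi = 38)
    x8 <- rep(0, n_steps)
    for (i in seq_along(meal_min)) {
      dt <- t_min - meal_min[i]
      on <- dt >= 0
      x8[on] <- x8[on] + meal_cal[i] * exp(-dt[on] / 60)
    }
    x8 <- pmin(x8, 1200)

    # fingerstick times: 15 min before / 120 min after meals, snapped to the
    # CGM grid; topped up with random grid times if more are requested
    n_ref <- config$references_per_day * config$duration_days
    cand <- sort(c(meal_min - 15, meal_min + 120))
    idx <- unique(pmin(pmax(round(cand / step_min) + 1L, 1L), n_steps))
    if (length(idx) > n_ref) {
      idx <- sort(sample(idx, n_ref))
    } else if (length(idx) < n_ref) {
      extra <- sample(setdiff(seq_len(n_steps), idx),
                      min(n_ref - length(idx), n_steps - length(idx)))
      idx <- sort(c(idx, extra))
    }

    g_r <- g_true[idx]
    cl <- assign_cluster(g_r)
    cov <- cbind(x2 = x2[idx], x3 = x3[idx], x4 = x4[idx], x5 = x5[idx],
                 x6 = x6[idx], x7 = x7[idx], x8 = x8[idx])
    offset_p <- stats::rnorm(1, 0, em$patient_offset_sd)
    noise <- stats::rnorm(length(idx), 0, em$noise_sd)
    bias <- em$per_cluster_bias[cl + 1L]
    slope_term <- em$per_cluster_slope[cl + 1L] * g_r
    covariate_term <- as.vector(cov %*% em$covariate_coefficients)
    err <- bias + slope_term + covariate_term + offset_p + noise
    g_m <- pmax(g_r + err, 1)  # floor; untouched under realistic settings
    err <- g_m - g_r

    readings[[p]] <- data.frame(patient_id = pid, timestamp = times[idx],
                                g_m = g_m, g_r = g_r, cov,
                                stringsAsFactors = FALSE)
    truths[[p]] <- data.frame(patient_id = pid, timestamp = times[idx],
                              cluster = cl, bias = bias,
                              slope_term = slope_term,
                              covariate_term = covariate_term,
                              patient_offset = offset_p, noise = noise,
                              error = err, stringsAsFactors = FALSE)
  }
  out <- list(readings = do.call(rbind, readings),
              truth = do.call(rbind, truths),
              config = config)
  rownames(out$readings) <- NULL
  rownames(out$truth) <- NULL
  class(out) <- "cgm_cohort"
  out
}

#' @export
print.cgm_cohort <- function(x, ...) {
  cnt <- table(factor(x$truth$cluster, levels = 0:5))
  cat(sprintf("Synthetic CGM cohort: %d readings, %d patients\n",
              nrow(x$readings), length(unique(x$readings$patient_id))))
  cat("  per-cluster counts:", paste(as.integer(cnt), collapse = " "), "\n")
  invisible(x)
}

#' Pair reference readings with the nearest CGM and covariate rows
#'
#' Matches every reference (fingerstick) reading to the nearest-in-time CGM
#' reading and nearest covariate row of the same patient, within a time
#' tolerance. References without a match inside the tolerance are dropped and
#' counted.
#'
#' @param cgm_table data.frame with columns `patient_id`, `timestamp`, `g_m`.
#' @param reference_table data.frame with columns `patient_id`, `timestamp`,
#'   `g_r`.
#' @param covariate_table data.frame with columns `patient_id`, `timestamp`,
#'   `x2`..`x8`.
#' @param tolerance Maximum timestamp gap in minutes (default 5, one CGM
#'   interval).
#' @return Paired-readings data.frame sorted by patient then time, with an
#'   attribute `dropped` giving the number of unmatched references.
#' @export
pair_and_merge <- function(cgm_table, reference_table, covariate_table,
                           tolerance = 5) {
  stop_if_not_scalar_number(tolerance, "tolerance")
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  check_cols <- function(tab, need, what) {
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop(sprintf("%s is missing required columns: %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  check_cols(cgm_table, c("patient_id", "timestamp", "g_m"), "cgm_table")
  check_cols(reference_table, c("patient_id", "timestamp", "g_r"),
             "reference_table")
  check_cols(covariate_table,
             c("patient_id", "timestamp", covariate_columns()),
             "covariate_table")

  ref <- data.table::as.data.table(reference_table)[
    , c("patient_id", "timestamp", "g_r"), with = FALSE]
  cgm <- data.table::as.data.table(cgm_table)[
    , c("patient_id", "timestamp", "g_m"), with = FALSE]
  cov <- data.table::as.data.table(covariate_table)[
    , c("patient_id", "timestamp", covariate_columns()), with = FALSE]
  cgm[, ts_cgm := timestamp]
  cov[, ts_cov := timestamp]
  data.table::setkey(ref, patient_id, timestamp)

  m <- cgm[ref, on = c("patient_id", "timestamp"), roll = "nearest"]
  m <- cov[m, on = c("patient_id", "timestamp"), roll = "nearest"]
  tol_s <- tolerance * 60
  gap_cgm <- abs(as.numeric(m$timestamp) - as.numeric(m$ts_cgm))
  gap_cov <- abs(as.numeric(m$timestamp) - as.numeric(m$ts_cov))
  ok <- !is.na(m$g_m) & !is.na(m$x2) & gap_cgm <= tol_s & gap_cov <= tol_s
  dropped <- sum(!ok)
  m <- m[ok]
  data.table::setorder(m, patient_id, timestamp)
  out <- as.data.frame(m[, c("patient_id", "timestamp", "g_m", "g_r",
                             covariate_columns()), with = FALSE])
  attr(out, "dropped") <- dropped
  out
}

iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write / read a cohort CSV
#'
#' The cohort file is a plain CSV with one header row and the fixed column
#' order of [reading_columns()]; timestamps are ISO-8601 UTC. Numeric fields
#' are written with full precision so that `read_cohort(write_cohort(x))`
#' reproduces `x` exactly.
#'
#' @param readings Paired-readings data.frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   readings data.frame (empty, with the right columns, for a header-only
#'   file).
#' @export
write_cohort <- function(readings, path) {
  validate_readings(readings)
  num <- setdiff(reading_columns(), c("patient_id", "timestamp"))
  out <- readings[, reading_columns(), drop = FALSE]
  out$timestamp <- iso8601(out$timestamp)
  for (cn in num) out[[cn]] <- formatC(out[[cn]], digits = 17, format = "g")
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(reading_columns(), names(raw))
  if (length(miss))
    stop("cohort file is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  raw <- raw[, intersect(c(reading_columns(), "food_quality"), names(raw)),
             drop = FALSE]
  if (!nrow(raw)) {
    out <- data.frame(patient_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"))
    for (cn in setdiff(names(raw), c("patient_id", "timestamp")))
      out[[cn]] <- numeric(0)
    return(out)
  }
  num_cols <- setdiff(names(raw), c("patient_id", "timestamp"))
  out <- raw
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & !is.na(raw[[cn]]))
    if (length(bad))
      stop(sprintf("parse error in '%s' line %d: non-numeric value '%s' in column %s",
                   basename(path), bad[1] + 1L, raw[[cn]][bad[1]], cn),
           call. = FALSE)
    out[[cn]] <- v
  }
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- which(is.na(ts))
  if (length(bad))
    stop(sprintf("parse error in '%s' line %d: bad timestamp '%s'",
                 basename(path), bad[1] + 1L, raw$timestamp[bad[1]]),
         call. = FALSE)
  out$timestamp <- ts
  validate_readings(out)
  out
}

#' Best-effort reader for wearable summary CSV files
#'
#' Reads a Zephyr-BioHarness-style `Summary.csv` and maps the recognized
#' columns onto the pipeline's covariates: heart rate to `x5`, breathing
#' rate to `x6`, device/skin temperature to `x7`, posture to `x4`, activity
#' to `x2` and peak acceleration to `x3`. Matching is case-insensitive on
#' column names; unrecognized columns are ignored, absent ones yield `NA`.
#'
#' @param path Path to the summary CSV.
#' @param patient_id Patient identifier to attach (default the file's parent
#'   directory name).
#' @return data.frame with `patient_id`, `timestamp`, `x2`..`x7`.
#' @export
read_wearable_summary <- function(path, patient_id = basename(dirname(path))) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(gsub("[^a-z]", "", tolower(names(raw))))
  pick <- function(patterns) {
    for (p in patterns) {
      hit <- which(grepl(p, nm))
      if (length(hit)) return(raw[[hit[1]]])
    }
    rep(NA_real_, nrow(raw))
  }
  ts_raw <- pick(c("^time$", "time", "^date"))
  ts <- as.POSIXct(ts_raw, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (all(is.na(ts)))
    ts <- as.POSIXct(ts_raw, format = "%d/%m/%Y %H:%M:%OS", tz = "UTC")
  if (all(is.na(ts)))
    ts <- as.POSIXct(ts_raw, tz = "UTC")
  data.frame(patient_id = patient_id,
             timestamp = ts,
             x2 = as.numeric(pick(c("^activity"))),
             x3 = as.numeric(pick(c("peakaccel"))),
             x4 = as.numeric(pick(c("^posture"))),
             x5 = as.numeric(pick(c("^heartrate$", "^hr$", "heartrate"))),
             x6 = as.numeric(pick(c("breathingrate", "breathrate", "^br$"))),
             x7 = as.numeric(pick(c("devicetemp", "coretemp", "^temp"))),
             stringsAsFactors = FALSE)
}
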