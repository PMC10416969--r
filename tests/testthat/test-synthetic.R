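test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_patients = 3, duration_days = 2, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # and writing both gives byte-identical files
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a$readings, fa)
  write_cohort(b$readings, fb)
  expect_identical(readLines(fa), readLines(fb))
  # a different seed changes the cohort
  expect_false(identical(
    generate_cohort(cohort_config(n_patients = 3, duration_days = 2,
                                  seed = 8))$readings$g_r,
    a$readings$g_r))
})

test_that("zero-error model reproduces the reference exactly", {
  em <- error_model_spec(per_cluster_bias = rep(0, 6),
                         per_cluster_slope = rep(0, 6),
                         covariate_coefficients = rep(0, 7),
                         noise_sd = 0, patient_offset_sd = 0)
  coh <- generate_cohort(cohort_config(n_patients = 2, duration_days = 2,
                                       error_model = em, seed = 5))
  expect_equal(coh$readings$g_m, coh$readings$g_r)
  expect_equal(coh$truth$error, rep(0, nrow(coh$truth)))
})

test_that("per-cluster biases land on the clusters of the reference value", {
  em <- error_model_spec(per_cluster_bias = c(15, 0, 0, 0, 0, -20),
                         per_cluster_slope = rep(0, 6),
                         covariate_coefficients = rep(0, 7),
                         noise_sd = 0, patient_offset_sd = 0)
  coh <- generate_cohort(cohort_config(duration_days = 6, error_model = em,
                                       seed = 9))
  d <- coh$readings$g_m - coh$readings$g_r
  low <- coh$readings$g_r <= 80
  high <- coh$readings$g_r > 250
  expect_gt(sum(low), 0)
  expect_gt(sum(high), 0)
  expect_equal(d[low], rep(15, sum(low)))
  expect_equal(d[high], rep(-20, sum(high)))
  expect_equal(d[!low & !high], rep(0, sum(!low & !high)))
})

test_that("noiseless generated errors match the closed-form error model", {
  cfg <- cohort_config(duration_days = 3,
                       error_model = error_model_spec(noise_sd = 0),
                       seed = 3)
  coh <- generate_cohort(cfg)
  em <- cfg$error_model
  cl <- assign_cluster(coh$readings$g_r)
  covm <- as.matrix(coh$readings[, c("x2", "x3", "x4", "x5", "x6", "x7",
                                     "x8")])
  expected <- em$per_cluster_bias[cl + 1] +
    em$per_cluster_slope[cl + 1] * coh$readings$g_r +
    as.vector(covm %*% em$covariate_coefficients) +
    coh$truth$patient_offset
  expect_equal(coh$readings$g_m - coh$readings$g_r, expected,
               tolerance = 1e-12)
  expect_identical(cl, coh$truth$cluster)
})

test_that("invalid cohort configs name the offending field", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(cgm_interval = -5), "cgm_interval")
  expect_error(cohort_config(references_per_day = 0), "references_per_day")
  expect_error(cohort_config(glucose_process = list(mean = 140)),
               "glucose_process")
  expect_error(error_model_spec(noise_sd = -1), "noise_sd")
  expect_error(error_model_spec(per_cluster_bias = 1:3), "per_cluster_bias")
})

ts <- function(x) as.POSIXct(paste("2023-01-01", x), tz = "UTC")

test_that("pairing matches each reference to the nearest rows within tolerance", {
  cgm <- data.frame(patient_id = "p1", timestamp = ts(c("10:00", "10:05")),
                    g_m = c(111, 222))
  cov <- make_readings(c(111, 222))[, c("patient_id", "timestamp",
                                        covariate_columns())]
  cov$timestamp <- ts(c("10:00", "10:05"))
  ref <- data.frame(patient_id = "p1", timestamp = ts("10:02"), g_r = 105)
  out <- pair_and_merge(cgm, ref, cov, tolerance = 5)
  expect_identical(nrow(out), 1L)
  expect_identical(out$g_m, 111)  # 10:00 is nearest
  expect_identical(attr(out, "dropped"), 0L)

  # outside tolerance: dropped and counted
  ref2 <- data.frame(patient_id = "p1", timestamp = ts("10:30"), g_r = 100)
  out2 <- pair_and_merge(cgm, ref2, cov, tolerance = 5)
  expect_identical(nrow(out2), 0L)
  expect_identical(attr(out2, "dropped"), 1L)

  # three in-tolerance references give three paired readings
  cgm3 <- data.frame(patient_id = "p1",
                     timestamp = ts(c("10:00", "10:05", "10:10")),
                     g_m = c(1, 2, 3) + 100)
  cov3 <- cov[rep(1, 3), ]; cov3$timestamp <- cgm3$timestamp
  ref3 <- data.frame(patient_id = "p1",
                     timestamp = ts(c("10:01", "10:06", "10:09")),
                     g_r = c(101, 102, 103))
  out3 <- pair_and_merge(cgm3, ref3, cov3, tolerance = 5)
  expect_identical(out3$g_m, c(101, 102, 103))
})

test_that("pairing is invariant to input row order and respects patients", {
  set.seed(21)
  coh <- generate_cohort(cohort_config(n_patients = 3, duration_days = 2,
                                       seed = 12))
  r <- coh$readings
  cgm <- r[, c("patient_id", "timestamp", "g_m")]
  ref <- r[, c("patient_id", "timestamp", "g_r")]
  cov <- r[, c("patient_id", "timestamp", covariate_columns())]
  base <- pair_and_merge(cgm, ref, cov, tolerance = 5)
  shuf <- pair_and_merge(cgm[sample(nrow(cgm)), ],
                         ref[sample(nrow(ref)), ],
                         cov[sample(nrow(cov)), ], tolerance = 5)
  expect_equal(base, shuf)
  expect_equal(base$g_m, r$g_m[order(r$patient_id, r$timestamp)])
})

test_that("pairing reports missing columns by name", {
  bad_cgm <- data.frame(patient_id = "p1", timestamp = ts("10:00"))
  cgm <- data.frame(patient_id = "p1", timestamp = ts("10:00"), g_m = 100)
  ref <- data.frame(patient_id = "p1", timestamp = ts("10:00"), g_r = 100)
  cov <- make_readings(100)[, c("patient_id", "timestamp",
                                covariate_columns())]
  expect_error(pair_and_merge(bad_cgm, ref, cov), "g_m")
  expect_error(pair_and_merge(cgm, ref, cov[, 1:5]), "x6, x7, x8")
})

test_that("cohort CSV round-trips exactly", {
  coh <- generate_cohort(cohort_config(n_patients = 1, duration_days = 1,
                                       references_per_day = 10, seed = 2))
  r <- coh$readings[1:10, ]
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort(r, p)
  back <- read_cohort(p)
  expect_identical(back$g_m, r$g_m)
  expect_identical(back$g_r, r$g_r)
  expect_identical(back$x7, r$x7)
  expect_equal(back$timestamp, r$timestamp)
  expect_identical(names(back), reading_columns())
})

test_that("malformed cohort rows fail with the offending line number", {
  coh <- generate_cohort(cohort_config(n_patients = 1, duration_days = 1,
                                       seed = 2))
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh$readings[1:5, ], p)
  lines <- readLines(p)
  fields <- strsplit(lines[4], ",")[[1]]
  fields[3] <- "oops"  # g_m on data row 3 = file line 4
  lines[4] <- paste(fields, collapse = ",")
  writeLines(lines, p)
  expect_error(read_cohort(p), "line 4")
  # missing columns are a schema error
  writeLines(c("patient_id,timestamp,g_m", "p1,2023-01-01T00:00:00Z,100"), p)
  expect_error(read_cohort(p), "g_r")
})

test_that("a header-only cohort file reads as an empty collection", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(reading_columns(), collapse = ","), p)
  out <- read_cohort(p)
  expect_identical(nrow(out), 0L)
  expect_true(all(reading_columns() %in% names(out)))
})

test_that("wearable summary reader maps recognized columns onto covariates", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Time,HeartRate,BreathingRate,DeviceTemp,Posture,Activity,PeakAccel,Battery",
               "2023-01-01T10:00:00,72,15,33.5,12,0.3,0.9,80",
               "2023-01-01T10:00:01,74,16,33.6,11,0.2,0.7,80"), p)
  out <- read_wearable_summary(p, patient_id = "p9")
  expect_identical(out$x5, c(72, 74))
  expect_identical(out$x6, c(15, 16))
  expect_identical(out$x7, c(33.5, 33.6))
  expect_identical(out$x4, c(12, 11))
  expect_identical(out$x2, c(0.3, 0.2))
  expect_identical(out$x3, c(0.9, 0.7))
  expect_identical(out$patient_id, rep("p9", 2))
})
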