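# 20 fixed pairs with hand-computed relative errors: estimates are
# references scaled by (1 + e) for the e vector below, so
#   MARD        = 100 * mean(|e|)            = 15.2
#   RMSE (rel)  = 100 * sqrt(mean(e^2))      = 100 * sqrt(0.7474 / 20)
#   RMSE (abs)  = sqrt(mean((ref * e)^2))
fixed_rel <- c(0.1, -0.1, 0.2, -0.2, 0.05, -0.05, 0.25, -0.25, 0.15, -0.15,
               0.3, -0.3, 0.02, -0.02, 0.12, -0.12, 0.08, -0.08, 0.5, 0)
fixed_ref <- rep(c(100, 80, 250, 60, 400), 4)
fixed_est <- fixed_ref * (1 + fixed_rel)

test_that("mard, rmse and relative errors match their closed forms", {
  expect_identical(mard(c(100, 250), c(100, 250)), 0)
  expect_equal(mard(120, 100), 20, tolerance = 1e-12)
  expect_equal(mard(c(90, 110), c(100, 100)), 10, tolerance = 1e-12)

  expect_equal(mard(fixed_est, fixed_ref), 15.2, tolerance = 1e-9)
  expect_equal(rmse(fixed_est, fixed_ref, "relative"),
               100 * sqrt(0.7474 / 20), tolerance = 1e-9)
  expect_equal(rmse(fixed_est, fixed_ref, "absolute"),
               sqrt(mean((fixed_ref * fixed_rel)^2)), tolerance = 1e-9)
  re <- relative_errors(fixed_est, fixed_ref)
  expect_equal(re, 100 * fixed_rel, tolerance = 1e-9)
  expect_equal(max(re), 50, tolerance = 1e-12)
  expect_equal(min(re), -30, tolerance = 1e-12)

  expect_equal(relative_errors(80, 200), -60, tolerance = 1e-12)
  expect_equal(relative_errors(300, 200), 50, tolerance = 1e-12)
  expect_equal(rmse(c(110, 90), c(100, 100), "absolute"), 10,
               tolerance = 1e-12)
  expect_equal(rmse(c(110, 90), c(100, 100), "relative"), 10,
               tolerance = 1e-12)
})

test_that("metric domain errors are raised for empty or invalid inputs", {
  expect_error(mard(numeric(0), numeric(0)), "non-empty")
  expect_error(mard(c(1, 2), 1), "length")
  expect_error(mard(100, 0), "> 0")
  expect_error(mard(100, -3), "> 0")
  expect_error(rmse(NA_real_, 100), "finite")
})

test_that("mard obeys the scale law mard(a*ref, ref) = 100|a - 1|", {
  set.seed(5)
  ref <- runif(50, 40, 400)
  for (a in c(0.5, 0.8, 1, 1.2, 1.7)) {
    expect_equal(mard(a * ref, ref), 100 * abs(a - 1), tolerance = 1e-12)
  }
})

test_that("clarke_zone reproduces the canonical zone examples", {
  expect_identical(clarke_zone(100, 100), "A")
  expect_identical(clarke_zone(100, 119), "A")
  expect_identical(clarke_zone(c(50, 200, 50), c(200, 60, 120)),
                   c("E", "E", "D"))
  # a few independently placed interior points
  expect_identical(clarke_zone(100, 150), "B")
  expect_identical(clarke_zone(150, 300), "C")
  expect_identical(clarke_zone(160, 20), "C")
  expect_identical(clarke_zone(300, 120), "D")
  expect_identical(clarke_zone(60, 60), "A")
  expect_error(clarke_zone(-1, 100), "> 0")
  expect_error(clarke_zone(100, 0), "> 0")
})

test_that("the ordered rule set agrees with the point-in-polygon zone oracle", {
  set.seed(31)
  n <- 2000
  x <- runif(n, 1, 450)
  y <- runif(n, 1, 450)
  oracle <- clarke_polygon_oracle(x, y)
  expect_true(all(oracle$hits %in% c(0L, 1L)))  # zones are disjoint
  expect_identical(clarke_zone(x, y), oracle$zone)
})

test_that("cega_summary counts every pair exactly once, in any order", {
  est <- c(100, 119, 200); ref <- c(100, 100, 50)
  s <- cega_summary(est, ref)
  expect_identical(s$zone, c("A", "B", "C", "D", "E"))
  expect_identical(s$count, c(2L, 0L, 0L, 0L, 1L))
  expect_equal(sum(s$pct), 100, tolerance = 1e-9)
  set.seed(2)
  est2 <- runif(200, 40, 400); ref2 <- runif(200, 40, 400)
  s2 <- cega_summary(est2, ref2)
  expect_identical(sum(s2$count), 200L)
  perm <- sample(200)
  expect_identical(cega_summary(est2[perm], ref2[perm]), s2)
})

test_that("FDA compliance keys the rule on the sensor value", {
  expect_equal(fda_compliance(90, 95, "adjunctive"), 100)
  expect_equal(fda_compliance(150, 100, "adjunctive"), 0)
  expect_equal(fda_compliance(108, 100, "nonadjunctive"), 100)
  expect_equal(fda_compliance(85, 96, "nonadjunctive"), 0)  # 11 mg/dL off
  expect_equal(fda_compliance(c(90, 150), c(95, 100), "adjunctive"), 50)
})

test_that("before/after reports cover six clusters plus the overall row", {
  set.seed(9)
  n <- 300
  g_r <- runif(n, 45, 380)
  g_m <- pmax(g_r + rnorm(n, 10, 20), 1)
  g_p <- pmax(g_r + rnorm(n, 0, 5), 1)
  rep1 <- before_after_report(g_m, g_p, g_r)
  expect_identical(nrow(rep1$metrics), 7L)
  expect_identical(rep1$metrics$cluster, c(as.character(0:5), "All"))
  expect_identical(sum(rep1$metrics$n[1:6]), as.integer(n))
  expect_identical(sum(rep1$cega_before$count), as.integer(n))
  expect_identical(sum(rep1$cega_after$count), as.integer(n))

  # perfect correction: final MARD 0 and 100% zone A
  perfect <- before_after_report(g_m, g_r, g_r)
  all_row <- perfect$metrics[perfect$metrics$cluster == "All", ]
  expect_equal(all_row$mard_final, 0, tolerance = 1e-12)
  expect_equal(perfect$cega_after$pct[1], 100, tolerance = 1e-12)

  # no-op correction: initial and final columns identical
  noop <- before_after_report(g_m, g_m, g_r)
  expect_equal(noop$metrics$mard_initial, noop$metrics$mard_final)
  expect_equal(noop$metrics$rmse_initial, noop$metrics$rmse_final)
})

test_that("reports serialize to CSV and markdown", {
  set.seed(3)
  g_r <- runif(60, 45, 380)
  rep1 <- before_after_report(g_r + 12, g_r + 2, g_r)
  d <- withr::local_tempdir()
  paths <- write_report(rep1, d)
  expect_true(all(file.exists(paths)))
  back <- read.csv(file.path(d, "report.csv"))
  expect_identical(nrow(back), 7L)
  expect_true(any(grepl("^\\|", readLines(file.path(d, "report.md")))))
})

test_that("accuracy_report aggregates all summary statistics consistently", {
  ar <- accuracy_report(fixed_est, fixed_ref)
  expect_identical(ar$n_pairs, 20L)
  expect_equal(ar$mard, 15.2, tolerance = 1e-9)
  expect_identical(sum(ar$zones$count), 20L)
  expect_true(ar$fda_adjunctive >= ar$fda_nonadjunctive)
  expect_output(print(ar), "MARD")
})
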