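check_pairs <- function(estimates, references) {
  if (!length(estimates) || length(estimates) != length(references))
    stop("estimates and references must be non-empty and the same length",
         call. = FALSE)
  if (any(!is.finite(estimates)) || any(!is.finite(references)))
    stop("estimates and references must be finite", call. = FALSE)
  if (any(references <= 0))
    stop("references must be > 0", call. = FALSE)
}

#' Mean absolute relative difference (MARD)
#'
#' The standard accuracy summary for glucose sensors: the mean over pairs of
#' `|estimate - reference| / reference`, in percent.
#'
#' @param estimates Estimated (sensor or corrected) glucose, mg/dL.
#' @param references Reference glucose, mg/dL, all > 0.
#' @return MARD in percent.
#' @examples
#' mard(c(90, 110), c(100, 100))  # 10
#' @export
mard <- function(estimates, references) {
  check_pairs(estimates, references)
  100 * mean(abs(estimates - references) / references)
}

#' Signed per-pair relative errors
#'
#' @inheritParams mard
#' @return Numeric vector of signed errors `100 * (estimate - reference) /
#'   reference` (%); use `max()` / `min()` for the extreme errors.
#' @export
relative_errors <- function(estimates, references) {
  check_pairs(estimates, references)
  100 * (estimates - references) / references
}

#' Root mean squared error, absolute or relative
#'
#' @inheritParams mard
#' @param mode `"absolute"` (mg/dL) or `"relative"` (RMS of the signed
#'   percentage errors, %).
#' @return RMSE in the requested units.
#' @export
rmse <- function(estimates, references, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  check_pairs(estimates, references)
  if (mode == "absolute") sqrt(mean((estimates - references)^2))
  else sqrt(mean((100 * (estimates - references) / references)^2))
}

#' Clarke error grid zone of (reference, estimate) pairs
#'
#' Classifies each pair into one of the five clinically weighted zones of
#' Clarke error grid analysis. Zone A is clinically accurate (within 20% of
#' the reference, or both values hypoglycemic), B benign, C overcorrection,
#' D failure to detect hypo-/hyperglycemia, and E confusion of hypoglycemia
#' with hyperglycemia. The ordered piecewise-linear rule set below (first
#' match wins, priority A, E, C, D, else B) reproduces the canonical zone
#' geometry; the test suite cross-checks it against a point-in-polygon
#' evaluation of the published zone polygons.
#'
#' @param references Reference glucose, mg/dL, > 0 (x axis).
#' @param estimates Estimated glucose, mg/dL, > 0 (y axis).
#' @return Character vector of zone labels `"A"`..`"E"`.
#' @examples
#' clarke_zone(c(100, 100, 50), c(100, 119, 200))  # "A" "A" "E"
#' @export
clarke_zone <- function(references, estimates) {
  check_pairs(estimates, references)
  if (any(estimates <= 0))
    stop("estimates must be > 0", call. = FALSE)
  x <- references; y <- estimates
  zone <- rep(NA_character_, length(x))
  inA <- (x <= 70 & y <= 70) | (y >= 0.8 * x & y <= 1.2 * x)
  inE <- (x >= 180 & y <= 70) | (x <= 70 & y >= 180)
  inC <- (x >= 70 & x <= 290 & y >= x + 110) |
         (x >= 130 & x <= 180 & y <= (7 / 5) * x - 182)
  inD <- (x >= 240 & y >= 70 & y <= 180) |
         (x <= 175 / 3 & y >= 70 & y <= 180) |
         (x >= 175 / 3 & x <= 70 & y >= (6 / 5) * x)
  zone[inA] <- "A"
  zone[is.na(zone) & inE] <- "E"
  zone[is.na(zone) & inC] <- "C"
  zone[is.na(zone) & inD] <- "D"
  zone[is.na(zone)] <- "B"
  zone
}

#' Clarke error grid zone summary
#'
#' @inheritParams mard
#' @return data.frame with one row per zone A--E: `zone`, `count`, `pct`.
#'   Counts sum to the number of pairs; empty zones are reported as 0.
#' @export
cega_summary <- function(estimates, references) {
  z <- factor(clarke_zone(references, estimates), levels = c("A", "B", "C",
                                                             "D", "E"))
  cnt <- as.integer(table(z))
  data.frame(zone = levels(z), count = cnt,
             pct = 100 * cnt / length(z), stringsAsFactors = FALSE)
}

#' FDA accuracy-tier compliance
#'
#' Per-pair accuracy rule keyed on the sensor (estimate) value: for sensor
#' readings below 100 mg/dL the absolute error must be within 20 mg/dL
#' (adjunctive tier) or 10 mg/dL (nonadjunctive tier); at or above
#' 100 mg/dL the relative error must be within 20% (adjunctive) or 10%
#' (nonadjunctive). Nonadjunctive devices may drive insulin dosing without
#' fingerstick confirmation, hence the tighter bound.
#'
#' @inheritParams mard
#' @param mode `"adjunctive"` or `"nonadjunctive"`.
#' @return Percentage of compliant pairs.
#' @export
fda_compliance <- function(estimates, references,
                           mode = c("adjunctive", "nonadjunctive")) {
  mode <- match.arg(mode)
  check_pairs(estimates, references)
  lim_abs <- if (mode == "adjunctive") 20 else 10
  lim_rel <- if (mode == "adjunctive") 0.20 else 0.10
  abs_err <- abs(estimates - references)
  ok <- ifelse(estimates < 100,
               abs_err <= lim_abs,
               abs_err / references <= lim_rel)
  100 * mean(ok)
}

#' Accuracy report for one set of estimates
#'
#' @inheritParams mard
#' @return Object of class `accuracy_report`: number of pairs, MARD,
#'   absolute and relative RMSE, max/min signed relative error, Clarke zone
#'   counts and percentages, and FDA adjunctive/nonadjunctive compliance
#'   fractions.
#' @export
accuracy_report <- function(estimates, references) {
  check_pairs(estimates, references)
  re <- relative_errors(estimates, references)
  structure(list(n_pairs = length(estimates),
                 mard = mard(estimates, references),
                 rmse_abs = rmse(estimates, references, "absolute"),
                 rmse_rel = rmse(estimates, references, "relative"),
                 max_error = max(re), min_error = min(re),
                 zones = cega_summary(estimates, references),
                 fda_adjunctive = fda_compliance(estimates, references,
                                                 "adjunctive"),
                 fda_nonadjunctive = fda_compliance(estimates, references,
                                                    "nonadjunctive")),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Accuracy over %d pairs:\n", x$n_pairs))
  cat(sprintf("  MARD %.1f%%, RMSE %.1f mg/dL (%.1f%% relative)\n",
              x$mard, x$rmse_abs, x$rmse_rel))
  cat(sprintf("  error range [%.1f%%, %.1f%%]\n", x$min_error, x$max_error))
  cat("  Clarke zones:",
      paste(sprintf("%s %.1f%%", x$zones$zone, x$zones$pct), collapse = ", "),
      "\n")
  cat(sprintf("  FDA compliant pairs: %.1f%% adjunctive, %.1f%% nonadjunctive\n",
              x$fda_adjunctive, x$fda_nonadjunctive))
  invisible(x)
}

cluster_range_labels <- function(scheme) {
  b <- scheme$boundaries
  c(sprintf("<=%g", b[1]),
    sprintf("%g-%g", head_plus_one(b), b[-1]),
    sprintf(">%g", b[5]))
}

head_plus_one <- function(b) b[-length(b)] + 1

#' Before/after accuracy report, per cluster and overall
#'
#' Compares the uncorrected (measured vs reference) and corrected
#' (predicted vs reference) accuracy per glucose cluster and over the
#' entire range: relative and absolute RMSE, MARD, and the extreme signed
#' relative errors, plus Clarke zone summaries for both stages.
#'
#' @param measured Measured CGM values, mg/dL.
#' @param predicted Corrected glucose values, mg/dL.
#' @param references Reference glucose values, mg/dL.
#' @param scheme A [cluster_scheme()].
#' @param assign_by Cluster rows are formed from the `"measured"` (default)
#'   or `"reference"` values.
#' @return Object of class `before_after_report`: `$metrics` (7 rows: one
#'   per cluster plus `All`; `NA` metrics for empty clusters),
#'   `$cega_before`, `$cega_after`.
#' @export
before_after_report <- function(measured, predicted, references,
                                scheme = cluster_scheme(),
                                assign_by = c("measured", "reference")) {
  assign_by <- match.arg(assign_by)
  check_pairs(measured, references)
  check_pairs(predicted, references)
  if (length(measured) != length(predicted))
    stop("measured and predicted must be the same length", call. = FALSE)
  k <- assign_cluster(if (assign_by == "measured") measured else references,
                      scheme)
  groups <- c(as.list(0:5), list(0:5))
  labels <- c(as.character(0:5), "All")
  ranges <- c(cluster_range_labels(scheme), "entire range")
  rows <- lapply(seq_along(groups), function(i) {
    sel <- k %in% groups[[i]]
    if (!any(sel))
      return(data.frame(cluster = labels[i], range = ranges[i], n = 0L,
                        rmse_initial = NA_real_, rmse_final = NA_real_,
                        rmse_abs_initial = NA_real_, rmse_abs_final = NA_real_,
                        mard_initial = NA_real_, mard_final = NA_real_,
                        max_error_initial = NA_real_, max_error_final = NA_real_,
                        min_error_initial = NA_real_, min_error_final = NA_real_,
                        stringsAsFactors = FALSE))
    gm <- measured[sel]; gp <- predicted[sel]; gr <- references[sel]
    re0 <- relative_errors(gm, gr); re1 <- relative_errors(gp, gr)
    data.frame(cluster = labels[i], range = ranges[i], n = sum(sel),
               rmse_initial = rmse(gm, gr, "relative"),
               rmse_final = rmse(gp, gr, "relative"),
               rmse_abs_initial = rmse(gm, gr, "absolute"),
               rmse_abs_final = rmse(gp, gr, "absolute"),
               mard_initial = mard(gm, gr), mard_final = mard(gp, gr),
               max_error_initial = max(re0), max_error_final = max(re1),
               min_error_initial = min(re0), min_error_final = min(re1),
               stringsAsFactors = FALSE)
  })
  structure(list(metrics = do.call(rbind, rows),
                 cega_before = cega_summary(measured, references),
                 cega_after = cega_summary(predicted, references),
                 before = accuracy_report(measured, references),
                 after = accuracy_report(predicted, references)),
            class = "before_after_report")
}

#' @export
print.before_after_report <- function(x, ...) {
  m <- x$metrics
  cat("Before/after calibration accuracy (percent unless noted):\n")
  print(format(data.frame(cluster = m$cluster, range = m$range, n = m$n,
                          MARD = sprintf("%.1f -> %.1f", m$mard_initial,
                                         m$mard_final),
                          RMSE = sprintf("%.1f -> %.1f", m$rmse_initial,
                                         m$rmse_final)),
               justify = "left"), row.names = FALSE)
  a <- x$cega_before; b <- x$cega_after
  cat("Clarke zone A:", sprintf("%.1f%% -> %.1f%%", a$pct[1], b$pct[1]), "\n")
  invisible(x)
}

#' Write a before/after report to CSV and markdown
#'
#' @param report A [before_after_report()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "before_after_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "report.csv")
  p2 <- file.path(dir, "cega_summary.csv")
  p3 <- file.path(dir, "report.md")
  utils::write.csv(report$metrics, p1, row.names = FALSE)
  cg <- rbind(cbind(stage = "before", report$cega_before),
              cbind(stage = "after", report$cega_after))
  utils::write.csv(cg, p2, row.names = FALSE)
  md <- c("# Calibration accuracy report", "",
          md_table(report$metrics), "",
          "## Clarke error grid zones", "", md_table(cg))
  writeLines(md, p3)
  invisible(c(p1, p2, p3))
}

md_table <- function(df) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 1, format = "f") else
      as.character(col)
  }, character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(fmt, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, body)
}
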