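#' Knowledge-based glucose cluster scheme
#'
#' Defines the six fixed glucose ranges used to stratify calibration, named
#' after stages of diabetes. With the default thresholds the clusters are
#' hypoglycemia (<= 80 mg/dL), nondiabetic (81--115), prediabetes (116--150),
#' diabetes (151--180), severe diabetes (181--250) and critical diabetes
#' (> 250 mg/dL). Intervals are half-open at the top: a glucose value equal
#' to a threshold belongs to the lower cluster.
#'
#' @param boundaries Strictly increasing positive thresholds (mg/dL)
#'   separating the six clusters; length 5.
#' @param names Labels for the six clusters; length 6.
#' @return An object of class `cluster_scheme`.
#' @examples
#' sch <- cluster_scheme()
#' assign_cluster(c(75, 100, 300), sch)
#' @export
cluster_scheme <- function(boundaries = c(80, 115, 150, 180, 250),
                           names = c("hypoglycemia", "nondiabetic",
                                     "prediabetes", "diabetes",
                                     "severe diabetes", "critical diabetes")) {
  if (length(boundaries) != 5L || any(!is.finite(boundaries)))
    stop("boundaries must be 5 finite thresholds", call. = FALSE)
  if (any(boundaries <= 0) || any(diff(boundaries) <= 0))
    stop("boundaries must be positive and strictly increasing", call. = FALSE)
  if (length(names) != 6L || anyDuplicated(names))
    stop("names must be 6 distinct labels", call. = FALSE)
  structure(list(boundaries = as.numeric(boundaries),
                 names = as.character(names)),
            class = "cluster_scheme")
}

#' @export
print.cluster_scheme <- function(x, ...) {
  lo <- c(0, x$boundaries)
  hi <- c(x$boundaries, Inf)
  rng <- ifelse(is.infinite(hi), sprintf("> %g", lo),
                sprintf("(%g, %g]", lo, hi))
  rng[1] <- sprintf("<= %g", hi[1])
  cat("Glucose cluster scheme (mg/dL):\n")
  for (k in 1:6)
    cat(sprintf("  cluster %d: %-18s %s\n", k - 1L, x$names[k], rng[k]))
  invisible(x)
}

#' Assign glucose values to clusters
#'
#' @param g Numeric vector of glucose values (mg/dL), all > 0.
#' @param scheme A [cluster_scheme()].
#' @return Integer vector of cluster indices in 0--5.
#' @export
assign_cluster <- function(g, scheme = cluster_scheme()) {
  stopifnot(inherits(scheme, "cluster_scheme"))
  if (!is.numeric(g) || !length(g))
    stop("g must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(g)) || any(g <= 0))
    stop("glucose values must be finite and > 0", call. = FALSE)
  # value equal to a threshold stays in the lower cluster
  idx <- rowSums(outer(g, scheme$boundaries, FUN = ">"))
  as.integer(idx)
}

#' Partition readings by glucose cluster
#'
#' Splits a paired-readings table into the six cluster sub-tables. Cluster
#' membership is taken from the measured value `g_m` by default -- the value
#' available at deployment time -- or from the reference `g_r` for
#' experimentation.
#'
#' @param readings Paired-readings data.frame (see [reading_columns()]).
#' @param scheme A [cluster_scheme()].
#' @param assign_by `"measured"` (default) or `"reference"`.
#' @return Named list of six data.frames (one per cluster, possibly empty),
#'   with an attribute `counts` giving per-cluster sizes.
#' @export
partition_readings <- function(readings, scheme = cluster_scheme(),
                               assign_by = c("measured", "reference")) {
  assign_by <- match.arg(assign_by)
  validate_readings(readings, require_reference = assign_by == "reference")
  g <- if (assign_by == "measured") readings$g_m else readings$g_r
  k <- if (nrow(readings)) assign_cluster(g, scheme) else integer(0)
  out <- lapply(0:5, function(i) readings[k == i, , drop = FALSE])
  names(out) <- scheme$names
  attr(out, "counts") <- vapply(out, nrow, integer(1))
  attr(out, "cluster_index") <- k
  out
}

#' Read / write a cluster scheme as JSON
#'
#' @param scheme A [cluster_scheme()].
#' @param path File path.
#' @return `read_cluster_scheme` returns a [cluster_scheme()];
#'   `write_cluster_scheme` returns `path` invisibly.
#' @export
write_cluster_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "cluster_scheme"))
  jsonlite::write_json(list(boundaries = scheme$boundaries,
                            names = scheme$names),
                       path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cluster_scheme
#' @export
read_cluster_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cluster_scheme(boundaries = x$boundaries, names = x$names)
}
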