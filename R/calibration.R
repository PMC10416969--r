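#' Initial sensor errors
#'
#' The regression target of the calibrator: the signed difference between
#' the measured CGM value and the invasive reference, `d = g_m - g_r`
#' (mg/dL).
#'
#' @param readings Paired-readings data.frame.
#' @return Numeric vector of per-reading errors.
#' @export
compute_initial_errors <- function(readings) {
  validate_readings(readings)
  readings$g_m - readings$g_r
}

#' Train/test split settings
#'
#' @param train_fraction Fraction of each cluster used for training
#'   (default 0.7, i.e. a 70:30 split).
#' @param seed Seed for the split draw.
#' @return A list of class `calibration_split`.
#' @export
calibration_split <- function(train_fraction = 0.7, seed = 42) {
  stop_if_not_scalar_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  stop_if_not_scalar_number(seed, "seed")
  structure(list(train_fraction = train_fraction, seed = as.integer(seed)),
            class = "calibration_split")
}

#' Fit one cluster's error-prediction model
#'
#' Splits the cluster's readings into train and test sets, standardizes the
#' eight features (measured glucose plus seven covariates) on the training
#' split only, fits the configured regressor to predict the sensor error
#' `d = g_m - g_r`, and evaluates the corrected glucose on the held-out
#' split. Clusters with fewer than `min_samples` readings return an identity
#' model (predicted error 0) with a warning rather than an error.
#'
#' @param readings Readings of one cluster.
#' @param config A [regressor_config()].
#' @param split A [calibration_split()].
#' @param min_samples Minimum cluster size to attempt a fit (default 10).
#' @param seed Seed for the stochastic parts of training (weight init,
#'   bootstrap draws); the split uses `split$seed`.
#' @return Object of class `fitted_cluster_model`: the regressor, the
#'   feature scaling parameters, held-out predictions and metrics
#'   (`heldout$rmse` is relative RMSE in %, `heldout$rmse_abs` mg/dL,
#'   `heldout$mard`, `heldout$max_error`, `heldout$min_error` in %), and the
#'   training loss curve where the family records one.
#' @export
fit_cluster_model <- function(readings, config, split = calibration_split(),
                              min_samples = 10, seed = 1) {
  validate_readings(readings)
  stopifnot(inherits(config, "regressor_config"),
            inherits(split, "calibration_split"))
  n <- nrow(readings)
  if (n < min_samples) {
    warning(sprintf("cluster has %d readings (< min_samples = %d); using identity model",
                    n, min_samples), call. = FALSE)
    return(identity_cluster_model(n))
  }
  n_train <- max(1L, min(n - 1L, round(split$train_fraction * n)))
  train_idx <- with_seed(split$seed, sort(sample.int(n, n_train)))
  test_idx <- setdiff(seq_len(n), train_idx)

  feats <- feature_matrix(readings)
  d <- compute_initial_errors(readings)
  center <- colMeans(feats[train_idx, , drop = FALSE])
  scale <- apply(feats[train_idx, , drop = FALSE], 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  xs <- sweep(sweep(feats, 2, center), 2, scale, "/")

  reg <- fit_regressor(config, xs[train_idx, , drop = FALSE], d[train_idx],
                       seed = seed)
  d_pred <- predict(reg, xs[test_idx, , drop = FALSE])
  g_m <- readings$g_m[test_idx]
  g_r <- readings$g_r[test_idx]
  g_p <- pmax(g_m - d_pred, 1)

  structure(list(identity = FALSE, config = config, regressor = reg,
                 center = center, scale = scale,
                 n = n, n_train = n_train, n_test = length(test_idx),
                 heldout = list(index = test_idx, d_pred = d_pred, g_p = g_p,
                                rmse = rmse(g_p, g_r, mode = "relative"),
                                rmse_abs = rmse(g_p, g_r, mode = "absolute"),
                                mard = mard(g_p, g_r),
                                max_error = max(relative_errors(g_p, g_r)),
                                min_error = min(relative_errors(g_p, g_r))),
                 loss_curve = if (inherits(reg$model, "cgm_mlp"))
                   reg$model$loss_curve),
            class = "fitted_cluster_model")
}

identity_cluster_model <- function(n = 0L) {
  structure(list(identity = TRUE, config = NULL, regressor = NULL,
                 center = NULL, scale = NULL, n = n, n_train = 0L,
                 n_test = 0L, heldout = NULL, loss_curve = NULL),
            class = "fitted_cluster_model")
}

#' @export
print.fitted_cluster_model <- function(x, ...) {
  if (x$identity) {
    cat("Identity cluster model (predicted error 0)\n")
  } else {
    cat(sprintf("Fitted cluster model: %s\n  n=%d (train %d / test %d), held-out MARD %.2f%%, RMSE %.2f%%\n",
                format(x$config), x$n, x$n_train, x$n_test,
                x$heldout$mard, x$heldout$rmse))
  }
  invisible(x)
}

# Predicted error for arbitrary readings. Accepts the fitted model, a plain
# function(readings) -> d_pred (used as an oracle in validation), or an
# identity model.
predict_cluster_error <- function(model, readings) {
  if (is.function(model)) return(as.numeric(model(readings)))
  stopifnot(inherits(model, "fitted_cluster_model"))
  if (model$identity) return(rep(0, nrow(readings)))
  feats <- feature_matrix(readings)
  xs <- sweep(sweep(feats, 2, model$center), 2, model$scale, "/")
  as.numeric(predict(model$regressor, xs))
}

#' Calibrator ensemble
#'
#' Bundles the cluster scheme with one fitted error model per cluster.
#' Clusters without a model fall back to the identity correction
#' (predicted error 0). A model may also be given as a plain
#' `function(readings)` returning predicted errors, which is how oracle
#' corrections are expressed in validation.
#'
#' @param scheme A [cluster_scheme()].
#' @param models List of up to 6 models ([fit_cluster_model()] outputs,
#'   functions, or `NULL` for identity), in cluster order 0--5.
#' @param assign_by Whether deployment assigns clusters from the
#'   `"measured"` (default) or `"reference"` value.
#' @param metadata Optional free-form list (split seed, selection notes).
#' @return Object of class `calibrator_ensemble`.
#' @export
calibrator_ensemble <- function(scheme = cluster_scheme(), models = list(),
                                assign_by = c("measured", "reference"),
                                metadata = list()) {
  assign_by <- match.arg(assign_by)
  stopifnot(inherits(scheme, "cluster_scheme"))
  full <- vector("list", 6L)
  for (k in seq_len(6L)) {
    m <- if (k <= length(models)) models[[k]] else NULL
    if (is.null(m)) m <- identity_cluster_model()
    if (!is.function(m) && !inherits(m, "fitted_cluster_model"))
      stop("models must be fitted_cluster_model objects, functions or NULL",
           call. = FALSE)
    full[[k]] <- m
  }
  structure(list(scheme = scheme, models = full, assign_by = assign_by,
                 metadata = metadata),
            class = "calibrator_ensemble")
}

#' Identity ensemble (no-op correction)
#'
#' @param scheme A [cluster_scheme()].
#' @return A [calibrator_ensemble()] whose predicted error is 0 everywhere.
#' @export
identity_ensemble <- function(scheme = cluster_scheme()) {
  calibrator_ensemble(scheme, metadata = list(kind = "identity"))
}

#' @export
print.calibrator_ensemble <- function(x, ...) {
  kind <- vapply(x$models, function(m) {
    if (is.function(m)) "oracle/function"
    else if (m$identity) "identity"
    else format(m$config)
  }, "")
  cat("Calibrator ensemble (cluster assignment by", x$assign_by, "value):\n")
  for (k in 1:6)
    cat(sprintf("  cluster %d (%s): %s\n", k - 1L, x$scheme$names[k], kind[k]))
  invisible(x)
}

#' Correct measured CGM values
#'
#' Applies the ensemble: each reading is assigned to a cluster, that
#' cluster's model predicts the sensor error `d_pred`, and the corrected
#' (predicted) glucose is `g_p = g_m - d_pred`, floored at 1 mg/dL so
#' downstream relative statistics stay defined.
#'
#' @param readings Paired-readings data.frame (the reference column is only
#'   required when the ensemble assigns clusters by reference value).
#' @param ensemble A [calibrator_ensemble()].
#' @return Numeric vector `g_p`, one value per reading.
#' @export
correct <- function(readings, ensemble) {
  if (!inherits(ensemble, "calibrator_ensemble"))
    stop("ensemble must be a calibrator_ensemble", call. = FALSE)
  validate_readings(readings,
                    require_reference = ensemble$assign_by == "reference")
  if (!nrow(readings)) return(numeric(0))
  g_assign <- if (ensemble$assign_by == "measured") readings$g_m
              else readings$g_r
  k <- assign_cluster(g_assign, ensemble$scheme)
  d_pred <- numeric(nrow(readings))
  for (kk in sort(unique(k))) {
    sel <- which(k == kk)
    d_pred[sel] <- predict_cluster_error(ensemble$models[[kk + 1L]],
                                         readings[sel, , drop = FALSE])
  }
  pmax(readings$g_m - d_pred, 1)
}

#' Fit one configuration across all clusters
#'
#' Partitions the readings, fits `config` in every cluster with at least
#' `min_samples` readings (identity elsewhere), and returns the resulting
#' ensemble together with the pooled held-out evaluation.
#'
#' @inheritParams fit_cluster_model
#' @param scheme A [cluster_scheme()].
#' @param assign_by Cluster assignment mode, see [partition_readings()].
#' @return List with `ensemble`, per-cluster `models`, and `heldout`
#'   (data.frame of held-out `g_m`, `g_r`, `g_p`, `cluster`).
#' @export
fit_cluster_ensemble <- function(readings, config, scheme = cluster_scheme(),
                                 split = calibration_split(),
                                 min_samples = 10,
                                 assign_by = c("measured", "reference"),
                                 seed = 1) {
  assign_by <- match.arg(assign_by)
  parts <- partition_readings(readings, scheme, assign_by)
  models <- vector("list", 6L)
  held <- list()
  for (k in 1:6) {
    sub <- parts[[k]]
    if (nrow(sub) < min_samples) {
      models[[k]] <- identity_cluster_model(nrow(sub))
      next
    }
    m <- fit_cluster_model(sub, config, split = split,
                           min_samples = min_samples,
                           seed = seed + k)
    models[[k]] <- m
    held[[length(held) + 1L]] <-
      data.frame(cluster = k - 1L,
                 g_m = sub$g_m[m$heldout$index],
                 g_r = sub$g_r[m$heldout$index],
                 g_p = m$heldout$g_p)
  }
  ens <- calibrator_ensemble(scheme, models, assign_by = assign_by,
                             metadata = list(split = unclass(split),
                                             config = format(config)))
  list(ensemble = ens, models = models,
       heldout = if (length(held)) do.call(rbind, held) else
         data.frame(cluster = integer(0), g_m = numeric(0),
                    g_r = numeric(0), g_p = numeric(0)))
}

#' Screen the six model families
#'
#' Runs the clustered calibration pipeline once per family with that
#' family's default hyperparameters and summarizes held-out accuracy:
#' MARD and the percentage of held-out pairs in each Clarke zone. Rows are
#' sorted by MARD in decreasing order (worst family first). A family whose
#' fit fails contributes a row of `NA` metrics with the error message in
#' the `note` column.
#'
#' @param readings Paired-readings data.frame.
#' @param scheme A [cluster_scheme()].
#' @param configs Named list of [regressor_config()]s, one per family
#'   (default [default_family_configs()]).
#' @param split A [calibration_split()].
#' @param min_samples Minimum cluster size (identity fallback below it).
#' @param seed Seed for stochastic trainers.
#' @return data.frame with columns `family`, `mard`, `zone_A`..`zone_E`
#'   (percentages) and `note`.
#' @export
compare_model_families <- function(readings, scheme = cluster_scheme(),
                                   configs = default_family_configs(),
                                   split = calibration_split(),
                                   min_samples = 10, seed = 1) {
  validate_readings(readings)
  rows <- lapply(names(configs), function(fam) {
    res <- tryCatch({
      fit <- fit_cluster_ensemble(readings, configs[[fam]], scheme,
                                  split = split, min_samples = min_samples,
                                  seed = seed)
      h <- fit$heldout
      if (!nrow(h)) {  # all clusters under min_samples: no-op correction
        g_p <- correct(readings, fit$ensemble)
        h <- data.frame(g_r = readings$g_r, g_p = g_p)
      }
      z <- cega_summary(h$g_p, h$g_r)
      data.frame(family = fam, mard = mard(h$g_p, h$g_r),
                 zone_A = z$pct[1], zone_B = z$pct[2], zone_C = z$pct[3],
                 zone_D = z$pct[4], zone_E = z$pct[5], note = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(family = fam, mard = NA_real_, zone_A = NA_real_,
                 zone_B = NA_real_, zone_C = NA_real_, zone_D = NA_real_,
                 zone_E = NA_real_, note = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mard, out$family, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Save / load a calibrator ensemble archive
#'
#' Writes the ensemble (scheme, per-cluster configs, fitted weights and
#' scalers) as a single RDS archive.
#'
#' @param ensemble A [calibrator_ensemble()].
#' @param path File path (conventionally `.rds`).
#' @return `save_ensemble` returns `path` invisibly; `load_ensemble` the
#'   restored ensemble.
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "calibrator_ensemble"))
  if (any(vapply(ensemble$models, is.function, TRUE)))
    stop("function-backed (oracle) models cannot be archived", call. = FALSE)
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "calibrator_ensemble"))
    stop("file does not contain a calibrator_ensemble", call. = FALSE)
  x
}
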