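#' MLP hyperparameter grid
#'
#' The Cartesian search space for the per-cluster MLP regressor. The
#' default axes are: seven hidden-layer options (20, 100 or 200 perceptrons
#' in a single layer; 10 or 20 in each of two layers; 10 or 20 in each of
#' four layers), six initial learning rates, three learning-rate schedules,
#' two activations, three solvers, three iteration counts and two momentum
#' values -- 7 x 6 x 3 x 2 x 3 x 3 x 2 = 4536 combinations. Momentum only
#' affects the SGD solver but remains a grid axis for all solvers, so the
#' grid cardinality is the full product.
#'
#' @param hidden_layer_options List of integer vectors (layer sizes).
#' @param learning_rates Initial learning rates.
#' @param learning_types Learning-rate schedules.
#' @param activations Activation functions.
#' @param solvers Training solvers.
#' @param iteration_counts Maximum iteration options.
#' @param momenta Momentum options.
#' @return Object of class `hyperparameter_grid`.
#' @examples
#' grid_size(hyperparameter_grid())  # 4536
#' @export
hyperparameter_grid <- function(hidden_layer_options =
                                  list(20, 100, 200, c(10, 10), c(20, 20),
                                       rep(10, 4), rep(20, 4)),
                                learning_rates = c(0.001, 0.01, 0.05,
                                                   0.1, 0.5, 1),
                                learning_types = c("constant", "invscaling",
                                                   "adaptive"),
                                activations = c("relu", "tanh"),
                                solvers = c("lbfgs", "sgd", "adam"),
                                iteration_counts = c(100, 500, 1000),
                                momenta = c(0.9, 0.99)) {
  axes <- list(hidden_layer_options = hidden_layer_options,
               learning_rates = learning_rates,
               learning_types = learning_types,
               activations = activations,
               solvers = solvers,
               iteration_counts = iteration_counts,
               momenta = momenta)
  for (nm in names(axes))
    if (!length(axes[[nm]]))
      stop(sprintf("grid axis '%s' is empty", nm), call. = FALSE)
  if (!is.list(axes$hidden_layer_options))
    axes$hidden_layer_options <- as.list(axes$hidden_layer_options)
  structure(axes, class = "hyperparameter_grid")
}

#' Number of configurations in a grid
#'
#' @param grid A [hyperparameter_grid()].
#' @return Integer product of the axis sizes.
#' @export
grid_size <- function(grid) {
  stopifnot(inherits(grid, "hyperparameter_grid"))
  prod(vapply(unclass(grid), length, 0L))
}

#' @export
print.hyperparameter_grid <- function(x, ...) {
  cat("MLP hyperparameter grid:\n")
  for (nm in names(unclass(x))) {
    vals <- x[[nm]]
    txt <- if (is.list(vals))
      paste(vapply(vals, function(v) paste(v, collapse = "x"), ""),
            collapse = ", ")
    else paste(vals, collapse = ", ")
    cat(sprintf("  %-21s (%d): %s\n", nm, length(vals), txt))
  }
  cat("  total configurations:", grid_size(x), "\n")
  invisible(x)
}

#' Enumerate a hyperparameter grid
#'
#' Produces every configuration of the Cartesian product in a fixed,
#' deterministic nesting order: hidden layers outermost, then learning
#' rate, learning-rate type, activation, iteration count, momentum, and
#' solver innermost (the solver axis varies fastest).
#'
#' @param grid A [hyperparameter_grid()].
#' @return List of [regressor_config()] objects, length [grid_size()].
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "hyperparameter_grid"))
  idx <- expand.grid(solver = seq_along(grid$solvers),
                     momentum = seq_along(grid$momenta),
                     max_iter = seq_along(grid$iteration_counts),
                     activation = seq_along(grid$activations),
                     learning_type = seq_along(grid$learning_types),
                     learning_rate = seq_along(grid$learning_rates),
                     hidden = seq_along(grid$hidden_layer_options))
  lapply(seq_len(nrow(idx)), function(i) {
    r <- idx[i, ]
    regressor_config("MLP",
                     hidden_layers = grid$hidden_layer_options[[r$hidden]],
                     learning_rate_init = grid$learning_rates[r$learning_rate],
                     learning_rate_type = grid$learning_types[r$learning_type],
                     activation = grid$activations[r$activation],
                     solver = grid$solvers[r$solver],
                     max_iterations = grid$iteration_counts[r$max_iter],
                     momentum = grid$momenta[r$momentum])
  })
}

config_log_row <- function(config) {
  hp <- config$hyperparameters
  data.frame(hidden = paste(hp$hidden_layers, collapse = "x"),
             learning_rate = hp$learning_rate_init,
             learning_type = hp$learning_rate_type,
             activation = hp$activation,
             solver = hp$solver,
             iterations = as.integer(hp$max_iterations),
             momentum = hp$momentum,
             stringsAsFactors = FALSE)
}

# Lexicographic winner: smallest RMSE, then smallest MARD, then first in
# enumeration order. NA metrics (failed candidates) always lose.
select_best_candidate <- function(log) {
  stopifnot(all(c("rmse", "mard") %in% names(log)))
  r <- log$rmse; m <- log$mard
  r[is.na(r)] <- Inf; m[is.na(m)] <- Inf
  ord <- order(r, m, seq_along(r))
  ord[1]
}

#' Grid search over one cluster
#'
#' Trains every candidate configuration on the cluster's training split and
#' scores the corrected glucose on the held-out split; the winner is the
#' candidate with the smallest held-out RMSE, ties broken by smallest MARD
#' and then by enumeration order. The same train/test split is used for
#' every candidate; per-candidate seeds (weight initialization) are derived
#' deterministically from the cluster index and candidate position. An
#' optional accuracy goal stops the search early once a candidate's MARD
#' meets it.
#'
#' @param readings Readings of one cluster (must meet `min_samples`).
#' @param grid A [hyperparameter_grid()].
#' @param split A [calibration_split()].
#' @param goal Optional MARD (%) early-stop threshold; `NULL` (default)
#'   evaluates the full grid.
#' @param min_samples Minimum cluster size.
#' @param cluster_index Cluster index 0--5, used for seed derivation and
#'   bookkeeping.
#' @return Object of class `selection_result`: `best_config`, `best_model`,
#'   `best_index`, and `log` (one row per evaluated candidate with its
#'   hyperparameters and held-out `rmse` (relative, %), `rmse_abs` (mg/dL),
#'   `mard`, `max_error`, `min_error`).
#' @export
grid_search_cluster <- function(readings, grid = hyperparameter_grid(),
                                split = calibration_split(), goal = NULL,
                                min_samples = 10, cluster_index = 0L) {
  validate_readings(readings)
  stopifnot(inherits(grid, "hyperparameter_grid"))
  if (nrow(readings) < min_samples)
    stop(sprintf("cluster has %d readings; need at least %d for grid search",
                 nrow(readings), min_samples), call. = FALSE)
  configs <- enumerate_grid(grid)
  rows <- vector("list", length(configs))
  models <- vector("list", length(configs))
  n_eval <- 0L
  for (i in seq_along(configs)) {
    seed_i <- 1000L * (as.integer(cluster_index) + 1L) + i
    fit <- tryCatch(
      fit_cluster_model(readings, configs[[i]], split = split,
                        min_samples = min_samples, seed = seed_i),
      error = function(e) e)
    n_eval <- i
    if (inherits(fit, "error")) {
      rows[[i]] <- cbind(config_log_row(configs[[i]]),
                         data.frame(rmse = NA_real_, rmse_abs = NA_real_,
                                    mard = NA_real_, max_error = NA_real_,
                                    min_error = NA_real_,
                                    note = conditionMessage(fit),
                                    stringsAsFactors = FALSE))
      next
    }
    models[[i]] <- fit
    h <- fit$heldout
    rows[[i]] <- cbind(config_log_row(configs[[i]]),
                       data.frame(rmse = h$rmse, rmse_abs = h$rmse_abs,
                                  mard = h$mard, max_error = h$max_error,
                                  min_error = h$min_error, note = "",
                                  stringsAsFactors = FALSE))
    if (!is.null(goal) && is.finite(h$mard) && h$mard <= goal) break
  }
  log <- do.call(rbind, rows[seq_len(n_eval)])
  rownames(log) <- NULL
  if (all(is.na(log$rmse)))
    stop("all grid candidates failed to train; see the candidate log",
         call. = FALSE)
  best <- select_best_candidate(log)
  structure(list(cluster = as.integer(cluster_index),
                 best_config = configs[[best]],
                 best_model = models[[best]],
                 best_index = best,
                 log = log),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Grid search, cluster %d: %d candidates evaluated\n",
              x$cluster, nrow(x$log)))
  cat("  winner:", format(x$best_config), "\n")
  cat(sprintf("  held-out RMSE %.2f%%, MARD %.2f%%\n",
              x$log$rmse[x$best_index], x$log$mard[x$best_index]))
  invisible(x)
}

#' Grid search across all clusters
#'
#' Partitions the readings by cluster, runs [grid_search_cluster()] in every
#' cluster with at least `min_samples` readings (clusters below that get an
#' identity-fallback row), and assembles the winning models into a
#' [calibrator_ensemble()].
#'
#' @param readings Paired-readings data.frame.
#' @param scheme A [cluster_scheme()].
#' @param grid A [hyperparameter_grid()].
#' @param split A [calibration_split()].
#' @param goal Optional early-stop MARD (%) per cluster.
#' @param min_samples Minimum cluster size.
#' @param assign_by Cluster assignment mode (see [partition_readings()]).
#' @return Object of class `cgm_selection`: `ensemble`, per-cluster
#'   `results` (`selection_result` or `NULL` for fallback clusters), and
#'   `table` -- the selection report with one row per cluster (`cluster`,
#'   `range`, `n`, `hyperparameters`, `fallback`, held-out `rmse`, `mard`).
#' @export
select_all_clusters <- function(readings, scheme = cluster_scheme(),
                                grid = hyperparameter_grid(),
                                split = calibration_split(), goal = NULL,
                                min_samples = 10,
                                assign_by = c("measured", "reference")) {
  assign_by <- match.arg(assign_by)
  parts <- partition_readings(readings, scheme, assign_by)
  ranges <- cluster_range_labels(scheme)
  models <- vector("list", 6L)
  results <- vector("list", 6L)
  rows <- vector("list", 6L)
  for (k in 1:6) {
    sub <- parts[[k]]
    if (nrow(sub) < min_samples) {
      models[[k]] <- identity_cluster_model(nrow(sub))
      rows[[k]] <- data.frame(cluster = k - 1L, range = ranges[k],
                              n = nrow(sub), hyperparameters = "identity",
                              fallback = TRUE, rmse = NA_real_,
                              mard = NA_real_, stringsAsFactors = FALSE)
      next
    }
    res <- grid_search_cluster(sub, grid, split = split, goal = goal,
                               min_samples = min_samples,
                               cluster_index = k - 1L)
    results[[k]] <- res
    models[[k]] <- res$best_model
    rows[[k]] <- data.frame(cluster = k - 1L, range = ranges[k],
                            n = nrow(sub),
                            hyperparameters = format(res$best_config),
                            fallback = FALSE,
                            rmse = res$log$rmse[res$best_index],
                            mard = res$log$mard[res$best_index],
                            stringsAsFactors = FALSE)
  }
  ens <- calibrator_ensemble(scheme, models, assign_by = assign_by,
                             metadata = list(split = unclass(split),
                                             grid_size = grid_size(grid),
                                             selection = "lexicographic (rmse, mard)"))
  structure(list(ensemble = ens, results = results,
                 table = do.call(rbind, rows)),
            class = "cgm_selection")
}

#' @export
print.cgm_selection <- function(x, ...) {
  cat("Per-cluster hyperparameter selection:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Read / write a hyperparameter grid as JSON
#'
#' @param grid A [hyperparameter_grid()].
#' @param path File path.
#' @return `read_grid` returns a [hyperparameter_grid()]; `write_grid`
#'   returns `path` invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "hyperparameter_grid"))
  jsonlite::write_json(unclass(grid), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hyperparameter_grid(hidden_layer_options = lapply(x$hidden_layer_options,
                                                    as.integer),
                      learning_rates = x$learning_rates,
                      learning_types = x$learning_types,
                      activations = x$activations,
                      solvers = x$solvers,
                      iteration_counts = x$iteration_counts,
                      momenta = x$momenta)
}
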