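test_that("grid cardinality is the product of the axis sizes", {
  expect_identical(grid_size(hyperparameter_grid()), 4536)
  expect_length(hyperparameter_grid()$hidden_layer_options, 7L)
  # halving one axis halves the product
  expect_identical(grid_size(hyperparameter_grid(momenta = 0.9)), 2268)
  # singleton product
  g1 <- hyperparameter_grid(hidden_layer_options = list(5),
                            learning_rates = 0.1,
                            learning_types = "constant",
                            activations = "relu", solvers = "adam",
                            iteration_counts = 50, momenta = 0.9)
  expect_identical(grid_size(g1), 1)
  expect_length(enumerate_grid(g1), 1L)
  expect_error(hyperparameter_grid(solvers = character(0)), "solvers")
})

test_that("enumeration covers random grids without duplicates, solver varying fastest", {
  set.seed(77)
  for (rep in 1:5) {
    g <- hyperparameter_grid(
      hidden_layer_options = lapply(seq_len(sample(1:3, 1)),
                                    function(i) sample(5:20, i)),
      learning_rates = sort(runif(sample(1:2, 1), 0.001, 0.5)),
      learning_types = sample(c("constant", "invscaling", "adaptive"),
                              sample(1:2, 1)),
      activations = sample(c("relu", "tanh"), sample(1:2, 1)),
      solvers = sample(c("lbfgs", "sgd", "adam"), sample(1:3, 1)),
      iteration_counts = sample(c(50, 100, 200), sample(1:2, 1)),
      momenta = sample(c(0.9, 0.99), sample(1:2, 1)))
    cfgs <- enumerate_grid(g)
    expect_length(cfgs, grid_size(g))
    expect_identical(anyDuplicated(vapply(cfgs, format, "")), 0L)
  }
  # nesting order: innermost axis (solver) cycles first, hidden layers last
  g2 <- hyperparameter_grid(hidden_layer_options = list(5, 10),
                            learning_rates = 0.1,
                            learning_types = "constant",
                            activations = "relu",
                            solvers = c("lbfgs", "adam"),
                            iteration_counts = 100, momenta = 0.9)
  cfgs2 <- enumerate_grid(g2)
  expect_identical(vapply(cfgs2, function(c) c$hyperparameters$solver, ""),
                   c("lbfgs", "adam", "lbfgs", "adam"))
  expect_identical(vapply(cfgs2, function(c) c$hyperparameters$hidden_layers,
                          0), c(5, 5, 10, 10))
})

test_that("the winner minimizes RMSE with MARD and enumeration order as tie-breaks", {
  sb <- cgmcal:::select_best_candidate
  expect_identical(sb(data.frame(rmse = c(10, 12), mard = c(9, 4))), 1L)
  expect_identical(sb(data.frame(rmse = c(10, 10), mard = c(9, 5))), 2L)
  expect_identical(sb(data.frame(rmse = c(10, 10), mard = c(5, 5))), 1L)
  expect_identical(sb(data.frame(rmse = c(NA, 20), mard = c(NA, 30))), 2L)
})

test_that("grid search over a cluster matches brute-force lexicographic minimization", {
  lin <- function(r) 0.05 * r$g_r + 1.5 * r$x2 - 3
  r <- make_cluster_readings(80, c(116, 150), lin, seed = 10)
  sel <- grid_search_cluster(r, reduced_mlp_grid(), cluster_index = 2L)
  log <- sel$log
  expect_identical(nrow(log), 8L)  # full log, no early stop
  # independent brute-force scan of the candidate log
  best <- 1L
  for (i in seq_len(nrow(log))) {
    if (log$rmse[i] < log$rmse[best] ||
        (log$rmse[i] == log$rmse[best] && log$mard[i] < log$mard[best]))
      best <- i
  }
  expect_identical(sel$best_index, best)
  expect_identical(format(sel$best_config),
                   with(log[best, ], sprintf(
                     "MLP(hidden=%s, lr=%g, %s, %s, %s, iter=%d, momentum=%g)",
                     hidden, learning_rate, learning_type, activation,
                     solver, iterations, momentum)))
})

test_that("an accuracy goal stops the search early; rerunning reproduces the winner", {
  r <- make_cluster_readings(60, c(116, 150), function(r) 12, seed = 4)
  sel <- grid_search_cluster(r, reduced_mlp_grid(), goal = 50)
  expect_lt(nrow(sel$log), 8L)  # constant error is met immediately
  a <- grid_search_cluster(r, reduced_mlp_grid())
  b <- grid_search_cluster(r, reduced_mlp_grid())
  expect_identical(format(a$best_config), format(b$best_config))
  expect_identical(a$log, b$log)
  expect_error(grid_search_cluster(r[1:4, ], reduced_mlp_grid()),
               "at least")
})

test_that("select_all_clusters reports one row per cluster and flags fallbacks", {
  coh <- generate_cohort(cohort_config(duration_days = 6, seed = 20))
  keep <- coh$readings[coh$readings$g_m <= 250, ]  # empty critical cluster
  g1 <- hyperparameter_grid(hidden_layer_options = list(10),
                            learning_rates = 0.05,
                            learning_types = "constant",
                            activations = "relu", solvers = "lbfgs",
                            iteration_counts = 200, momenta = 0.9)
  sel <- select_all_clusters(keep, grid = g1)
  expect_identical(nrow(sel$table), 6L)
  expect_identical(sel$table$cluster, 0:5)
  expect_true(sel$table$fallback[6])
  expect_identical(sel$table$hyperparameters[6], "identity")
  expect_false(any(sel$table$fallback[sel$table$n >= 10]))
  # the ensemble still covers all six clusters
  expect_length(sel$ensemble$models, 6L)
})

test_that("grids round-trip through JSON", {
  g <- reduced_mlp_grid()
  p <- withr::local_tempfile(fileext = ".json")
  write_grid(g, p)
  back <- read_grid(p)
  expect_identical(grid_size(back), grid_size(g))
  expect_identical(vapply(enumerate_grid(back), format, ""),
                   vapply(enumerate_grid(g), format, ""))
})
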