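#' Error-regressor configuration
#'
#' A hyperparameter point for one of the six supported model families. For
#' the MLP family the hyperparameters mirror the grid-search axes:
#' `hidden_layers` (integer vector of layer sizes), `learning_rate_init`,
#' `learning_rate_type` (constant / invscaling / adaptive), `activation`
#' (relu / tanh), `solver` (lbfgs / sgd / adam), `max_iterations` and
#' `momentum` (used by the SGD solver; ignored, but carried, by the others).
#' Other families take their library's hyperparameters (e.g. `k` for KNN,
#' `ntree` for RF, `n_estimators` for AdaBoost, `cost`/`epsilon` for SVR,
#' rpart control fields for DT).
#'
#' @param family One of `"MLP"`, `"SVR"`, `"KNN"`, `"DT"`, `"RF"`,
#'   `"AdaBoost"`.
#' @param ... Family-specific hyperparameters.
#' @return An object of class `regressor_config`.
#' @export
regressor_config <- function(family = c("MLP", "SVR", "KNN", "DT", "RF",
                                        "AdaBoost"), ...) {
  family <- match.arg(family)
  hp <- list(...)
  if (family == "MLP") {
    defaults <- list(hidden_layers = c(100L), learning_rate_init = 0.001,
                     learning_rate_type = "constant", activation = "relu",
                     solver = "adam", max_iterations = 200L, momentum = 0.9)
    hp <- utils::modifyList(defaults, hp)
    if (any(hp$hidden_layers < 1))
      stop("hidden_layers must be positive", call. = FALSE)
    if (hp$learning_rate_init <= 0 || hp$max_iterations <= 0 ||
        hp$momentum < 0)
      stop("MLP hyperparameters must be positive", call. = FALSE)
  }
  structure(list(family = family, hyperparameters = hp),
            class = "regressor_config")
}

#' @export
print.regressor_config <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.regressor_config <- function(x, ...) {
  hp <- x$hyperparameters
  if (x$family == "MLP") {
    sprintf("MLP(hidden=%s, lr=%g, %s, %s, %s, iter=%d, momentum=%g)",
            paste(hp$hidden_layers, collapse = "x"), hp$learning_rate_init,
            hp$learning_rate_type, hp$activation, hp$solver,
            as.integer(hp$max_iterations), hp$momentum)
  } else if (length(hp)) {
    sprintf("%s(%s)", x$family,
            paste(names(hp), vapply(hp, function(v)
              paste(format(v), collapse = "x"), ""), sep = "=",
              collapse = ", "))
  } else sprintf("%s(defaults)", x$family)
}

#' Default configuration for each model family
#'
#' One library-default hyperparameter point per family, used by the
#' six-family screen ([compare_model_families()]).
#'
#' @return Named list of six [regressor_config()] objects.
#' @export
default_family_configs <- function() {
  list(SVR = regressor_config("SVR"),
       KNN = regressor_config("KNN", k = 5),
       DT = regressor_config("DT"),
       RF = regressor_config("RF", ntree = 500),
       AdaBoost = regressor_config("AdaBoost", n_estimators = 50),
       MLP = regressor_config("MLP"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit an error regressor
#'
#' Dispatches to the requested family. A target with (numerically) zero
#' variance short-circuits to an exact constant predictor -- the degenerate
#' case every family should solve but some libraries reject.
#'
#' @param config A [regressor_config()].
#' @param x Numeric predictor matrix.
#' @param y Numeric response.
#' @param seed Seed for stochastic trainers (RF, AdaBoost, MLP init).
#' @return Object of class `cgm_regressor` with a `predict` method.
#' @export
fit_regressor <- function(config, x, y, seed = 1) {
  stopifnot(inherits(config, "regressor_config"))
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (!nrow(x) || nrow(x) != length(y))
    stop("x and y must be non-empty and conformable", call. = FALSE)
  hp <- config$hyperparameters
  cn <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  colnames(x) <- cn

  if (stats::sd(y) < 1e-10) {
    model <- list(type = "constant", value = mean(y))
  } else if (config$family == "MLP") {
    model <- mlp_fit(x, y,
                     hidden = hp$hidden_layers,
                     activation = hp$activation,
                     solver = hp$solver,
                     learning_rate_init = hp$learning_rate_init,
                     learning_rate_type = hp$learning_rate_type,
                     max_iter = hp$max_iterations,
                     momentum = hp$momentum,
                     alpha = hp$alpha %||% 1e-4,
                     seed = seed)
  } else if (config$family == "SVR") {
    model <- e1071::svm(x, y, type = "eps-regression",
                        kernel = hp$kernel %||% "radial",
                        cost = hp$cost %||% 1,
                        epsilon = hp$epsilon %||% 0.1)
  } else if (config$family == "KNN") {
    model <- caret::knnreg(as.data.frame(x), y, k = hp$k %||% 5)
  } else if (config$family == "DT") {
    df <- data.frame(.y = y, as.data.frame(x))
    ctl <- rpart::rpart.control(minsplit = hp$minsplit %||% 10,
                                cp = hp$cp %||% 0.01,
                                maxdepth = hp$maxdepth %||% 30)
    model <- rpart::rpart(.y ~ ., data = df, method = "anova", control = ctl)
  } else if (config$family == "RF") {
    model <- with_seed(seed,
      randomForest::randomForest(x, y, ntree = hp$ntree %||% 500))
  } else if (config$family == "AdaBoost") {
    model <- with_seed(seed,
      adaboost_r2_fit(x, y, n_estimators = hp$n_estimators %||% 50))
  }
  structure(list(family = config$family, config = config, model = model,
                 feature_names = cn),
            class = "cgm_regressor")
}

#' @param object A fitted `cgm_regressor`.
#' @param newdata Numeric matrix with the training columns.
#' @param ... Unused.
#' @rdname fit_regressor
#' @export
predict.cgm_regressor <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$feature_names
  m <- object$model
  if (is.list(m) && identical(m$type, "constant"))
    return(rep(m$value, nrow(newdata)))
  switch(object$family,
         MLP = predict(m, newdata),
         SVR = as.numeric(predict(m, newdata)),
         KNN = as.numeric(predict(m, as.data.frame(newdata))),
         DT = as.numeric(predict(m, as.data.frame(newdata))),
         RF = as.numeric(predict(m, newdata)),
         AdaBoost = adaboost_r2_predict(m, newdata))
}

# --- AdaBoost.R2 (Drucker 1997) with regression-tree base learners --------
# Boosting for regression: reweight observations by linear loss relative to
# the worst residual, stop when the weighted loss reaches 0.5, and predict
# with the weighted median of the stage predictions.
adaboost_r2_fit <- function(x, y, n_estimators = 50) {
  n <- nrow(x)
  df <- data.frame(.y = y, as.data.frame(x))
  w <- rep(1 / n, n)
  stages <- list()
  beta <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w * n, method = "anova",
                        control = rpart::rpart.control(minsplit = 5,
                                                       cp = 0.001))
    pred <- as.numeric(predict(fit, df))
    e <- abs(pred - y)
    D <- max(e)
    if (D <= 0) { stages[[m]] <- fit; beta[m] <- 1e-10; break }
    L <- e / D
    ebar <- sum(w * L)
    if (ebar >= 0.5) break
    b <- ebar / (1 - ebar)
    stages[[m]] <- fit
    beta[m] <- max(b, 1e-10)
    w <- w * beta[m]^(1 - L)
    w <- w / sum(w)
  }
  if (!length(stages)) {  # first learner already at weighted loss >= 0.5
    fit <- rpart::rpart(.y ~ ., data = df, method = "anova")
    stages <- list(fit); beta <- 0.5
  }
  list(stages = stages, log_inv_beta = log(1 / beta))
}

adaboost_r2_predict <- function(model, newdata) {
  df <- as.data.frame(newdata)
  preds <- vapply(model$stages, function(s) as.numeric(predict(s, df)),
                  numeric(nrow(df)))
  preds <- matrix(preds, nrow = nrow(df))
  wts <- model$log_inv_beta
  apply(preds, 1, function(p) weighted_median(p, wts))
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= 0.5 * sum(w))[1]]
}
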