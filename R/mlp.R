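#' Multilayer perceptron regressor
#'
#' Feed-forward neural network for regression with an arbitrary stack of
#' hidden layers, linear output, and squared-error loss with L2 weight
#' penalty. Training follows the usual forward/backward-pass gradient
#' computation; three solvers are available: full-batch stochastic gradient
#' descent with momentum and a learning-rate schedule, ADAM, and L-BFGS
#' (via [stats::optim()]). Semantics (Glorot initialization, `alpha` penalty
#' scaled by sample size, `invscaling`/`adaptive` schedules) mirror the
#' conventions of mainstream MLP regressor implementations so that a
#' hyperparameter grid expressed in those terms carries over directly.
#'
#' Inputs are used as given; callers are expected to standardize features.
#' The target is internally centered and scaled for numerical conditioning
#' and predictions are returned on the original scale. The per-iteration
#' training loss (sum of squared errors on the scaled target) is recorded
#' for convergence diagnostics.
#'
#' @param x Numeric matrix of predictors (n x p).
#' @param y Numeric response vector, length n.
#' @param hidden Integer vector of hidden layer sizes, e.g. `c(10, 10)`.
#' @param activation `"relu"` or `"tanh"` (hidden layers; output is linear).
#' @param solver `"lbfgs"`, `"sgd"` or `"adam"`.
#' @param learning_rate_init Initial learning rate (SGD/ADAM).
#' @param learning_rate_type Schedule for SGD: `"constant"`, `"invscaling"`
#'   (divide by iteration^0.5) or `"adaptive"` (divide by 5 when the loss
#'   stops improving). Ignored by ADAM and L-BFGS.
#' @param max_iter Maximum training iterations.
#' @param momentum Momentum coefficient for SGD; ignored by other solvers.
#' @param alpha L2 penalty strength.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `cgm_mlp` with a [predict][predict.cgm_mlp]
#'   method and a `loss_curve` element.
#' @examples
#' x <- matrix(rnorm(200), 100, 2)
#' y <- 3 * x[, 1] - 2 * x[, 2] + 1
#' fit <- mlp_fit(x, y, hidden = 8, solver = "lbfgs", max_iter = 200)
#' max(abs(predict(fit, x) - y)) < 0.5
#' @export
mlp_fit <- function(x, y,
                    hidden = c(20),
                    activation = c("relu", "tanh"),
                    solver = c("adam", "sgd", "lbfgs"),
                    learning_rate_init = 0.001,
                    learning_rate_type = c("constant", "invscaling", "adaptive"),
                    max_iter = 200,
                    momentum = 0.9,
                    alpha = 1e-4,
                    seed = 1) {
  activation <- match.arg(tolower(activation[1]), c("relu", "tanh"))
  solver <- match.arg(tolower(solver[1]), c("adam", "sgd", "lbfgs"))
  learning_rate_type <- match.arg(tolower(learning_rate_type[1]),
                                  c("constant", "invscaling", "adaptive"))
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  hidden <- as.integer(hidden)
  if (!length(hidden) || any(hidden < 1))
    stop("hidden must be positive layer sizes", call. = FALSE)
  stop_if_not_scalar_number(learning_rate_init, "learning_rate_init",
                            positive = TRUE)
  stop_if_not_scalar_number(max_iter, "max_iter", positive = TRUE)

  # scale target for conditioning; un-scaled at predict time
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  ys <- (y - y_center) / y_scale

  sizes <- c(ncol(x), hidden, 1L)
  par0 <- with_seed(seed, mlp_init(sizes))
  n <- nrow(x)

  act <- mlp_activation(activation)
  loss_grad <- function(theta) {
    w <- mlp_unflatten(theta, sizes)
    fw <- mlp_forward(x, w, act$f)
    r <- fw$out - ys
    loss <- 0.5 * sum(r^2) / n +
      0.5 * alpha * sum(vapply(w$W, function(m) sum(m^2), 0)) / n
    g <- mlp_backward(x, w, fw, r, act$df, alpha)
    list(loss = loss, grad = mlp_flatten(g) / n)
  }

  fit <- switch(solver,
    lbfgs = mlp_train_lbfgs(par0, loss_grad, max_iter),
    sgd = mlp_train_sgd(par0, loss_grad, max_iter, learning_rate_init,
                        learning_rate_type, momentum),
    adam = mlp_train_adam(par0, loss_grad, max_iter, learning_rate_init))

  structure(list(weights = mlp_unflatten(fit$par, sizes),
                 sizes = sizes, activation = activation, solver = solver,
                 y_center = y_center, y_scale = y_scale,
                 loss_curve = fit$loss_curve * n,  # SSE on scaled target
                 n_iter = length(fit$loss_curve)),
            class = "cgm_mlp")
}

#' @param object A fitted `cgm_mlp`.
#' @param newdata Numeric matrix with the training predictor columns.
#' @param ... Unused.
#' @rdname mlp_fit
#' @export
predict.cgm_mlp <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$sizes[1])
    stop("newdata has wrong number of columns", call. = FALSE)
  act <- mlp_activation(object$activation)
  out <- mlp_forward(newdata, object$weights, act$f)$out
  out * object$y_scale + object$y_center
}

#' @export
print.cgm_mlp <- function(x, ...) {
  cat(sprintf("MLP regressor: layers %s, %s activation, %s solver, %d iterations\n",
              paste(x$sizes, collapse = "-"), x$activation, x$solver, x$n_iter))
  invisible(x)
}

mlp_activation <- function(name) {
  if (name == "relu")
    list(f = function(z) pmax(z, 0), df = function(z) (z > 0) * 1)
  else
    list(f = tanh, df = function(z) 1 - tanh(z)^2)
}

# Glorot-uniform weight matrices, zero biases
mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  mlp_flatten(list(W = W, b = b))
}

mlp_flatten <- function(w) c(unlist(w$W), unlist(w$b))

mlp_unflatten <- function(theta, sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  pos <- 0L
  for (l in seq_len(L)) {
    k <- sizes[l] * sizes[l + 1L]
    W[[l]] <- matrix(theta[pos + seq_len(k)], sizes[l], sizes[l + 1L])
    pos <- pos + k
  }
  for (l in seq_len(L)) {
    k <- sizes[l + 1L]
    b[[l]] <- theta[pos + seq_len(k)]
    pos <- pos + k
  }
  list(W = W, b = b)
}

# forward pass: returns pre-activations z and activations a per layer
mlp_forward <- function(x, w, f) {
  L <- length(w$W)
  a <- vector("list", L + 1L)
  z <- vector("list", L)
  a[[1]] <- x
  for (l in seq_len(L)) {
    z[[l]] <- sweep(a[[l]] %*% w$W[[l]], 2, w$b[[l]], "+")
    a[[l + 1L]] <- if (l < L) f(z[[l]]) else z[[l]]  # linear output
  }
  list(z = z, a = a, out = as.vector(a[[L + 1L]]))
}

# backward pass: gradients of sum(0.5 r^2) + 0.5*alpha*sum(W^2) w.r.t. W, b
mlp_backward <- function(x, w, fw, r, df, alpha) {
  L <- length(w$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- matrix(r, ncol = 1)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$a[[l]], delta) + alpha * w$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(w$W[[l]])) * df(fw$z[[l - 1L]])
  }
  list(W = gW, b = gb)
}

mlp_train_lbfgs <- function(par0, loss_grad, max_iter) {
  trace_env <- new.env()
  trace_env$losses <- numeric(0)
  res <- stats::optim(par0,
                      fn = function(p) {
                        lg <- loss_grad(p)
                        trace_env$losses <- c(trace_env$losses, lg$loss)
                        lg$loss
                      },
                      gr = function(p) loss_grad(p)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = as.integer(max_iter)))
  list(par = res$par, loss_curve = trace_env$losses)
}

mlp_train_sgd <- function(par0, loss_grad, max_iter, lr0, schedule, momentum) {
  par <- par0
  v <- numeric(length(par0))
  losses <- numeric(max_iter)
  lr <- lr0
  best <- Inf; stall <- 0L
  for (it in seq_len(max_iter)) {
    lg <- loss_grad(par)
    losses[it] <- lg$loss
    eff_lr <- switch(schedule,
                     constant = lr,
                     invscaling = lr0 / it^0.5,
                     adaptive = lr)
    if (schedule == "adaptive") {
      if (lg$loss < best - 1e-6) { best <- lg$loss; stall <- 0L }
      else {
        stall <- stall + 1L
        if (stall >= 2L) { lr <- lr / 5; stall <- 0L }
      }
    }
    v <- momentum * v - eff_lr * lg$grad
    par <- par + v
    if (!all(is.finite(par))) {  # diverged: back off and restart descent
      par <- par0; v[] <- 0; lr <- lr / 10
      if (lr < 1e-8) break
    }
  }
  list(par = par, loss_curve = losses[seq_len(min(it, max_iter))])
}

mlp_train_adam <- function(par0, loss_grad, max_iter, lr,
                           b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  par <- par0
  m <- numeric(length(par0)); v <- numeric(length(par0))
  losses <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    lg <- loss_grad(par)
    losses[it] <- lg$loss
    m <- b1 * m + (1 - b1) * lg$grad
    v <- b2 * v + (1 - b2) * lg$grad^2
    mh <- m / (1 - b1^it)
    vh <- v / (1 - b2^it)
    par <- par - lr * mh / (sqrt(vh) + eps)
    if (!all(is.finite(par))) { par <- par0; m[] <- 0; v[] <- 0; lr <- lr / 10 }
  }
  list(par = par, loss_curve = losses)
}
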