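#' Training configuration for the feed-forward classifier
#'
#' Defaults follow the published parameter table of the model this package
#' implements: 16 hidden nodes, learning rate 0.005, 500 epochs, mean
#' squared error goal 1e-5, minimum (validation) error 0.002 and momentum
#' 0.6. Learning rate and momentum are not native Levenberg-Marquardt
#' parameters; they are stored for fidelity and drive the alternative
#' gradient-descent-with-momentum trainer ([gdm_train()]).
#'
#' @param hidden_nodes Hidden layer width.
#' @param learning_rate Step size of the gradient-descent trainer.
#' @param max_epochs Maximum training epochs.
#' @param mse_goal Stop when the training MSE falls to this value.
#' @param min_error Early-stop threshold on validation MSE (used only when
#'   a validation split is supplied).
#' @param momentum Momentum coefficient of the gradient-descent trainer.
#' @param lm_lambda_init Initial Levenberg-Marquardt damping \eqn{\lambda}.
#' @param lm_lambda_factor Multiplicative \eqn{\lambda} adjustment factor.
#' @param seed Seed for weight initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(hidden_nodes = 16L,
                         learning_rate = 0.005,
                         max_epochs = 500L,
                         mse_goal = 1e-5,
                         min_error = 0.002,
                         momentum = 0.6,
                         lm_lambda_init = 1e-2,
                         lm_lambda_factor = 10,
                         seed = 1L) {
  cfg <- list(hidden_nodes = as.integer(hidden_nodes),
              learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
              mse_goal = mse_goal, min_error = min_error, momentum = momentum,
              lm_lambda_init = lm_lambda_init, lm_lambda_factor = lm_lambda_factor,
              seed = as.integer(seed))
  stopifnot(cfg$hidden_nodes >= 1, cfg$max_epochs >= 1,
            cfg$learning_rate > 0, cfg$mse_goal > 0, cfg$momentum >= 0,
            cfg$lm_lambda_init > 0, cfg$lm_lambda_factor > 1)
  class(cfg) <- "train_config"
  cfg
}

#' Initialize the three-layer network
#'
#' Architecture `n_inputs -> hidden_nodes -> 1` with hyperbolic-tangent
#' sigmoid ("tansig") hidden units and a linear ("purelin") output. Weights
#' and biases are drawn uniformly from `[-0.5, 0.5]` under `config$seed`.
#'
#' @param n_inputs Number of input features (>= 1).
#' @param config A [train_config()].
#' @param hidden_activation `"tansig"` (default) or `"purelin"`; the latter
#'   collapses the network to an affine map, useful for linear benchmarks.
#' @return An object of class `network_model`.
#' @export
init_network <- function(n_inputs, config = train_config(),
                         hidden_activation = c("tansig", "purelin")) {
  hidden_activation <- match.arg(hidden_activation)
  if (n_inputs < 1) stop("`n_inputs` must be >= 1", call. = FALSE)
  h <- config$hidden_nodes
  if (h < 1) stop("`hidden_nodes` must be >= 1", call. = FALSE)
  pars <- with_seed(config$seed, stats::runif(h * n_inputs + h + h + 1, -0.5, 0.5))
  model <- list(
    w_hidden = matrix(pars[seq_len(h * n_inputs)], h, n_inputs),
    b_hidden = pars[h * n_inputs + seq_len(h)],
    w_out = matrix(pars[h * n_inputs + h + seq_len(h)], 1, h),
    b_out = pars[h * n_inputs + 2 * h + 1],
    hidden_activation = hidden_activation,
    output_activation = "purelin",
    center = NULL, scale = NULL
  )
  class(model) <- "network_model"
  model
}

n_params <- function(model) {
  length(model$w_hidden) + length(model$b_hidden) + length(model$w_out) + 1L
}

params_to_vector <- function(model) {
  c(as.vector(model$w_hidden), model$b_hidden, as.vector(model$w_out), model$b_out)
}

vector_to_params <- function(model, theta) {
  h <- nrow(model$w_hidden); d <- ncol(model$w_hidden)
  model$w_hidden <- matrix(theta[seq_len(h * d)], h, d)
  model$b_hidden <- theta[h * d + seq_len(h)]
  model$w_out <- matrix(theta[h * d + h + seq_len(h)], 1, h)
  model$b_out <- theta[h * d + 2 * h + 1]
  model
}

# Apply stored z-score standardization, if any.
standardize_input <- function(model, X) {
  if (!is.null(model$center)) {
    X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  }
  X
}

#' Forward pass of the network
#'
#' Computes `purelin(w_out %*% tansig(w_hidden %*% x + b_hidden) + b_out)`
#' for one feature vector or row-wise for a feature matrix. If the model
#' carries standardization constants (stored by [lm_train()]), they are
#' applied first.
#'
#' @param model A `network_model`.
#' @param x Numeric vector of length `n_inputs`, or a matrix with
#'   `n_inputs` columns.
#' @return Numeric vector of network outputs.
#' @examples
#' m <- init_network(1, train_config(hidden_nodes = 1))
#' m$w_hidden[] <- 1; m$b_hidden[] <- 0; m$w_out[] <- 1; m$b_out <- 0
#' nn_forward(m, 1)  # tanh(1)
#' @export
nn_forward <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != ncol(model$w_hidden)) {
    stop("input length does not match the network's n_inputs", call. = FALSE)
  }
  X <- standardize_input(model, X)
  nn_forward_raw(model, X)
}

# Analytic Jacobian of the network output with respect to every parameter,
# evaluated at each sample: an n x P matrix ordered like params_to_vector().
# X must already be standardized.
nn_jacobian <- function(model, X) {
  n <- nrow(X); h <- nrow(model$w_hidden); d <- ncol(model$w_hidden)
  Z <- X %*% t(model$w_hidden) + matrix(model$b_hidden, n, h, byrow = TRUE)
  if (identical(model$hidden_activation, "purelin")) {
    H <- Z
    dH <- matrix(1, n, h)
  } else {
    H <- tanh(Z)
    dH <- 1 - H^2                                 # n x h
  }
  w2 <- as.vector(model$w_out)                    # h
  # d yhat / d w_hidden[j,k] = w2_j * dH_j * x_k
  Jw1 <- matrix(0, n, h * d)
  for (k in seq_len(d)) {
    Jw1[, (k - 1) * h + seq_len(h)] <- dH * matrix(w2, n, h, byrow = TRUE) * X[, k]
  }
  Jb1 <- dH * matrix(w2, n, h, byrow = TRUE)      # n x h
  Jw2 <- H                                        # n x h
  Jb2 <- matrix(1, n, 1)
  cbind(Jw1, Jb1, Jw2, Jb2)
}

#' Train by Levenberg-Marquardt damped least squares
#'
#' Each epoch computes the residual Jacobian analytically by
#' backpropagation, solves the damped normal equations
#' \eqn{(J^T J + \lambda I)\Delta = J^T e} and accepts the step only when
#' the mean squared error decreases, dividing \eqn{\lambda} by
#' `lm_lambda_factor` on acceptance and multiplying on rejection (retrying
#' within the epoch). Stops when the MSE goal is met, the epochs are
#' exhausted, or \eqn{\lambda} overflows (no descent direction found).
#'
#' Features are z-scored with training-set statistics before training
#' (raw texture features differ by orders of magnitude); the constants are
#' stored in the model so prediction applies them transparently. `NA`
#' features (e.g. undefined correlation) are imputed to the training mean.
#'
#' @param model A `network_model` from [init_network()], or `NULL` to
#'   initialize from `config`.
#' @param X Numeric feature matrix (samples x features) or data frame.
#' @param y Binary 0/1 target vector.
#' @param config A [train_config()].
#' @param validation Optional list `list(X, y)`; when supplied, training
#'   also stops once validation MSE drops below `config$min_error`.
#' @param standardize Z-score the features? Default `TRUE`.
#' @return List with `model` (trained `network_model`) and `report` (class
#'   `train_report`: `mse_trace`, `epochs_run`, `stop_reason`).
#' @export
lm_train <- function(model = NULL, X, y, config = train_config(),
                     validation = NULL, standardize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) < 2) stop("need at least 2 training samples", call. = FALSE)
  if (length(y) != nrow(X)) stop("X and y disagree in length", call. = FALSE)
  # classification uses 0/1 coding, but the trainer is a generic
  # least-squares optimizer and accepts any finite numeric target
  if (any(!is.finite(y))) stop("targets must be finite numbers", call. = FALSE)
  if (is.null(model)) model <- init_network(ncol(X), config)

  if (standardize) {
    ctr <- colMeans(X, na.rm = TRUE)
    ctr[is.nan(ctr)] <- 0
    scl <- apply(X, 2, stats::sd, na.rm = TRUE)
    scl[!is.finite(scl) | scl == 0] <- 1
    model$center <- ctr
    model$scale <- scl
  }
  # impute NA features (undefined correlation on constant regions) to the
  # training-set mean, i.e. to 0 after centering
  for (j in seq_len(ncol(X))) {
    bad <- is.na(X[, j])
    if (any(bad)) X[bad, j] <- if (is.null(model$center)) 0 else model$center[j]
  }
  Xs <- standardize_input(model, X)

  theta <- params_to_vector(model)
  P <- length(theta)
  lambda <- config$lm_lambda_init
  lambda_max <- 1e12
  mse_of <- function(th) {
    mean((y - nn_forward_raw(vector_to_params(model, th), Xs))^2)
  }

  mse <- mse_of(theta)
  trace <- numeric(0)
  stop_reason <- "max_epochs"
  epochs <- 0L
  for (ep in seq_len(config$max_epochs)) {
    m_cur <- vector_to_params(model, theta)
    yhat <- nn_forward_raw(m_cur, Xs)
    e <- y - yhat
    J <- nn_jacobian(m_cur, Xs)
    JtJ <- crossprod(J)
    Jte <- crossprod(J, e)
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(
        solve(JtJ + diag(lambda, P), Jte),
        error = function(err) NULL
      )
      if (!is.null(step)) {
        cand <- theta + as.vector(step)
        mse_new <- mse_of(cand)
        if (is.finite(mse_new) && mse_new < mse) {
          theta <- cand
          mse <- mse_new
          lambda <- lambda / config$lm_lambda_factor
          accepted <- TRUE
        }
      }
      if (!accepted) {
        lambda <- lambda * config$lm_lambda_factor
        if (lambda > lambda_max) break
      }
    }
    if (!accepted) {
      stop_reason <- "lambda_overflow"
      break
    }
    epochs <- ep
    trace[ep] <- mse
    if (mse <= config$mse_goal) {
      stop_reason <- "goal_met"
      break
    }
    if (!is.null(validation)) {
      mv <- vector_to_params(model, theta)
      vhat <- nn_forward_raw(mv, standardize_input(model, as.matrix(validation$X)))
      if (mean((as.numeric(validation$y) - vhat)^2) < config$min_error) {
        stop_reason <- "validation_goal"
        break
      }
    }
  }

  model <- vector_to_params(model, theta)
  report <- structure(
    list(mse_trace = trace, epochs_run = epochs, stop_reason = stop_reason),
    class = "train_report"
  )
  list(model = model, report = report)
}

# forward pass on pre-standardized input
nn_forward_raw <- function(model, Xs) {
  Z <- Xs %*% t(model$w_hidden) + matrix(model$b_hidden, nrow(Xs),
                                         length(model$b_hidden), byrow = TRUE)
  H <- if (identical(model$hidden_activation, "purelin")) Z else tanh(Z)
  as.vector(H %*% t(model$w_out) + model$b_out)
}

#' Train by gradient descent with momentum
#'
#' The alternative trainer that honors the published learning-rate (0.005)
#' and momentum (0.6) parameters directly: full-batch gradient descent on
#' the mean squared error with a momentum term. Provided for fidelity and
#' comparison; [lm_train()] is the default and much faster.
#'
#' @inheritParams lm_train
#' @return List with `model` and `report`, as for [lm_train()].
#' @export
gdm_train <- function(model = NULL, X, y, config = train_config(),
                      standardize = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (is.null(model)) model <- init_network(ncol(X), config)
  if (standardize) {
    model$center <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    model$scale <- scl
  }
  Xs <- standardize_input(model, X)
  theta <- params_to_vector(model)
  vel <- numeric(length(theta))
  trace <- numeric(0)
  stop_reason <- "max_epochs"
  n <- nrow(Xs)
  for (ep in seq_len(config$max_epochs)) {
    m_cur <- vector_to_params(model, theta)
    yhat <- nn_forward_raw(m_cur, Xs)
    e <- y - yhat
    J <- nn_jacobian(m_cur, Xs)
    grad <- -2 / n * as.vector(crossprod(J, e))
    vel <- config$momentum * vel - config$learning_rate * grad
    theta <- theta + vel
    trace[ep] <- mean((y - nn_forward_raw(vector_to_params(model, theta), Xs))^2)
    if (trace[ep] <= config$mse_goal) {
      stop_reason <- "goal_met"
      break
    }
  }
  model <- vector_to_params(model, theta)
  list(model = model,
       report = structure(list(mse_trace = trace, epochs_run = length(trace),
                               stop_reason = stop_reason),
                          class = "train_report"))
}

#' Predict the binary tumor label
#'
#' Thresholds the network output at `threshold` (default 0.5, the midpoint
#' of the 0/1 target coding: tumor-free images train toward 0, tumor images
#' toward 1).
#'
#' @param model A trained `network_model`.
#' @param x Feature vector or matrix.
#' @param threshold Decision threshold.
#' @return Integer 0/1 labels.
#' @export
predict_label <- function(model, x, threshold = 0.5) {
  as.integer(nn_forward(model, x) >= threshold)
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("Feed-forward network %d -> %d -> 1 (tansig / purelin), %d parameters\n",
              ncol(x$w_hidden), nrow(x$w_hidden), n_params(x)))
  invisible(x)
}

#' Tidy a trained network into one row per parameter group
#'
#' @param x A `network_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `n` and the root-mean-square magnitude.
#' @method tidy network_model
#' @export
tidy.network_model <- function(x, ...) {
  grp <- list(w_hidden = as.vector(x$w_hidden), b_hidden = x$b_hidden,
              w_out = as.vector(x$w_out), b_out = x$b_out)
  tibble::tibble(
    term = names(grp),
    n = vapply(grp, length, integer(1)),
    rms = vapply(grp, function(v) sqrt(mean(v^2)), numeric(1))
  )
}

#' One-line summary of a training run
#'
#' @param x A `train_report`.
#' @param ... Unused.
#' @return One-row tibble with `epochs_run`, final `mse`, `stop_reason`.
#' @method glance train_report
#' @export
glance.train_report <- function(x, ...) {
  tibble::tibble(
    epochs_run = x$epochs_run,
    mse = if (length(x$mse_trace)) x$mse_trace[length(x$mse_trace)] else NA_real_,
    stop_reason = x$stop_reason
  )
}

#' Plot the training error trace
#'
#' @param object A `train_report`.
#' @param ... Unused.
#' @return A ggplot of MSE against epoch (log scale).
#' @method autoplot train_report
#' @export
autoplot.train_report <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$mse_trace), mse = object$mse_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Epoch", y = "Training MSE")
}

#' Serialize a network model to JSON
#'
#' Shapes, weights, activations and standardization constants round-trip
#' exactly through [read_network_json()].
#'
#' @param model A `network_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(model, path) {
  obj <- list(
    n_inputs = ncol(model$w_hidden), hidden_nodes = nrow(model$w_hidden),
    w_hidden = model$w_hidden, b_hidden = model$b_hidden,
    w_out = as.vector(model$w_out), b_out = model$b_out,
    hidden_activation = model$hidden_activation,
    output_activation = model$output_activation,
    center = model$center, scale = model$scale
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a network model from JSON
#'
#' @param path File written by [write_network_json()].
#' @return A `network_model`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(
    w_hidden = matrix(unlist(obj$w_hidden), obj$hidden_nodes, obj$n_inputs),
    b_hidden = as.numeric(obj$b_hidden),
    w_out = matrix(as.numeric(obj$w_out), 1, obj$hidden_nodes),
    b_out = as.numeric(obj$b_out),
    hidden_activation = obj$hidden_activation,
    output_activation = obj$output_activation,
    center = if (is.null(obj$center)) NULL else as.numeric(obj$center),
    scale = if (is.null(obj$scale)) NULL else as.numeric(obj$scale)
  )
  class(model) <- "network_model"
  model
}
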