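#' One accelerated-PSO step
#'
#' The velocity-free accelerated particle swarm update
#' \deqn{x_{t+1} = (1-\beta) x_t + \beta g^* + \alpha_t \epsilon,}
#' with \eqn{g^*} the global best position, \eqn{\beta} the attraction
#' coefficient, \eqn{\alpha_t = \alpha_0 \gamma^t} a decaying randomization
#' amplitude and \eqn{\epsilon} standard normal per coordinate. Positions
#' are clipped to the bounds; a particle whose objective evaluates
#' non-finite is scored `+Inf` and resampled uniformly within the bounds.
#'
#' @param state Swarm state as built by [apso_optimize()]: list with
#'   `positions` (n_particles x dim), `scores`, `global_best`,
#'   `global_best_score`, `iteration`, `alpha0`, `gamma`, `beta`.
#' @param objective Function mapping a position vector to a scalar score
#'   (lower is better).
#' @param bounds List with numeric vectors `lower` and `upper`.
#' @return The updated swarm state.
#' @export
apso_step <- function(state, objective, bounds) {
  n <- nrow(state$positions); d <- ncol(state$positions)
  if (any(!is.finite(bounds$lower)) || any(!is.finite(bounds$upper))) {
    stop("bounds must be finite", call. = FALSE)
  }
  alpha_t <- state$alpha0 * state$gamma^state$iteration
  eps <- matrix(stats::rnorm(n * d), n, d)
  gb <- matrix(state$global_best, n, d, byrow = TRUE)
  pos <- (1 - state$beta) * state$positions + state$beta * gb + alpha_t * eps
  lo <- matrix(bounds$lower, n, d, byrow = TRUE)
  hi <- matrix(bounds$upper, n, d, byrow = TRUE)
  pos <- pmin(pmax(pos, lo), hi)

  scores <- vapply(seq_len(n), function(i) objective(pos[i, ]), numeric(1))
  bad <- !is.finite(scores)
  if (any(bad)) {
    pos[bad, ] <- lo[bad, , drop = FALSE] +
      matrix(stats::runif(sum(bad) * d), sum(bad), d) *
        (hi[bad, , drop = FALSE] - lo[bad, , drop = FALSE])
    scores[bad] <- Inf
  }
  best_i <- which.min(scores)
  if (scores[best_i] < state$global_best_score) {
    state$global_best <- pos[best_i, ]
    state$global_best_score <- scores[best_i]
  }
  state$positions <- pos
  state$scores <- scores
  state$iteration <- state$iteration + 1L
  state
}

#' Accelerated particle swarm optimization
#'
#' Minimizes `objective` over a box by iterating [apso_step()] from a
#' seeded uniform initialization. All randomness is driven by `seed`, so a
#' run is bit-reproducible.
#'
#' @param objective Function position -> scalar score (lower is better).
#' @param dim Problem dimension.
#' @param bounds List `list(lower =, upper =)`, each of length 1 or `dim`.
#' @param n_particles Swarm size (default 20).
#' @param n_iter Number of iterations.
#' @param alpha0 Initial randomization amplitude; default `0.2 *` the mean
#'   box range.
#' @param gamma Amplitude decay per iteration (default 0.97).
#' @param beta Attraction toward the global best in `(0, 1]` (default 0.5).
#' @param seed Integer seed.
#' @return List with `best_position`, `best_score` and `trace` (tibble of
#'   per-iteration best score).
#' @examples
#' apso_optimize(function(x) sum(x^2), dim = 2,
#'               bounds = list(lower = -1, upper = 1), n_iter = 50, seed = 1)$best_score
#' @export
apso_optimize <- function(objective, dim, bounds, n_particles = 20L,
                          n_iter = 200L, alpha0 = NULL, gamma = 0.97,
                          beta = 0.5, seed = 1L) {
  if (n_particles < 1 || n_iter < 1) {
    stop("`n_particles` and `n_iter` must be >= 1", call. = FALSE)
  }
  lower <- rep_len(as.numeric(bounds$lower), dim)
  upper <- rep_len(as.numeric(bounds$upper), dim)
  if (length(lower) == 0 || any(upper < lower)) {
    stop("invalid bounds", call. = FALSE)
  }
  if (is.null(alpha0)) alpha0 <- 0.2 * mean(upper - lower)

  with_seed(seed, {
    pos <- matrix(stats::runif(n_particles * dim), n_particles, dim)
    pos <- sweep(sweep(pos, 2, upper - lower, "*"), 2, lower, "+")
    scores <- vapply(seq_len(n_particles), function(i) objective(pos[i, ]), numeric(1))
    scores[!is.finite(scores)] <- Inf
    best_i <- which.min(scores)
    state <- list(
      positions = pos, scores = scores,
      global_best = pos[best_i, ], global_best_score = scores[best_i],
      iteration = 0L, alpha0 = alpha0, gamma = gamma, beta = beta
    )
    trace <- numeric(n_iter)
    for (t in seq_len(n_iter)) {
      state <- apso_step(state, objective, list(lower = lower, upper = upper))
      trace[t] <- state$global_best_score
    }
    list(
      best_position = state$global_best,
      best_score = state$global_best_score,
      trace = tibble::tibble(iteration = seq_len(n_iter), best_score = trace)
    )
  })
}

#' Tune the classifier with APSO
#'
#' Wraps [lm_train()] in an accelerated-PSO search. The objective is the
#' k-fold (default 3) cross-validated mean squared error of the trained
#' network on `(X, y)` — MSE rather than accuracy, so the search surface is
#' smooth. Two search modes are supported, mirroring the ambiguity of what
#' "optimizing the network" means in practice:
#' \describe{
#'   \item{`"weights"`}{searches the initial weight vector; dimension is
#'     the network parameter count, bounds `weight_bounds`.}
#'   \item{`"hyper"`}{searches `hidden_nodes` (rounded to integer within
#'     `hidden_bounds`) and `log10(lm_lambda_init)` within `lambda_bounds`.}
#' }
#' The best candidate is refit on the full data and returned.
#'
#' @param X Feature matrix or data frame.
#' @param y Binary targets.
#' @param mode `"weights"` or `"hyper"`.
#' @param config Base [train_config()]; `config$seed` drives all
#'   randomness, `config$max_epochs` bounds each inner fit (tuning uses a
#'   reduced epoch budget by default, see `tune_epochs`).
#' @param n_particles,n_iter Swarm size and iteration count.
#' @param k Number of CV folds.
#' @param tune_epochs Epoch budget for each candidate fit during the
#'   search; the final refit uses `config$max_epochs`.
#' @param weight_bounds,hidden_bounds,lambda_bounds Search boxes.
#' @param beta,gamma APSO coefficients, as in [apso_optimize()].
#' @return List with `model`, `report` (from the final refit), `best_score`
#'   (CV MSE) and `trace`.
#' @export
apso_tune_network <- function(X, y, mode = c("weights", "hyper"),
                              config = train_config(), n_particles = 10L,
                              n_iter = 20L, k = 3L, tune_epochs = 30L,
                              weight_bounds = c(-1, 1),
                              hidden_bounds = c(2L, 24L),
                              lambda_bounds = c(-4, 1),
                              beta = 0.5, gamma = 0.97) {
  mode <- match.arg(mode)
  X <- as.matrix(X); y <- as.numeric(y)
  if (mode == "hyper" && hidden_bounds[1] < 1) {
    stop("infeasible hidden_nodes bounds", call. = FALSE)
  }

  folds <- with_seed(derive_seed(config$seed, 17L), {
    sample(rep_len(seq_len(k), nrow(X)))
  })
  cv_mse <- function(fit_fun) {
    errs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || sum(!tr) == 0) return(NA_real_)
      fit <- fit_fun(X[tr, , drop = FALSE], y[tr])
      yhat <- nn_forward(fit$model, X[!tr, , drop = FALSE])
      mean((y[!tr] - yhat)^2)
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }
  tune_cfg <- config
  tune_cfg$max_epochs <- as.integer(tune_epochs)

  if (mode == "weights") {
    proto <- init_network(ncol(X), config)
    dim_ <- n_params(proto)
    objective <- function(theta) {
      cv_mse(function(Xtr, ytr) {
        lm_train(vector_to_params(proto, theta), Xtr, ytr, tune_cfg)
      })
    }
    bounds <- list(lower = weight_bounds[1], upper = weight_bounds[2])
    opt <- apso_optimize(objective, dim_, bounds, n_particles, n_iter,
                         beta = beta, gamma = gamma,
                         seed = derive_seed(config$seed, 29L))
    final <- lm_train(vector_to_params(proto, opt$best_position), X, y, config)
  } else {
    objective <- function(z) {
      cfg <- tune_cfg
      cfg$hidden_nodes <- as.integer(round(z[1]))
      cfg$lm_lambda_init <- 10^z[2]
      cv_mse(function(Xtr, ytr) lm_train(NULL, Xtr, ytr, cfg))
    }
    bounds <- list(lower = c(hidden_bounds[1], lambda_bounds[1]),
                   upper = c(hidden_bounds[2], lambda_bounds[2]))
    opt <- apso_optimize(objective, 2L, bounds, n_particles, n_iter,
                         beta = beta, gamma = gamma,
                         seed = derive_seed(config$seed, 29L))
    cfg <- config
    cfg$hidden_nodes <- as.integer(round(opt$best_position[1]))
    cfg$lm_lambda_init <- 10^opt$best_position[2]
    final <- lm_train(NULL, X, y, cfg)
  }
  list(model = final$model, report = final$report,
       best_score = opt$best_score, trace = opt$trace)
}
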