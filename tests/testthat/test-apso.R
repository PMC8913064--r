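sphere <- function(x) sum(x^2)

test_that("apso_step degenerates correctly at the update's corner cases", {
  set.seed(1)
  state <- list(
    positions = matrix(runif(10, -1, 1), 5, 2), scores = rep(Inf, 5),
    global_best = c(0.3, -0.2), global_best_score = sphere(c(0.3, -0.2)),
    iteration = 0L, alpha0 = 0, gamma = 0.97, beta = 1
  )
  out <- apso_step(state, sphere, list(lower = c(-1, -1), upper = c(1, 1)))
  # beta = 1, alpha = 0: every particle jumps exactly to the global best
  expect_true(all(abs(sweep(out$positions, 2, state$global_best)) < 1e-15))

  # single particle already at the optimum with alpha = 0 stays put
  st2 <- list(positions = matrix(0, 1, 2), scores = 0,
              global_best = c(0, 0), global_best_score = 0,
              iteration = 0L, alpha0 = 0, gamma = 0.97, beta = 0.5)
  out2 <- apso_step(st2, sphere, list(lower = c(-1, -1), upper = c(1, 1)))
  expect_equal(out2$positions, matrix(0, 1, 2))
  expect_equal(out2$global_best_score, 0)

  expect_error(apso_step(st2, sphere, list(lower = -Inf, upper = Inf)),
               "finite")
})

test_that("best-so-far score is monotone and bounds are respected", {
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  res <- apso_optimize(rosen, 2, list(lower = -2, upper = 2),
                       n_particles = 15, n_iter = 100, seed = 3)
  expect_true(all(diff(res$trace$best_score) <= 0))
  expect_true(all(res$best_position >= -2 & res$best_position <= 2))
})

test_that("apso is bit-deterministic under a fixed seed", {
  a <- apso_optimize(sphere, 3, list(lower = -1, upper = 1), 10, 50, seed = 9)
  b <- apso_optimize(sphere, 3, list(lower = -1, upper = 1), 10, 50, seed = 9)
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_position, b$best_position)
})

test_that("apso solves sphere and Rosenbrock benchmarks", {
  res <- apso_optimize(sphere, 5, list(lower = -5.12, upper = 5.12),
                       n_particles = 20, n_iter = 200, seed = 1)
  expect_lt(res$best_score, 1e-4)

  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  wins <- sum(vapply(1:10, function(s) {
    apso_optimize(rosen, 2, list(lower = -2, upper = 2), 20, 200,
                  seed = s)$best_score < 0.1
  }, logical(1)))
  expect_gt(wins, 5)  # majority of runs
})

test_that("non-finite objectives score +Inf and the particle is resampled", {
  nasty <- function(x) if (x[1] < 0) NaN else sum(x^2)
  res <- apso_optimize(nasty, 2, list(lower = -1, upper = 1), 10, 30, seed = 4)
  expect_true(is.finite(res$best_score))
  expect_gte(res$best_position[1], 0)
})

test_that("with alpha = 0 the swarm contracts geometrically toward g*", {
  set.seed(6)
  frozen <- function(x) 100  # frozen objective: g* never moves
  state <- list(positions = matrix(runif(20, -1, 1), 10, 2),
                scores = rep(100, 10), global_best = c(0.5, 0.5),
                global_best_score = 50, iteration = 0L,
                alpha0 = 0, gamma = 0.97, beta = 0.4)
  b <- list(lower = c(-1, -1), upper = c(1, 1))
  dist_max <- function(st) {
    max(sqrt(rowSums(sweep(st$positions, 2, st$global_best)^2)))
  }
  d0 <- dist_max(state)
  s1 <- apso_step(state, frozen, b)
  s2 <- apso_step(s1, frozen, b)
  expect_equal(dist_max(s1) / d0, 0.6, tolerance = 1e-9)
  expect_equal(dist_max(s2) / d0, 0.36, tolerance = 1e-9)
})

test_that("apso tuning of initial weights recovers separable data", {
  sep <- separable_features(18, seed = 5)
  res <- apso_tune_network(sep$X, sep$y, mode = "weights",
                           config = train_config(hidden_nodes = 3,
                                                 max_epochs = 60, seed = 2),
                           n_particles = 5, n_iter = 5, tune_epochs = 15)
  expect_equal(predict_label(res$model, sep$X), sep$y)
  expect_true(all(diff(res$trace$best_score) <= 0))
})

test_that("a one-point weight search reproduces plain lm_train", {
  sep <- separable_features(12, seed = 8)
  cfg <- train_config(hidden_nodes = 2, max_epochs = 40, seed = 3)
  proto <- init_network(ncol(sep$X), cfg)
  theta0 <- tumorseg:::params_to_vector(proto)
  # degenerate box: lower = upper = theta0 forces every candidate to theta0
  res <- apso_tune_network(sep$X, sep$y, mode = "weights", config = cfg,
                           n_particles = 2, n_iter = 2,
                           weight_bounds = c(0, 0))
  # with bounds collapsed to {0}, candidates are the zero vector; compare
  # against lm_train started from the same zero initialization
  zero_model <- tumorseg:::vector_to_params(proto, numeric(length(theta0)))
  ref <- lm_train(zero_model, sep$X, sep$y, cfg)
  expect_equal(res$model$w_hidden, ref$model$w_hidden, tolerance = 1e-12)
  expect_equal(nn_forward(res$model, sep$X), nn_forward(ref$model, sep$X),
               tolerance = 1e-12)
})

test_that("hyperparameter mode rejects infeasible bounds and otherwise runs", {
  sep <- separable_features(12, seed = 2)
  expect_error(
    apso_tune_network(sep$X, sep$y, mode = "hyper",
                      hidden_bounds = c(0L, 4L)),
    "infeasible"
  )
  res <- apso_tune_network(sep$X, sep$y, mode = "hyper",
                           config = train_config(max_epochs = 30, seed = 1),
                           n_particles = 3, n_iter = 3, tune_epochs = 10,
                           hidden_bounds = c(2L, 6L))
  expect_s3_class(res$model, "network_model")
  expect_true(is.finite(res$best_score))
})
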