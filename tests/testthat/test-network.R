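test_that("initialization is seeded and has the right parameter count", {
  cfg <- train_config(hidden_nodes = 16, seed = 42)
  m1 <- init_network(7, cfg)
  m2 <- init_network(7, cfg)
  expect_identical(m1, m2)
  expect_equal(nrow(m1$w_hidden), 16)    # published default width
  # parameter count = hidden*(inputs+1) + hidden + 1
  P <- length(m1$w_hidden) + length(m1$b_hidden) + length(m1$w_out) + 1
  expect_equal(P, 16 * (7 + 1) + 16 + 1)
  expect_true(all(abs(c(m1$w_hidden, m1$b_hidden, m1$w_out, m1$b_out)) <= 0.5))
  expect_error(init_network(0, cfg), "n_inputs")
})

test_that("forward pass evaluates tansig/purelin analytically", {
  m <- init_network(1, train_config(hidden_nodes = 1))
  m$w_hidden[] <- 1; m$b_hidden[] <- 0; m$w_out[] <- 1; m$b_out <- 0
  expect_equal(nn_forward(m, 1), tanh(1), tolerance = 1e-12)

  z <- init_network(3, train_config(hidden_nodes = 4))
  z$w_hidden[] <- 0; z$b_hidden[] <- 0; z$w_out[] <- 0; z$b_out <- 0
  expect_equal(nn_forward(z, c(1, 2, 3)), 0)

  # oddness with zero biases
  m2 <- init_network(2, train_config(hidden_nodes = 3, seed = 8))
  m2$b_hidden[] <- 0; m2$b_out <- 0
  x <- c(0.4, -0.7)
  expect_equal(nn_forward(m2, x), -nn_forward(m2, -x), tolerance = 1e-12)

  expect_error(nn_forward(m2, c(1, 2, 3)), "n_inputs")
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(10)
  for (trial in 1:20) {
    d <- sample(2:4, 1); h <- sample(2:5, 1); n <- 6
    m <- init_network(d, train_config(hidden_nodes = h, seed = trial))
    X <- matrix(rnorm(n * d), n, d)
    J <- tumorseg:::nn_jacobian(m, X)
    theta <- tumorseg:::params_to_vector(m)
    eps <- 1e-6
    for (k in sample(seq_along(theta), 5)) {
      tp <- theta; tp[k] <- tp[k] + eps
      tm <- theta; tm[k] <- tm[k] - eps
      fp <- nn_forward(tumorseg:::vector_to_params(m, tp), X)
      fm <- nn_forward(tumorseg:::vector_to_params(m, tm), X)
      fd <- (fp - fm) / (2 * eps)
      denom <- pmax(abs(fd), 1e-8)
      expect_lt(max(abs(J[, k] - fd) / denom), 1e-5)
    }
  }
})

test_that("LM solves a linear regression task to numerical precision", {
  # y = 2x is exactly representable (an exact least-squares solution exists),
  # so LM must drive the MSE below 1e-10 within 20 epochs
  X <- matrix(seq(-1, 1, length.out = 20))
  y <- 2 * X[, 1]
  cfg <- train_config(hidden_nodes = 3, max_epochs = 20, mse_goal = 1e-12,
                      seed = 4)
  model <- init_network(1, cfg, hidden_activation = "purelin")
  fit <- lm_train(model, X, y, cfg, standardize = FALSE)
  expect_lt(min(fit$report$mse_trace), 1e-10)
  # accepted-step trace strictly decreasing
  expect_true(all(diff(fit$report$mse_trace) < 0))
})

test_that("LM training is deterministic and reaches 100% on separable data", {
  sep <- separable_features(20, seed = 6)
  cfg <- train_config(hidden_nodes = 5, max_epochs = 100, seed = 3)
  f1 <- lm_train(NULL, sep$X, sep$y, cfg)
  f2 <- lm_train(NULL, sep$X, sep$y, cfg)
  expect_identical(f1$model, f2$model)
  expect_equal(predict_label(f1$model, sep$X), sep$y)
})

test_that("XOR is learned by at least one of five seeds", {
  set.seed(1)
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  X <- X[rep(1:4, 3), ] + matrix(rnorm(24, 0, 0.01), 12, 2)
  y <- rep(c(0, 1, 1, 0), 3)
  best <- Inf
  for (s in 1:5) {
    cfg <- train_config(hidden_nodes = 5, max_epochs = 200, mse_goal = 1e-8,
                        seed = s)
    fit <- lm_train(NULL, X, y, cfg)
    best <- min(best, min(fit$report$mse_trace))
  }
  expect_lt(best, 1e-3)
})

test_that("predict_label thresholds at the 0/1 coding midpoint", {
  m <- init_network(1, train_config(hidden_nodes = 1))
  m$w_hidden[] <- 0; m$b_hidden[] <- 0; m$b_out <- 0.9; m$w_out[] <- 0
  expect_equal(predict_label(m, 0), 1L)
  m$b_out <- 0.1
  expect_equal(predict_label(m, 0), 0L)
  expect_equal(predict_label(m, 0, threshold = 0.05), 1L)
})

test_that("gradient-descent trainer uses the published rate and momentum", {
  sep <- separable_features(20, seed = 2)
  cfg <- train_config(hidden_nodes = 4, learning_rate = 0.005, momentum = 0.6,
                      max_epochs = 300, seed = 5)
  fit <- gdm_train(NULL, sep$X, sep$y, cfg)
  expect_lt(fit$report$mse_trace[length(fit$report$mse_trace)],
            fit$report$mse_trace[1])
})

test_that("validation split triggers the minimum-error early stop", {
  sep <- separable_features(40, seed = 9)
  tr <- c(1:10, 21:30); va <- c(11:20, 31:40)
  cfg <- train_config(hidden_nodes = 4, max_epochs = 500, mse_goal = 1e-12,
                      min_error = 0.05, seed = 2)
  fit <- lm_train(NULL, sep$X[tr, ], sep$y[tr], cfg,
                  validation = list(X = sep$X[va, ], y = sep$y[va]))
  expect_true(fit$report$stop_reason %in% c("validation_goal", "goal_met"))
  expect_lt(fit$report$epochs_run, 500)
})

test_that("model JSON serialization round-trips", {
  sep <- separable_features(12, seed = 3)
  fit <- lm_train(NULL, sep$X, sep$y,
                  train_config(hidden_nodes = 3, max_epochs = 30, seed = 1))
  path <- tempfile(fileext = ".json")
  write_network_json(fit$model, path)
  back <- read_network_json(path)
  expect_equal(nn_forward(back, sep$X), nn_forward(fit$model, sep$X),
               tolerance = 1e-12)
})
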