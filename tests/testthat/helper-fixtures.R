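# Shared in-code fixtures: tiny images, random GLCMs and separable feature
# sets, all generated deterministically at test time.

# a small noise-free two-level image (values lo / hi, left and right halves)
two_level_image <- function(n = 16, lo = 0.2, hi = 0.8) {
  cbind(matrix(lo, n, n / 2), matrix(hi, n, n / 2))
}

# filled disc of radius r centered in an n x n frame
disc_image <- function(n = 101, r = 30, fg = 0.8, bg = 0.1) {
  cr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  img <- matrix(bg, n, n)
  img[(rows - cr)^2 + (cols - cr)^2 <= r^2] <- fg
  img
}

# random normalized GLCM (optionally symmetric)
random_glcm <- function(n_levels = 6, symmetric = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(stats::runif(n_levels^2), n_levels, n_levels)
  if (symmetric) p <- p + t(p)
  p / sum(p)
}

# independent double-loop oracles for the GLCM statistics
oracle_glcm_stats <- function(p) {
  n <- nrow(p)
  contrast <- homog <- energy <- 0
  marg <- numeric(n)
  for (a in 0:(n - 1)) for (b in 0:(n - 1)) {
    v <- p[a + 1, b + 1]
    contrast <- contrast + v * (a - b)^2
    homog <- homog + v / (1 + (a - b)^2)
    energy <- energy + v^2
    marg[a + 1] <- marg[a + 1] + v / 2
    marg[b + 1] <- marg[b + 1] + v / 2
  }
  mu <- sum((0:(n - 1)) * marg)
  s2 <- sum(((0:(n - 1)) - mu)^2 * marg)
  corr <- if (s2 == 0) NA_real_ else {
    acc <- 0
    for (a in 0:(n - 1)) for (b in 0:(n - 1)) {
      acc <- acc + p[a + 1, b + 1] * (a - mu) * (b - mu)
    }
    acc / s2
  }
  list(contrast = contrast, homogeneity = homog, energy = energy,
       correlation = corr)
}

# linearly separable two-class feature set (two informative columns)
separable_features <- function(n = 20, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(stats::rnorm(n, ifelse(y == 1, 2, -2), 0.3),
             stats::rnorm(n, ifelse(y == 1, -1, 1), 0.3))
  list(X = X, y = y)
}
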