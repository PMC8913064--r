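test_that("fcm objective matches term-by-term enumeration", {
  # every pixel at its sole center -> 0
  img <- matrix(0.5, 2, 2)
  F1 <- matrix(1, 4, 1)
  expect_equal(fcm_objective(img, F1, 0.5), 0)

  # crisp memberships at matching centers -> 0
  img2 <- matrix(c(0, 1), 1)
  expect_equal(fcm_objective(img2, cbind(c(1, 0), c(0, 1)), c(0, 1)), 0)

  # pixels {0,1}, centers {0,1}, all memberships 0.5, m = 2:
  # enumerate the 4 terms: 0.25*(0-0)^2 + 0.25*(0-1)^2 + 0.25*(1-0)^2 + 0.25*(1-1)^2
  F3 <- matrix(0.5, 2, 2)
  oracle <- 0.5^2 * (0 - 0)^2 + 0.5^2 * (0 - 1)^2 + 0.5^2 * (1 - 0)^2 + 0.5^2 * (1 - 1)^2
  expect_equal(fcm_objective(img2, F3, c(0, 1), m = 2), oracle)
  expect_error(fcm_objective(img2, F3, c(0, 1), m = 1), "m")
})

test_that("membership update follows the closed-form rule", {
  # equidistant pixel -> (0.5, 0.5)
  expect_equal(as.vector(update_membership(matrix(0.5), c(0, 1))), c(0.5, 0.5))

  # pixel at a center -> crisp
  Fm <- update_membership(matrix(c(0, 0.3), 1), c(0, 1))
  expect_equal(Fm[1, ], c(1, 0))

  # duplicate coinciding centers share the membership
  Fd <- update_membership(matrix(0.2), c(0.2, 0.2, 0.9))
  expect_equal(Fd[1, ], c(0.5, 0.5, 0))

  # independent scalar oracle at p = 0.2, centers {0, 1}, m = 2
  p <- 0.2
  oracle <- function(j, centers, m) {
    1 / sum((abs(p - centers[j]) / abs(p - centers))^(2 / (m - 1)))
  }
  got <- update_membership(matrix(p), c(0, 1), m = 2)
  expect_equal(got[1, 1], oracle(1, c(0, 1), 2), tolerance = 1e-12)
  expect_equal(got[1, 2], oracle(2, c(0, 1), 2), tolerance = 1e-12)
  expect_equal(sum(got[1, ]), 1, tolerance = 1e-12)

  # rows always sum to 1 (property over random pixels/centers)
  set.seed(4)
  for (i in 1:20) {
    Fr <- update_membership(matrix(runif(30), 5), sort(runif(3)), m = 1.8)
    expect_equal(rowSums(Fr), rep(1, 30), tolerance = 1e-9)
  }
})

test_that("center update reduces to weighted means", {
  img <- matrix(c(0, 0, 0, 10, 10, 10) / 10, 2)
  crisp <- cbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  u <- update_centers(img, crisp)
  expect_equal(as.numeric(u), c(0, 1))

  uniform <- matrix(0.5, 6, 2)
  u2 <- update_centers(img, uniform)
  expect_equal(as.numeric(u2), rep(mean(img), 2))

  near_crisp <- cbind(c(.99, .99, .99, .01, .01, .01),
                      c(.01, .01, .01, .99, .99, .99))
  u3 <- sort(as.numeric(update_centers(img, near_crisp)))
  expect_lt(abs(u3[1] - 0), 0.01)
  expect_lt(abs(u3[2] - 1), 0.01)

  # zero-mass cluster is flagged and reseeded to a pixel value
  empty <- cbind(c(1, 1, 1, 1, 1, 1), rep(0, 6))
  u4 <- update_centers(img, empty, seed = 3)
  expect_true(attr(u4, "empty")[2])
  expect_true(u4[2] %in% as.vector(img))
})

test_that("fcm_cluster recovers planted two-level intensities", {
  img <- two_level_image(16, 0.2, 0.8)
  fit <- fcm_cluster(img, c = 2, m = 2, alpha = 1e-5, seed = 1)
  expect_true(fit$converged)
  expect_equal(sort(fit$centers), c(0.2, 0.8), tolerance = 1e-3)
  expect_equal(rowSums(fit$membership), rep(1, 256), tolerance = 1e-9)

  # c = 1 converges immediately to the mean intensity
  fit1 <- fcm_cluster(img, c = 1, seed = 1)
  expect_equal(fit1$centers, mean(img))
  expect_true(fit1$converged)
})

test_that("objective trace is non-increasing on random images", {
  set.seed(7)
  for (i in 1:20) {
    img <- matrix(runif(64), 8)
    fit <- fcm_cluster(img, c = 3, m = 2, alpha = 1e-6, max_iter = 60,
                       seed = i)
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
  }
})

test_that("permuting the initialization permutes the solution", {
  img <- two_level_image(8)
  f1 <- fcm_cluster(img, c = 2, seed = 5)
  f2 <- fcm_cluster(img, c = 2, seed = 6)
  expect_equal(sort(f1$centers), sort(f2$centers), tolerance = 1e-4)
})

test_that("memberships approach crisp nearest-center assignment as m -> 1+", {
  img <- two_level_image(8, 0.1, 0.9)
  fit <- fcm_cluster(img, c = 2, m = 1.05, alpha = 1e-6, seed = 2)
  hard <- max.col(fit$membership)
  # k-means-style oracle: nearest center wins
  d <- abs(outer(as.vector(img), fit$centers, `-`))
  oracle <- max.col(-d)
  expect_equal(hard, oracle)
  expect_gt(min(apply(fit$membership, 1, max)), 0.99)
})

test_that("tumor_mask picks the brightest cluster and honors the brain mask", {
  ph <- generate_phantom(phantom_spec(noise_density = 0.05, seed = 13L))
  filt <- median_filter(ph$image, 3)
  fit <- fcm_cluster(filt, c = 4, seed = 13)
  mask <- tumor_mask(fit, filt, ph$brain_mask)
  expect_gte(dice_overlap(mask, ph$mask), 0.85)

  # c = 1: the whole region comes back
  fit1 <- fcm_cluster(filt, c = 1, seed = 1)
  expect_true(all(tumor_mask(fit1, filt) == 1))

  # empty brain mask -> empty tumor mask
  expect_true(all(tumor_mask(fit, filt, matrix(0, 128, 128)) == 0))
})

test_that("fcm_cluster validates arguments and warns on degenerate c", {
  img <- two_level_image(4)
  expect_error(fcm_cluster(img, c = 0), "positive integer")
  expect_error(fcm_cluster(img, alpha = 0), "alpha")
  expect_error(fcm_cluster(img, m = 1), "m")
  expect_warning(fcm_cluster(img, c = 5, max_iter = 5), "distinct")
})

test_that("tidy and glance summarize an fcm fit", {
  fit <- fcm_cluster(two_level_image(8), c = 2, seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$size), 64)
  gl <- glance(fit)
  expect_true(gl$converged)
})
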