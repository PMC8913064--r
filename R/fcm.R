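#' Fuzzy c-means objective function
#'
#' The weighted within-cluster sum of squares
#' \deqn{A = \sum_{i=1}^n \sum_{j=1}^c F_{ij}^m (p_i - U_j)^2,}
#' where \eqn{p_i} is the scalar intensity of pixel \eqn{i}, \eqn{U_j} the
#' center of cluster \eqn{j}, \eqn{F_{ij}} the fuzzy membership of pixel
#' \eqn{i} in cluster \eqn{j} and \eqn{m > 1} the fuzzifier.
#'
#' @param image Numeric matrix (or vector) of pixel intensities.
#' @param membership `n_pixels x c` matrix of memberships, rows summing to 1.
#' @param centers Numeric vector of `c` cluster centers.
#' @param m Fuzzifier, `> 1`.
#' @return The scalar objective value.
#' @examples
#' fcm_objective(matrix(c(0, 1), 1), cbind(c(1, 0), c(0, 1)), c(0, 1))
#' @export
fcm_objective <- function(image, membership, centers, m = 2) {
  p <- as.vector(image)
  if (m <= 1) stop("fuzzifier `m` must be > 1", call. = FALSE)
  if (!is.matrix(membership) || nrow(membership) != length(p) ||
      ncol(membership) != length(centers)) {
    stop("membership must be n_pixels x n_centers", call. = FALSE)
  }
  d2 <- outer(p, centers, `-`)^2
  sum(membership^m * d2)
}

#' Membership update of fuzzy c-means
#'
#' For each pixel \eqn{p_i} and cluster \eqn{j},
#' \deqn{F_{ij} = 1 / \sum_{k=1}^{c} (|p_i - U_j| / |p_i - U_k|)^{2/(m-1)}.}
#' A pixel coinciding with one or more centers receives crisp membership
#' split equally among the coinciding centers (the standard singularity
#' convention).
#'
#' @inheritParams fcm_objective
#' @return `n_pixels x c` membership matrix; every row sums to 1.
#' @examples
#' update_membership(matrix(0.5), c(0, 1), m = 2)  # 0.5 / 0.5 by symmetry
#' @export
update_membership <- function(image, centers, m = 2) {
  p <- as.vector(image)
  if (length(centers) < 1) stop("need at least one cluster center", call. = FALSE)
  if (m <= 1) stop("fuzzifier `m` must be > 1", call. = FALSE)
  c_n <- length(centers)
  d <- abs(outer(p, centers, `-`))        # n x c distances
  Fm <- matrix(0, length(p), c_n)
  zero <- d == 0
  has_zero <- rowSums(zero) > 0
  if (any(has_zero)) {
    z <- zero[has_zero, , drop = FALSE]
    Fm[has_zero, ] <- z / rowSums(z)
  }
  if (any(!has_zero)) {
    dd <- d[!has_zero, , drop = FALSE]
    e <- 2 / (m - 1)
    # F_ij = 1 / sum_k (d_ij/d_ik)^e = d_ij^-e / sum_k d_ik^-e.
    # Dividing by the row minimum keeps the powers in [0, 1] so that a small
    # fuzzifier (large exponent) cannot overflow.
    dmin <- do.call(pmin, lapply(seq_len(ncol(dd)), function(j) dd[, j]))
    w <- (dd / dmin)^(-e)
    Fm[!has_zero, ] <- w / rowSums(w)
  }
  Fm
}

#' Center update of fuzzy c-means
#'
#' \deqn{U_j = \sum_i F_{ij}^m p_i / \sum_i F_{ij}^m.}
#' A cluster whose membership mass is zero is flagged empty and
#' reinitialized to a random pixel intensity (seeded).
#'
#' @inheritParams fcm_objective
#' @param seed Seed used only if an empty cluster needs reinitialization.
#' @return Numeric vector of `c` centers, with attribute `"empty"` marking
#'   reinitialized clusters.
#' @examples
#' update_centers(matrix(c(0, 0, 1, 1), 2), cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
#' @export
update_centers <- function(image, membership, m = 2, seed = 1L) {
  p <- as.vector(image)
  Fm <- membership^m
  num <- colSums(Fm * p)
  den <- colSums(Fm)
  empty <- den == 0
  u <- num / den
  if (any(empty)) {
    u[empty] <- with_seed(seed, sample(p, sum(empty), replace = TRUE))
  }
  attr(u, "empty") <- empty
  u
}

#' Fuzzy c-means clustering of pixel intensities
#'
#' Alternates the center update and the membership update from a seeded
#' random initial membership (each row drawn uniformly on the simplex)
#' until the largest membership change drops below the ending factor
#' \eqn{\alpha}: \eqn{\max_{ij} |F_{ij}^{(k+1)} - F_{ij}^{(k)}| < \alpha},
#' or `max_iter` is reached. Pixels are clustered on scalar intensity only.
#'
#' @inheritParams fcm_objective
#' @param c Number of clusters (>= 1).
#' @param alpha Ending factor in `(0, 1)`: iteration stops when the largest
#'   membership change falls below it.
#' @param max_iter Maximum number of iterations.
#' @param seed Integer seed for the random initialization.
#' @return An object of class `fcm_result`: list with `membership`,
#'   `centers`, `objective_trace` (objective value per iteration),
#'   `iterations`, `converged`, `m`, `seed` and the image dimensions.
#' @examples
#' img <- matrix(c(rep(0.2, 8), rep(0.8, 8)), 4)
#' fit <- fcm_cluster(img, c = 2, seed = 1)
#' sort(fit$centers)
#' @export
fcm_cluster <- function(image, c = 4L, m = 2, alpha = 1e-5,
                        max_iter = 500L, seed = 1L) {
  assert_image(image)
  if (c < 1 || c != round(c)) stop("`c` must be a positive integer", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  if (m <= 1) stop("fuzzifier `m` must be > 1", call. = FALSE)
  p <- as.vector(image)
  n <- length(p)
  if (c > length(unique(p))) {
    warning("more clusters than distinct pixel values; degenerate clusters possible")
  }

  # Seeded simplex-uniform initial membership (normalized exponentials).
  Fm <- with_seed(seed, {
    e <- matrix(stats::rexp(n * c), n, c)
    e / rowSums(e)
  })

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  centers <- rep(NA_real_, c)
  while (iter < max_iter) {
    iter <- iter + 1L
    centers <- update_centers(image, Fm, m = m, seed = derive_seed(seed, iter))
    F_new <- update_membership(image, centers, m = m)
    trace[iter] <- fcm_objective(image, F_new, centers, m = m)
    delta <- max(abs(F_new - Fm))
    Fm <- F_new
    if (delta < alpha) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(membership = Fm, centers = as.numeric(centers),
         objective_trace = trace, iterations = iter, converged = converged,
         m = m, seed = seed, dim = dim(image)),
    class = "fcm_result"
  )
}

#' Extract the tumor mask from an FCM fit
#'
#' Defuzzifies the membership matrix (each pixel goes to its highest
#' membership cluster; ties break toward the lower cluster index) and
#' returns the pixels of the cluster with the brightest center, optionally
#' intersected with a brain mask. The brightest-cluster heuristic encodes
#' the assumption that the tumor is the most intense tissue class.
#'
#' @param result An [fcm_cluster()] fit.
#' @param image The clustered image (used for its dimensions).
#' @param brain_mask Optional 0/1 matrix restricting the tumor search.
#' @return Binary (0/1) matrix of tumor pixels.
#' @export
tumor_mask <- function(result, image, brain_mask = NULL) {
  stopifnot(inherits(result, "fcm_result"))
  # max.col with ties.method "first" implements the lower-index tie-break
  hard <- max.col(result$membership, ties.method = "first")
  target <- which.max(result$centers)
  mask <- matrix(as.numeric(hard == target), nrow(image), ncol(image))
  if (!is.null(brain_mask)) {
    assert_mask(brain_mask, dim_ref = image, arg = "brain_mask")
    mask <- mask * brain_mask
  }
  mask
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf(
    "Fuzzy c-means fit: %d clusters, m = %g, %d iterations (%s)\ncenters: %s\n",
    length(x$centers), x$m, x$iterations,
    if (x$converged) "converged" else "max_iter reached",
    paste(signif(sort(x$centers), 4), collapse = ", ")
  ))
  invisible(x)
}

#' Tidy an FCM fit into one row per cluster
#'
#' @param x An `fcm_result`.
#' @param ... Unused.
#' @return A tibble with `cluster`, `center` and `size` (pixel count of the
#'   defuzzified assignment).
#' @method tidy fcm_result
#' @export
tidy.fcm_result <- function(x, ...) {
  hard <- max.col(x$membership, ties.method = "first")
  tibble::tibble(
    cluster = seq_along(x$centers),
    center = x$centers,
    size = vapply(seq_along(x$centers), function(j) sum(hard == j), integer(1))
  )
}

#' One-line summary of an FCM fit
#'
#' @param x An `fcm_result`.
#' @param ... Unused.
#' @return A one-row tibble with `n_clusters`, `m`, `iterations`,
#'   `converged` and the final `objective`.
#' @method glance fcm_result
#' @export
glance.fcm_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = length(x$centers), m = x$m, iterations = x$iterations,
    converged = x$converged,
    objective = x$objective_trace[length(x$objective_trace)]
  )
}

#' Plot the FCM objective trace
#'
#' @param object An `fcm_result`.
#' @param ... Unused.
#' @return A ggplot of objective value against iteration.
#' @method autoplot fcm_result
#' @export
autoplot.fcm_result <- function(object, ...) {
  df <- tibble::tibble(
    iteration = seq_along(object$objective_trace),
    objective = object$objective_trace
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Iteration", y = "FCM objective")
}
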