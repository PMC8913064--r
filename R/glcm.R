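#' Gray-level co-occurrence matrix
#'
#' Quantizes intensities to `n_levels` uniform bins over `[0, 1]` and counts
#' ordered pixel pairs `(p, p + offset)` with both ends inside the image
#' (and inside `roi` when given). With `symmetric = TRUE` the transposed
#' counts are added, which makes the two marginal level distributions equal
#' so that the correlation statistic has a single well-defined mean and
#' variance. Counts are normalized to sum to 1.
#'
#' @param image Numeric matrix with intensities in `[0, 1]`.
#' @param roi Optional 0/1 matrix; only pairs with both pixels in the ROI
#'   are counted.
#' @param n_levels Number of gray levels (>= 2).
#' @param offset `(drow, dcol)` displacement between paired pixels; the
#'   default `c(0, 1)` pairs each pixel with its horizontal neighbor.
#' @param symmetric Accumulate pairs in both directions?
#' @return An object of class `glcm`: the `n_levels x n_levels` probability
#'   matrix with attributes `n_levels`, `offset`, `symmetric`.
#' @examples
#' g <- compute_glcm(matrix(c(0, 1, 0, 1), 2), n_levels = 2)
#' @export
compute_glcm <- function(image, roi = NULL, n_levels = 8L,
                         offset = c(0L, 1L), symmetric = TRUE) {
  assert_image(image)
  if (n_levels < 2) stop("`n_levels` must be >= 2", call. = FALSE)
  if (length(offset) != 2L || all(offset == 0)) {
    stop("`offset` must be a (drow, dcol) pair different from (0, 0)", call. = FALSE)
  }
  lev <- quantize_levels(image, n_levels)
  nr <- nrow(image); nc <- ncol(image)
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])

  r0 <- seq_len(nr); c0 <- seq_len(nc)
  r_ok <- r0[r0 + dr >= 1 & r0 + dr <= nr]
  c_ok <- c0[c0 + dc >= 1 & c0 + dc <= nc]
  if (length(r_ok) == 0 || length(c_ok) == 0) {
    stop("offset larger than the image: no pixel pairs", call. = FALSE)
  }
  a <- lev[r_ok, c_ok, drop = FALSE]
  b <- lev[r_ok + dr, c_ok + dc, drop = FALSE]
  keep <- rep(TRUE, length(a))
  if (!is.null(roi)) {
    assert_mask(roi, dim_ref = image, arg = "roi")
    keep <- roi[r_ok, c_ok, drop = FALSE] == 1 & roi[r_ok + dr, c_ok + dc, drop = FALSE] == 1
  }
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) stop("ROI holds fewer than 2 pixel pairs; GLCM undefined", call. = FALSE)

  counts <- matrix(tabulate(a * n_levels + b + 1L, nbins = n_levels^2),
                   n_levels, n_levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  p <- counts / sum(counts)
  structure(p, class = c("glcm", "matrix"),
            n_levels = as.integer(n_levels),
            offset = c(dr, dc), symmetric = isTRUE(symmetric))
}

# Map [0,1] intensities to integer levels 0 .. n_levels-1 (uniform bins).
quantize_levels <- function(image, n_levels) {
  lev <- floor(image * n_levels)
  lev[lev == n_levels] <- n_levels - 1L
  storage.mode(lev) <- "integer"
  lev
}

# Level-index grids used by every GLCM statistic: a varies over rows,
# b over columns, both 0-based.
glcm_indices <- function(g) {
  n <- nrow(g)
  list(a = matrix(0:(n - 1), n, n), b = matrix(0:(n - 1), n, n, byrow = TRUE))
}

#' GLCM contrast
#'
#' \eqn{\sum_{a,b} p(a,b) (a-b)^2}: co-occurrence mass weighted by squared
#' level difference; separation of lighter and darker areas.
#'
#' @param g A normalized GLCM (matrix summing to 1).
#' @return Scalar contrast.
#' @export
glcm_contrast <- function(g) {
  ix <- glcm_indices(g)
  sum(g * (ix$a - ix$b)^2)
}

#' GLCM homogeneity
#'
#' \eqn{\sum_{a,b} p(a,b) / (1 + (a-b)^2)}: closeness of the co-occurrence
#' mass to the matrix diagonal; equals 1 for a purely diagonal GLCM.
#'
#' @inheritParams glcm_contrast
#' @return Scalar homogeneity in `(0, 1]`.
#' @export
glcm_homogeneity <- function(g) {
  ix <- glcm_indices(g)
  sum(g / (1 + (ix$a - ix$b)^2))
}

#' GLCM correlation
#'
#' \eqn{\sum_{a,b} p(a,b)(a-\mu)(b-\mu)/\sigma^2} with \eqn{\mu, \sigma^2}
#' the mean and variance of the symmetric marginal level distribution.
#' Ranges over `[-1, 1]`. For a constant image the marginal variance is 0
#' and the statistic is undefined: `NA` is returned with attribute
#' `"undefined" = TRUE` rather than coercing to a number.
#'
#' @inheritParams glcm_contrast
#' @return Scalar correlation in `[-1, 1]`, or flagged `NA` when undefined.
#' @export
glcm_correlation <- function(g) {
  ix <- glcm_indices(g)
  marg <- (rowSums(g) + colSums(g)) / 2
  lv <- 0:(nrow(g) - 1)
  mu <- sum(lv * marg)
  s2 <- sum((lv - mu)^2 * marg)
  if (s2 == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  sum(g * (ix$a - mu) * (ix$b - mu)) / s2
}

#' GLCM energy (angular second moment)
#'
#' \eqn{\sum_{a,b} p(a,b)^2}: the sum of squared co-occurrence
#' probabilities; 1 for a single-entry GLCM, `1/n^2` for a uniform one.
#'
#' @inheritParams glcm_contrast
#' @return Scalar energy in `(0, 1]`.
#' @export
glcm_energy <- function(g) sum(g^2)

#' First-order intensity statistics
#'
#' Mean and standard deviation of the raw intensities over the ROI, plus
#' the Shannon entropy (bits/pixel) of the `n_levels`-bin normalized
#' intensity histogram, with the convention \eqn{0 \log 0 = 0}. The
#' standard deviation is the population form (denominator `n`), so a
#' constant region has exactly zero spread.
#'
#' @inheritParams compute_glcm
#' @return Named list with `mean`, `std` and `entropy_bits`.
#' @export
intensity_stats <- function(image, roi = NULL, n_levels = 8L) {
  assert_image(image)
  v <- if (is.null(roi)) {
    as.vector(image)
  } else {
    assert_mask(roi, dim_ref = image, arg = "roi")
    image[roi == 1]
  }
  if (length(v) == 0) stop("empty ROI", call. = FALSE)
  h <- tabulate(quantize_levels(matrix(v, 1), n_levels) + 1L, nbins = n_levels)
  h <- h / sum(h)
  nz <- h > 0
  list(
    mean = mean(v),
    std = sqrt(mean((v - mean(v))^2)),
    entropy_bits = -sum(h[nz] * log2(h[nz]))
  )
}

#' Extract the per-image texture feature vector
#'
#' Assembles the seven numeric features used by the classifier: first-order
#' mean, standard deviation and entropy (bits/pixel), and the GLCM
#' contrast, correlation, energy and homogeneity. Deterministic; column
#' names and order are stable.
#'
#' @inheritParams compute_glcm
#' @return A one-row tibble with columns `mean`, `std`, `entropy_bits`,
#'   `contrast`, `correlation`, `energy`, `homogeneity`. An undefined
#'   correlation (constant region) is reported as `NA`.
#' @examples
#' extract_features(matrix(runif(64), 8))
#' @export
extract_features <- function(image, roi = NULL, n_levels = 8L,
                             offset = c(0L, 1L), symmetric = TRUE) {
  st <- intensity_stats(image, roi, n_levels)
  g <- compute_glcm(image, roi, n_levels, offset, symmetric)
  corr <- glcm_correlation(g)
  tibble::tibble(
    mean = st$mean,
    std = st$std,
    entropy_bits = st$entropy_bits,
    contrast = glcm_contrast(g),
    correlation = as.numeric(corr),
    energy = glcm_energy(g),
    homogeneity = glcm_homogeneity(g)
  )
}
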