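#' Median filter for impulse (salt-and-pepper) noise
#'
#' Replaces every pixel by the median of the `window` x `window`
#' neighborhood centered on it. Borders are handled by reflecting the image
#' at its edges, so the output has the same shape as the input. The median
#' is an order statistic, hence the output range is always contained in the
#' input range, and piecewise-constant regions wider than the window are
#' left untouched.
#'
#' @param image Numeric matrix with intensities in `[0, 1]`.
#' @param window Odd positive window size, at most `min(dim(image))`.
#' @return Filtered matrix, same shape as `image`.
#' @examples
#' x <- matrix(c(.1, .2, .3, .4, 1, .6, .7, .8, .9), 3, byrow = TRUE)
#' median_filter(x, 3)[2, 2]  # 0.6
#' @export
median_filter <- function(image, window = 3L) {
  assert_image(image)
  if (!is.numeric(window) || length(window) != 1L || window != round(window) ||
      window < 1 || window %% 2 == 0) {
    stop("`window` must be a positive odd integer", call. = FALSE)
  }
  if (window > min(dim(image))) {
    stop("`window` exceeds the image size", call. = FALSE)
  }
  if (window == 1) return(image)
  k <- (window - 1L) / 2L
  pad <- pad_reflect(image, k)
  nr <- nrow(image); nc <- ncol(image)
  # Stack every window offset as one column, then take row-wise medians.
  stack <- matrix(0, nr * nc, window * window)
  idx <- 1L
  for (dr in 0:(window - 1L)) {
    for (dc in 0:(window - 1L)) {
      stack[, idx] <- pad[dr + seq_len(nr), dc + seq_len(nc)]
      idx <- idx + 1L
    }
  }
  med <- apply(stack, 1L, stats::median)
  matrix(med, nr, nc)
}

# Separable Gaussian smoothing with reflect padding.
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  k <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(-k:k, sd = sigma)
  g <- g / sum(g)
  pad <- pad_reflect(image, k)
  nr <- nrow(image); nc <- ncol(image)
  # rows pass
  tmp <- matrix(0, nr, ncol(pad))
  for (i in seq_along(g)) {
    tmp <- tmp + g[i] * pad[(i - 1L) + seq_len(nr), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (i in seq_along(g)) {
    out <- out + g[i] * tmp[, (i - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

# Sobel gradients with reflect padding; returns list(gx, gy) where gx is the
# horizontal (column-direction) derivative and gy the vertical (row) one.
sobel_gradients <- function(image) {
  p <- pad_reflect(image, 1L)
  nr <- nrow(image); nc <- ncol(image)
  at <- function(dr, dc) p[dr + seq_len(nr), dc + seq_len(nc)]
  gx <- (at(0, 2) + 2 * at(1, 2) + at(2, 2)) - (at(0, 0) + 2 * at(1, 0) + at(2, 0))
  gy <- (at(2, 0) + 2 * at(2, 1) + at(2, 2)) - (at(0, 0) + 2 * at(0, 1) + at(0, 2))
  list(gx = gx, gy = gy)
}

#' Canny edge detection
#'
#' The full Canny chain: Gaussian smoothing, Sobel gradient magnitude and
#' direction, non-maximum suppression along the quantized gradient
#' direction, and double-threshold hysteresis linking (8-connected).
#' Thresholds are given as fractions of the maximum gradient magnitude
#' (`low <= high`), so their meaning does not depend on image contrast.
#'
#' @param image Numeric matrix with intensities in `[0, 1]`.
#' @param gaussian_sigma Smoothing scale in pixels.
#' @param low_threshold,high_threshold Hysteresis thresholds as fractions of
#'   the maximum gradient magnitude; values outside `[0, 1]` trigger a
#'   warning, not an error.
#' @return Binary (0/1) matrix of edge pixels, same shape as `image`.
#' @examples
#' canny_edges(matrix(0.5, 8, 8))  # all zeros
#' @export
canny_edges <- function(image, gaussian_sigma = 1.4,
                        low_threshold = 0.1, high_threshold = 0.2) {
  assert_image(image)
  if (low_threshold < 0 || low_threshold > high_threshold) {
    stop("need 0 <= low_threshold <= high_threshold", call. = FALSE)
  }
  if (high_threshold > 1) {
    warning("high_threshold exceeds the maximum gradient fraction 1")
  }
  sm <- gaussian_blur(image, gaussian_sigma)
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(0, nrow(image), ncol(image)))

  # Quantize gradient direction to 0, 45, 90, 135 degrees and compare each
  # pixel with its two neighbors along that direction.
  ang <- atan2(g$gy, g$gx)            # (-pi, pi]
  ang[ang < 0] <- ang[ang < 0] + pi   # fold to [0, pi)
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  # sector 0: horizontal gradient -> neighbors left/right (dc = +-1)
  # sector 1: 45 deg  -> (dr, dc) = (+1,+1)/(-1,-1) in row-down convention
  # sector 2: vertical gradient -> neighbors up/down (dr = +-1)
  # sector 3: 135 deg -> (+1,-1)/(-1,+1)
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (s in 0:3) {
    d <- offs[[s + 1L]]
    n1 <- shift_mat(mag, d[1], d[2], fill = 0)
    n2 <- shift_mat(mag, -d[1], -d[2], fill = 0)
    sel <- sector == s & mag >= n1 & mag >= n2
    keep[sel] <- TRUE
  }
  nms <- mag * keep

  strong <- nms >= high_threshold * mmax & nms > 0
  weak <- nms >= low_threshold * mmax & nms > 0

  # Hysteresis: grow strong edges through weak pixels (8-connectivity).
  edges <- strong
  repeat {
    grown <- edges
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift_mat(edges, dr, dc, fill = FALSE)
    }
    grown <- grown & weak
    if (identical(grown, edges)) break
    edges <- grown
  }
  edges * 1
}
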