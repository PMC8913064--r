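#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit signed integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647)
}

assert_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (any(!is.finite(image))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 1) {
    stop(sprintf("`%s` intensities must lie in [0, 1]", arg), call. = FALSE)
  }
  invisible(image)
}

assert_mask <- function(mask, dim_ref = NULL, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  if (!all(mask %in% c(0, 1))) {
    stop(sprintf("`%s` must be binary (0/1)", arg), call. = FALSE)
  }
  if (!is.null(dim_ref) && !identical(dim(mask), dim(dim_ref))) {
    stop(sprintf("`%s` must have the same dimensions as the image", arg), call. = FALSE)
  }
  invisible(mask)
}

assert_scalar_number <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", arg), call. = FALSE)
  }
  invisible(x)
}

# pmin/pmax keep the attributes (incl. dim) of their first argument, so the
# data must come first or matrices silently collapse to vectors
clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Reflect-pad a matrix by `k` pixels on every side (edge row/col mirrored
# without repeating the border pixel is the classic "symmetric" policy;
# here we use symmetric-with-border-repeat, i.e. [b a | a b c | c b] style
# reflection including the edge pixel, matching scipy's "reflect"/"even").
pad_reflect <- function(x, k) {
  if (k == 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(rev(seq_len(min(k, nr))), seq_len(nr), nr + 1 - rev(seq_len(min(k, nr))))
  if (k > nr) stop("padding exceeds image size", call. = FALSE)
  ci <- c(rev(seq_len(min(k, nc))), seq_len(nc), nc + 1 - rev(seq_len(min(k, nc))))
  if (k > nc) stop("padding exceeds image size", call. = FALSE)
  x[ri, ci, drop = FALSE]
}

# Shift a matrix by (dr, dc) filling vacated cells with `fill`.
shift_mat <- function(x, dr, dc, fill = 0) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- x[src_r[ok_r], src_c[ok_c]]
  out
}
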