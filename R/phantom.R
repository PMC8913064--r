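#' Specify a synthetic brain phantom
#'
#' Describes a 2-D grayscale phantom: a brain-like ellipse of nested tissue
#' intensity classes on a dark background, optionally carrying a bright
#' elliptical tumor blob, corrupted by additive Gaussian intensity noise and
#' salt-and-pepper impulse noise. The phantom plays the role of an MRI slice
#' with exact ground truth, so that every stage of the detection pipeline can
#' be validated without access to clinical data.
#'
#' Intensities are real numbers in \eqn{[0,1]} throughout; quantization
#' happens only at GLCM/feature computation time and at 8-bit image export.
#' Salt-and-pepper corruption replaces each selected pixel by exactly 0 or 1
#' with equal probability, the impulse-noise model that median filtering
#' targets.
#'
#' @param height,width Image dimensions in pixels.
#' @param tissue_levels Mean intensities of the background and the nested
#'   tissue classes, ordered outside-in. The first entry is the background;
#'   each subsequent entry fills a concentric ellipse shrunk by equal steps.
#' @param tumor_present Logical; add a bright tumor ellipse?
#' @param tumor_center `(row, col)` center of the tumor ellipse, in pixels.
#' @param tumor_axes `(a, b)` semi-axes of the tumor ellipse (rows, cols).
#' @param tumor_intensity Mean intensity of the tumor blob in `[0, 1]`.
#' @param noise_density Fraction of pixels replaced by salt/pepper impulses.
#' @param gaussian_sigma Standard deviation of additive Gaussian intensity
#'   noise (intensity units; applied before impulse corruption and clipped
#'   back to `[0, 1]`).
#' @param seed Integer seed driving all randomness of the phantom.
#'
#' @return An object of class `phantom_spec` (a named list).
#' @examples
#' spec <- phantom_spec(noise_density = 0)
#' ph <- generate_phantom(spec)
#' table(ph$mask)
#' @export
phantom_spec <- function(height = 128L,
                         width = 128L,
                         tissue_levels = c(0, 0.35, 0.55),
                         tumor_present = TRUE,
                         tumor_center = c(round(height * 0.42), round(width * 0.6)),
                         tumor_axes = c(12, 9),
                         tumor_intensity = 0.9,
                         noise_density = 0.05,
                         gaussian_sigma = 0.02,
                         seed = 1L) {
  spec <- list(
    height = as.integer(height), width = as.integer(width),
    tissue_levels = as.numeric(tissue_levels),
    tumor_present = isTRUE(tumor_present),
    tumor_center = as.numeric(tumor_center),
    tumor_axes = as.numeric(tumor_axes),
    tumor_intensity = as.numeric(tumor_intensity),
    noise_density = as.numeric(noise_density),
    gaussian_sigma = as.numeric(gaussian_sigma),
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$height <= 0 || spec$width <= 0) {
    stop("phantom dimensions must be positive", call. = FALSE)
  }
  if (length(spec$tissue_levels) < 3) {
    stop("need a background level and at least two tissue levels", call. = FALSE)
  }
  if (any(spec$tissue_levels < 0 | spec$tissue_levels > 1)) {
    stop("tissue_levels must lie in [0, 1]", call. = FALSE)
  }
  if (spec$noise_density < 0 || spec$noise_density > 1) {
    stop("noise_density must lie in [0, 1]", call. = FALSE)
  }
  if (spec$tumor_intensity < 0 || spec$tumor_intensity > 1) {
    stop("tumor_intensity must lie in [0, 1]", call. = FALSE)
  }
  if (spec$gaussian_sigma < 0) stop("gaussian_sigma must be >= 0", call. = FALSE)
  if (spec$tumor_present) {
    geom <- brain_geometry(spec)
    # The tumor ellipse must sit fully inside the brain ellipse: check the
    # worst case along each principal direction of the tumor ellipse and on
    # a dense angular grid for safety.
    th <- seq(0, 2 * pi, length.out = 181L)
    tr <- spec$tumor_center[1] + spec$tumor_axes[1] * sin(th)
    tc <- spec$tumor_center[2] + spec$tumor_axes[2] * cos(th)
    inside <- ((tr - geom$cr) / geom$ar)^2 + ((tc - geom$cc) / geom$ac)^2 <= 1
    if (!all(inside)) {
      stop("tumor ellipse extends outside the brain ellipse", call. = FALSE)
    }
  }
  invisible(spec)
}

# Geometry of the brain ellipse: centered, covering ~60% of the frame.
brain_geometry <- function(spec) {
  list(
    cr = (spec$height + 1) / 2,
    cc = (spec$width + 1) / 2,
    ar = 0.44 * spec$height,
    ac = 0.44 * spec$width
  )
}

ellipse_mask <- function(height, width, cr, cc, ar, ac) {
  r <- matrix(seq_len(height), height, width)
  cl <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((r - cr) / ar)^2 + ((cl - cc) / ac)^2 <= 1
}

#' Generate one labeled phantom image
#'
#' Renders the noise-free phantom described by `spec` (concentric tissue
#' ellipses, plus the tumor blob when requested), then adds Gaussian
#' intensity noise, then salt-and-pepper corruption. Deterministic for a
#' fixed `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A `labeled_image`: list with `image` (matrix in `[0,1]`), `mask`
#'   (0/1 matrix marking tumor pixels), `label` (1 if any tumor pixel),
#'   `brain_mask` (0/1 matrix of the brain ellipse) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' ph$label
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  h <- spec$height; w <- spec$width
  geom <- brain_geometry(spec)

  img <- matrix(spec$tissue_levels[1], h, w)
  n_tissue <- length(spec$tissue_levels) - 1L
  # Nested ellipses: the outermost tissue class fills the brain ellipse,
  # each deeper class an ellipse shrunk by an equal fraction.
  brain <- ellipse_mask(h, w, geom$cr, geom$cc, geom$ar, geom$ac)
  for (i in seq_len(n_tissue)) {
    shrink <- 1 - (i - 1) / (n_tissue + 0.5)
    m <- if (i == 1) brain else {
      ellipse_mask(h, w, geom$cr, geom$cc, geom$ar * shrink, geom$ac * shrink)
    }
    img[m] <- spec$tissue_levels[i + 1]
  }

  mask <- matrix(0, h, w)
  if (spec$tumor_present) {
    tm <- ellipse_mask(h, w, spec$tumor_center[1], spec$tumor_center[2],
                       spec$tumor_axes[1], spec$tumor_axes[2])
    img[tm] <- spec$tumor_intensity
    mask[tm] <- 1
  }

  img <- with_seed(spec$seed, {
    if (spec$gaussian_sigma > 0) {
      img <- clamp01(img + matrix(stats::rnorm(h * w, 0, spec$gaussian_sigma), h, w))
    }
    if (spec$noise_density > 0) {
      hit <- matrix(stats::runif(h * w) < spec$noise_density, h, w)
      salt <- matrix(stats::runif(h * w) < 0.5, h, w)
      img[hit & salt] <- 1
      img[hit & !salt] <- 0
    }
    img
  })

  structure(
    list(image = img, mask = mask, label = as.integer(any(mask == 1)),
         brain_mask = brain * 1, spec = spec),
    class = "labeled_image"
  )
}

#' Generate a labeled phantom dataset
#'
#' Draws `n` phantoms with exactly `round(n * tumor_fraction)` tumor-positive
#' images. Tumor center, semi-axes and intensity, and the tissue intensity
#' levels, are jittered per image by a generator seeded from `seed`, so
#' images differ while remaining reproducible.
#'
#' @param n Number of images (positive integer).
#' @param tumor_fraction Fraction of images carrying a tumor, in `[0, 1]`.
#' @param spec_template A [phantom_spec()] providing the base parameters.
#' @param seed Integer seed for the whole dataset.
#' @return A list of `labeled_image` objects, with a tibble manifest in
#'   attribute `"manifest"` (columns `id`, `label`, `seed`).
#' @examples
#' ds <- generate_dataset(6, 0.5, phantom_spec(), seed = 1)
#' attr(ds, "manifest")
#' @export
generate_dataset <- function(n, tumor_fraction = 0.5,
                             spec_template = phantom_spec(),
                             seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (tumor_fraction < 0 || tumor_fraction > 1) {
    stop("`tumor_fraction` must lie in [0, 1]", call. = FALSE)
  }
  n <- as.integer(n)
  n_pos <- as.integer(round(n * tumor_fraction))
  labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))

  images <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      sp <- spec_template
      sp$seed <- derive_seed(seed, i)
      sp$tumor_present <- labels[i] == 1L
      # per-image jitter: tumor placement/size/brightness and tissue levels
      geom <- brain_geometry(sp)
      sp$tumor_axes <- pmax(4, sp$tumor_axes * stats::runif(2, 0.8, 1.2))
      sp$tumor_center <- c(
        geom$cr + stats::runif(1, -0.35, 0.35) * geom$ar,
        geom$cc + stats::runif(1, -0.35, 0.35) * geom$ac
      )
      sp$tumor_intensity <- clamp01(sp$tumor_intensity + stats::runif(1, -0.04, 0.04))
      lv <- sp$tissue_levels
      lv[-1] <- clamp01(lv[-1] + stats::runif(length(lv) - 1, -0.02, 0.02))
      sp$tissue_levels <- lv
      generate_phantom(sp)
    })
  })

  attr(images, "manifest") <- tibble::tibble(
    id = sprintf("phantom_%03d", seq_len(n)),
    label = labels,
    seed = vapply(images, function(im) im$spec$seed, integer(1))
  )
  images
}
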