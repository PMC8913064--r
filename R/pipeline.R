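#' Read a grayscale image into a [0,1] intensity matrix
#'
#' Reads an 8- or 16-bit grayscale PNG; `png::readPNG` already rescales to
#' `[0, 1]` by the format's maximum value. An RGB(A) image whose color
#' channels are identical is accepted as grayscale; genuinely colored or
#' multi-frame input is rejected with an explicit unsupported-format error.
#'
#' @param path Path to a PNG file.
#' @return Numeric matrix with intensities in `[0, 1]` (row, col indexed).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!grepl("\\.png$", path, ignore.case = TRUE)) {
    stop("unsupported format (only grayscale PNG is supported): ", path,
         call. = FALSE)
  }
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) {
    ch <- dim(x)[3]
    rgb <- x[, , seq_len(min(ch, 3L)), drop = FALSE]
    if (dim(rgb)[3] > 1) {
      spread <- max(abs(rgb[, , 1] - rgb[, , 2]), abs(rgb[, , 1] - rgb[, , dim(rgb)[3]]))
      if (spread > 1e-9) {
        stop("unsupported format: color image (expected grayscale)", call. = FALSE)
      }
    }
    x <- rgb[, , 1]
  }
  assert_image(x, arg = "decoded image")
  x
}

#' Write a [0,1] intensity matrix as an 8-bit grayscale PNG
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  assert_image(image)
  png::writePNG(image, path)
  invisible(path)
}

#' Write a phantom dataset to disk
#'
#' Writes each image as an 8-bit grayscale PNG with a sidecar `_mask.png`
#' and a CSV manifest (`filename`, `mask_filename`, `label`, `seed`).
#'
#' @param dataset A list of `labeled_image` objects from
#'   [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- attr(dataset, "manifest")
  if (is.null(man)) {
    man <- tibble::tibble(
      id = sprintf("phantom_%03d", seq_along(dataset)),
      label = vapply(dataset, function(im) im$label, integer(1)),
      seed = vapply(dataset, function(im) im$spec$seed, integer(1))
    )
  }
  man$filename <- paste0(man$id, ".png")
  man$mask_filename <- paste0(man$id, "_mask.png")
  for (i in seq_along(dataset)) {
    write_image(dataset[[i]]$image, file.path(dir, man$filename[i]))
    write_image(dataset[[i]]$mask, file.path(dir, man$mask_filename[i]))
  }
  utils::write.csv(man[, c("filename", "mask_filename", "label", "seed")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Pipeline configuration
#'
#' One flat configuration object covering every stage. Defaults mirror the
#' per-module defaults; unknown keys are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param preprocess_window Median filter window (odd).
#' @param canny_sigma,canny_low,canny_high Canny parameters (edge maps are
#'   diagnostic output only; they are not consumed downstream).
#' @param fcm_clusters,fcm_m,fcm_alpha,fcm_max_iter FCM parameters.
#' @param glcm_levels,glcm_offset,glcm_symmetric GLCM parameters.
#' @param network A [train_config()].
#' @param tune `"none"`, `"weights"` or `"hyper"`: optional APSO tuning.
#' @param apso_particles,apso_iters,apso_beta,apso_gamma APSO parameters.
#' @param train_fraction Fraction of images in the training split.
#' @param split_seed Seed of the stratified train/test split.
#' @param threshold Decision threshold on the network output.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preprocess_window = 3L,
                            canny_sigma = 1.4, canny_low = 0.1, canny_high = 0.2,
                            fcm_clusters = 4L, fcm_m = 2, fcm_alpha = 1e-5,
                            fcm_max_iter = 500L,
                            glcm_levels = 8L, glcm_offset = c(0L, 1L),
                            glcm_symmetric = TRUE,
                            network = train_config(),
                            tune = c("none", "weights", "hyper"),
                            apso_particles = 10L, apso_iters = 20L,
                            apso_beta = 0.5, apso_gamma = 0.97,
                            train_fraction = 0.5, split_seed = 1L,
                            threshold = 0.5) {
  cfg <- list(
    preprocess_window = as.integer(preprocess_window),
    canny_sigma = canny_sigma, canny_low = canny_low, canny_high = canny_high,
    fcm_clusters = as.integer(fcm_clusters), fcm_m = fcm_m,
    fcm_alpha = fcm_alpha, fcm_max_iter = as.integer(fcm_max_iter),
    glcm_levels = as.integer(glcm_levels), glcm_offset = as.integer(glcm_offset),
    glcm_symmetric = isTRUE(glcm_symmetric),
    network = network, tune = match.arg(tune),
    apso_particles = as.integer(apso_particles), apso_iters = as.integer(apso_iters),
    apso_beta = apso_beta, apso_gamma = apso_gamma,
    train_fraction = train_fraction, split_seed = as.integer(split_seed),
    threshold = threshold
  )
  stopifnot(cfg$train_fraction > 0, cfg$train_fraction < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

# Per-image stage runner: filter -> segment -> features (+ diagnostics).
process_image <- function(image, cfg, brain_mask = NULL, seed = 1L) {
  filtered <- median_filter(image, cfg$preprocess_window)
  edges <- canny_edges(filtered, cfg$canny_sigma, cfg$canny_low, cfg$canny_high)
  fit <- fcm_cluster(filtered, c = cfg$fcm_clusters, m = cfg$fcm_m,
                     alpha = cfg$fcm_alpha, max_iter = cfg$fcm_max_iter,
                     seed = seed)
  mask <- tumor_mask(fit, filtered, brain_mask)
  roi <- if (sum(mask) >= 2) mask else NULL
  feats <- extract_features(filtered, roi, cfg$glcm_levels,
                            cfg$glcm_offset, cfg$glcm_symmetric)
  list(filtered = filtered, edges = edges, fcm = fit, mask = mask,
       features = feats)
}

#' Run the full detection pipeline on a labeled dataset
#'
#' For every image: median filtering, Canny edge extraction (diagnostic
#' only), fuzzy c-means segmentation, tumor-mask extraction
#' (brightest-center cluster), and GLCM/intensity feature extraction over
#' the tumor ROI. The images are then split into stratified train/test
#' sets, the classifier is trained (optionally APSO-tuned) on the training
#' features, and Dice overlap plus held-out confusion-matrix metrics are
#' reported. Deterministic given the config seeds.
#'
#' @param dataset A list of `labeled_image` objects (see
#'   [generate_dataset()]), or a directory written by [write_dataset()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for artifacts (filtered images, masks,
#'   feature CSV, model JSON, metrics JSON).
#' @return An object of class `pipeline_result`: list with `metrics`
#'   (one-row tibble), `predictions` (per-image tibble: id, label, split,
#'   score, prediction, dice), `features`, `model`, `report` and
#'   `config`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(), out_dir = NULL) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  if (length(dataset) == 0) stop("dataset is empty", call. = FALSE)
  cfg <- config
  n <- length(dataset)
  labels <- purrr::map_int(dataset, "label")
  ids <- attr(dataset, "manifest")$id
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_len(n))

  staged <- purrr::map(seq_len(n), function(i) {
    bm <- dataset[[i]]$brain_mask
    process_image(dataset[[i]]$image, cfg, brain_mask = bm,
                  seed = derive_seed(cfg$split_seed, i))
  })
  features <- dplyr::bind_rows(purrr::map(staged, "features"))
  dice <- purrr::map_dbl(seq_len(n), function(i) {
    if (labels[i] == 1) dice_overlap(staged[[i]]$mask, dataset[[i]]$mask) else NA_real_
  })

  # stratified split
  split <- with_seed(cfg$split_seed, {
    s <- rep("test", n)
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      n_tr <- round(length(idx) * cfg$train_fraction)
      s[sample(idx, n_tr)] <- "train"
    }
    s
  })
  tr <- split == "train"
  if (length(unique(labels[tr])) < 2) {
    stop("training split contains a single class; rebalance the dataset",
         call. = FALSE)
  }

  Xtr <- as.matrix(features[tr, ]); ytr <- labels[tr]
  if (cfg$tune == "none") {
    fit <- lm_train(NULL, Xtr, ytr, cfg$network)
    tune_trace <- NULL
  } else {
    tuned <- apso_tune_network(Xtr, ytr, mode = cfg$tune, config = cfg$network,
                               n_particles = cfg$apso_particles,
                               n_iter = cfg$apso_iters,
                               beta = cfg$apso_beta, gamma = cfg$apso_gamma)
    fit <- list(model = tuned$model, report = tuned$report)
    tune_trace <- tuned$trace
  }

  Xall <- as.matrix(features)
  # impute NA (undefined correlation) with training means, as in training
  for (j in seq_len(ncol(Xall))) {
    bad <- is.na(Xall[, j])
    if (any(bad)) Xall[bad, j] <- fit$model$center[j]
  }
  scores <- nn_forward(fit$model, Xall)
  preds <- as.integer(scores >= cfg$threshold)

  te <- !tr
  cm <- confusion(labels[te], preds[te])
  metrics <- classification_metrics(cm)

  predictions <- tibble::tibble(
    id = ids, label = labels, split = split,
    score = scores, prediction = preds, dice = dice
  )

  result <- structure(
    list(metrics = metrics, predictions = predictions, features = features,
         model = fit$model, report = fit$report, tune_trace = tune_trace,
         config = cfg),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(result, staged, dataset, out_dir)
  result
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv` plus the image/mask PNGs.
#' @return A list of `labeled_image` objects with a manifest attribute.
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv in ", dir, call. = FALSE)
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  images <- lapply(seq_len(nrow(man)), function(i) {
    img <- read_image(file.path(dir, man$filename[i]))
    mask <- read_image(file.path(dir, man$mask_filename[i]))
    mask <- (mask > 0.5) * 1
    structure(list(image = img, mask = mask,
                   label = as.integer(man$label[i]),
                   brain_mask = NULL, spec = NULL),
              class = "labeled_image")
  })
  attr(images, "manifest") <- tibble::tibble(
    id = sub("\\.png$", "", man$filename),
    label = as.integer(man$label),
    seed = if ("seed" %in% names(man)) as.integer(man$seed) else NA_integer_
  )
  images
}

write_pipeline_artifacts <- function(result, staged, dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- result$predictions$id
  for (i in seq_along(staged)) {
    write_image(staged[[i]]$filtered, file.path(out_dir, paste0(ids[i], "_filtered.png")))
    write_image(staged[[i]]$mask, file.path(out_dir, paste0(ids[i], "_tumormask.png")))
    write_image(staged[[i]]$edges, file.path(out_dir, paste0(ids[i], "_edges.png")))
  }
  utils::write.csv(cbind(id = ids, result$features),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(result$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  write_network_json(result$model, file.path(out_dir, "model.json"))
  cfg <- result$config
  cfg$network <- unclass(cfg$network)
  report <- list(
    metrics = as.list(result$metrics),
    counts = result$metrics[c("tp", "tn", "fp", "fn")],
    config_echo = unclass(cfg),
    predictions = result$predictions
  )
  jsonlite::write_json(report, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "Tumor-detection pipeline on %d images (%d train / %d test)\n",
    nrow(x$predictions), sum(x$predictions$split == "train"),
    sum(x$predictions$split == "test")
  ))
  cat(sprintf("held-out sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
              m$sensitivity, m$specificity, m$accuracy))
  d <- x$predictions$dice
  if (any(!is.na(d))) {
    cat(sprintf("mean Dice on tumor images: %.3f\n", mean(d, na.rm = TRUE)))
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return One-row tibble: n, sensitivity, specificity, accuracy,
#'   precision, mean Dice on positives.
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$predictions),
    sensitivity = x$metrics$sensitivity,
    specificity = x$metrics$specificity,
    accuracy = x$metrics$accuracy,
    precision = x$metrics$precision,
    mean_dice = mean(x$predictions$dice, na.rm = TRUE)
  )
}

#' Plot per-image classifier scores by true label
#'
#' @param object A `pipeline_result`.
#' @param ... Unused.
#' @return A ggplot: scores against labels, colored by split, with the
#'   decision threshold drawn.
#' @method autoplot pipeline_result
#' @export
autoplot.pipeline_result <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$label), .data$score,
                                   color = .data$split)) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::geom_hline(yintercept = object$config$threshold, linetype = 2) +
    ggplot2::labs(x = "True label", y = "Network output")
}
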