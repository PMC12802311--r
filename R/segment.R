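# 3-class trainable pixel classification: CELL / BACKGROUND / INTERSPACE

SEG_CLASSES <- c("CELL", "BACKGROUND", "INTERSPACE")
FEATURE_VERSION <- 1L

#' Sparse pixel annotations for classifier training
#'
#' Holds hand-traced (or truth-derived) pixel labels over one image in the
#' three segmentation classes. Each pixel may be labelled at most once.
#'
#' @param row,col 1-based pixel coordinates.
#' @param class character vector over `"CELL"`, `"BACKGROUND"`,
#'   `"INTERSPACE"`.
#' @param image_ref identifier of the annotated image.
#' @param dim image dimensions `c(H, W)` used to validate coordinates.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(row, col, class, image_ref = "", dim = NULL) {
  if (length(row) != length(col) || length(row) != length(class))
    abort("annotation_set: row, col, class must have equal length")
  if (!all(class %in% SEG_CLASSES))
    abort("annotation_set: classes must be among %s",
          paste(SEG_CLASSES, collapse = ", "))
  if (!is.null(dim)) {
    if (any(row < 1 | row > dim[1] | col < 1 | col > dim[2]))
      abort("annotation_set: coordinates outside the %d x %d image",
            dim[1], dim[2])
  }
  if (anyDuplicated(cbind(row, col)))
    abort("annotation_set: a pixel is labelled more than once")
  structure(list(row = as.integer(row), col = as.integer(col),
                 class = factor(class, levels = SEG_CLASSES),
                 image_ref = image_ref, dim = dim),
            class = "annotation_set")
}

#' Read annotations from a label raster
#'
#' Raster convention: 0 = unlabeled, 1 = cell, 2 = background,
#' 3 = intercellular space.
#'
#' @param path TIFF/PNG path.
#' @param image_ref identifier to attach.
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, image_ref = path) {
  px <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(px)) > 2) px <- px[, , 1]
  m <- t(round(px * if (max(px) <= 1) 255 else 1))
  m[m > 3] <- 0
  idx <- which(m > 0)
  annotation_set(row = ((idx - 1L) %% nrow(m)) + 1L,
                 col = ((idx - 1L) %/% nrow(m)) + 1L,
                 class = SEG_CLASSES[m[idx]], image_ref = image_ref,
                 dim = dim(m))
}

#' Gaussian smoothing that tolerates sigma = 0
#' @noRd
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

# central-difference derivatives with replicated borders
#' @noRd
grad_mag <- function(s) {
  gx <- (shift_mat(s, 0, -1, fill = NA) - shift_mat(s, 0, 1, fill = NA)) / 2
  gy <- (shift_mat(s, -1, 0, fill = NA) - shift_mat(s, 1, 0, fill = NA)) / 2
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
  sqrt(gx^2 + gy^2)
}

#' @noRd
laplacian <- function(s) {
  up <- shift_mat(s, 1, 0, fill = NA); dn <- shift_mat(s, -1, 0, fill = NA)
  lf <- shift_mat(s, 0, 1, fill = NA); rt <- shift_mat(s, 0, -1, fill = NA)
  # replicate borders so a constant image gives exactly zero
  up[is.na(up)] <- s[is.na(up)]; dn[is.na(dn)] <- s[is.na(dn)]
  lf[is.na(lf)] <- s[is.na(lf)]; rt[is.na(rt)] <- s[is.na(rt)]
  up + dn + lf + rt - 4 * s
}

#' Per-pixel feature stack for pixel classification
#'
#' A compact fixed-order feature bank for discriminating dark rods, gray
#' background and light seams: Gaussian smoothings over a sigma ladder,
#' gradient magnitude and Laplacian of each smoothing, and
#' difference-of-Gaussians between consecutive ladder rungs. A sigma of 0
#' means the raw image.
#'
#' @param image a [raster_image()].
#' @param sigma_ladder non-negative, sorted smoothing scales in px.
#' @return object of class `feature_stack`: list with `values` (n_pixels x
#'   n_features matrix, pixels in column-major order), `names`, `dim`,
#'   `sigma_ladder`, `version`.
#' @export
compute_features <- function(image, sigma_ladder = c(0, 1, 2, 4, 8)) {
  stopifnot(inherits(image, "raster_image"))
  m <- image$pixels
  if (length(m) == 0) abort("compute_features: empty image")
  if (any(sigma_ladder < 0) || is.unsorted(sigma_ladder))
    abort("compute_features: sigma_ladder must be sorted and >= 0")
  sm <- lapply(sigma_ladder, function(s) gauss_smooth(m, s))
  feats <- list(); nms <- character(0)
  for (i in seq_along(sigma_ladder)) {
    s <- sigma_ladder[i]
    feats[[length(feats) + 1]] <- sm[[i]]
    nms <- c(nms, sprintf("gauss_s%g", s))
    feats[[length(feats) + 1]] <- grad_mag(sm[[i]])
    nms <- c(nms, sprintf("grad_s%g", s))
    feats[[length(feats) + 1]] <- laplacian(sm[[i]])
    nms <- c(nms, sprintf("lap_s%g", s))
  }
  if (length(sigma_ladder) > 1) {
    for (i in seq_len(length(sigma_ladder) - 1)) {
      feats[[length(feats) + 1]] <- sm[[i]] - sm[[i + 1]]
      nms <- c(nms, sprintf("dog_s%g_s%g", sigma_ladder[i],
                            sigma_ladder[i + 1]))
    }
  }
  vals <- vapply(feats, as.vector, numeric(length(m)))
  colnames(vals) <- nms
  if (any(!is.finite(vals))) abort("compute_features: non-finite feature")
  structure(list(values = vals, names = nms, dim = dim(m),
                 sigma_ladder = sigma_ladder, version = FEATURE_VERSION),
            class = "feature_stack")
}

#' Train the 3-class random-forest pixel classifier
#'
#' Fits a random forest on the feature vectors of the annotated pixels.
#' All three classes must be represented across the annotation sets.
#'
#' @param images list of [raster_image()] (or a single one).
#' @param annotations list of [annotation_set()] matching `images`.
#' @param n_trees number of trees (default 100).
#' @param max_depth maximal tree depth; `NULL` = unlimited.
#' @param seed RNG seed; fixed seed gives a reproducible forest.
#' @param sigma_ladder feature scales, see [compute_features()].
#' @return object of class `pixel_classifier` with the fitted forest, the
#'   feature configuration, and training metadata including in-sample
#'   accuracy.
#' @export
train_classifier <- function(images, annotations, n_trees = 100,
                             max_depth = NULL, seed = 1L,
                             sigma_ladder = c(0, 1, 2, 4, 8)) {
  if (inherits(images, "raster_image")) images <- list(images)
  if (inherits(annotations, "annotation_set"))
    annotations <- list(annotations)
  if (length(images) < 1 || length(images) != length(annotations))
    abort("train_classifier: need matching non-empty image/annotation lists")
  X <- list(); y <- list()
  for (i in seq_along(images)) {
    fs <- compute_features(images[[i]], sigma_ladder)
    a <- annotations[[i]]
    if (!is.null(a$dim) && !all(a$dim == fs$dim))
      abort("train_classifier: annotation %d does not match its image", i)
    idx <- (a$col - 1L) * fs$dim[1] + a$row
    X[[i]] <- fs$values[idx, , drop = FALSE]
    y[[i]] <- a$class
  }
  X <- do.call(rbind, X); y <- unlist(lapply(y, as.character))
  missing <- setdiff(SEG_CLASSES, unique(y))
  if (length(missing) > 0)
    abort("train_classifier: no annotated pixels for class %s",
          paste(missing, collapse = ", "))
  y <- factor(y, levels = SEG_CLASSES)
  df <- as.data.frame(X)
  fit <- ranger::ranger(x = df, y = y, num.trees = n_trees,
                        max.depth = if (is.null(max_depth)) 0 else max_depth,
                        probability = TRUE, seed = seed, num.threads = 1)
  pred <- predict(fit, data = df, num.threads = 1)$predictions
  acc <- mean(SEG_CLASSES[max.col(pred[, SEG_CLASSES])] == as.character(y))
  structure(list(model = fit, sigma_ladder = sigma_ladder,
                 classes = SEG_CLASSES, feature_version = FEATURE_VERSION,
                 meta = list(n_pixels = as.list(table(y)), seed = seed,
                             n_trees = n_trees,
                             training_accuracy = acc)),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(paste0("<pixel_classifier> random forest, %d trees, ",
                     "sigma ladder {%s}, training accuracy %.3f\n"),
              x$meta$n_trees, paste(x$sigma_ladder, collapse = ","),
              x$meta$training_accuracy))
  invisible(x)
}

#' Save / load a trained pixel classifier
#'
#' The serialized file carries the feature configuration and version, so a
#' reloaded classifier reproduces identical probability maps.
#'
#' @param classifier a `pixel_classifier`.
#' @param path file path.
#' @return `load_classifier` returns the classifier; `save_classifier`
#'   invisibly returns `path`.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  cl <- readRDS(path)
  if (!inherits(cl, "pixel_classifier"))
    abort("load_classifier: %s is not a pixel classifier file", path)
  if (cl$feature_version != FEATURE_VERSION)
    abort("load_classifier: feature version %d != supported %d",
          cl$feature_version, FEATURE_VERSION)
  cl
}

#' Per-pixel class probabilities for an image
#'
#' @param classifier a trained `pixel_classifier`.
#' @param image a [raster_image()].
#' @return object of class `prob_map`: list with `p` (H x W x 3 array,
#'   dimnames over the classes), `pixel_size`.
#' @export
predict_probabilities <- function(classifier, image) {
  stopifnot(inherits(classifier, "pixel_classifier"),
            inherits(image, "raster_image"))
  if (length(image$pixels) == 0) abort("predict_probabilities: empty image")
  fs <- compute_features(image, classifier$sigma_ladder)
  if (fs$version != classifier$feature_version)
    abort("predict_probabilities: feature configuration mismatch")
  pred <- predict(classifier$model, data = as.data.frame(fs$values),
                  num.threads = 1)$predictions
  pred <- pred[, classifier$classes, drop = FALSE]
  p <- array(pred, dim = c(fs$dim, 3),
             dimnames = list(NULL, NULL, classifier$classes))
  bad <- abs(rowSums(matrix(p, ncol = 3)) - 1) > 1e-6
  if (any(bad))
    abort("predict_probabilities: probabilities do not sum to 1")
  structure(list(p = p, pixel_size = image$pixel_size), class = "prob_map")
}

#' Binarize a probability map into a cell mask
#'
#' Thresholds the CELL probability; INTERSPACE and BACKGROUND both map to
#' off, which is what separates touching cells. Interior holes smaller
#' than `min_hole_px` are then filled.
#'
#' @param prob a `prob_map` from [predict_probabilities()].
#' @param threshold CELL-probability threshold in (0, 1); default 0.5.
#' @param min_hole_px fill enclosed background components smaller than
#'   this many pixels (0 = keep all holes).
#' @return logical matrix of class `binary_mask` with a `pixel_size`
#'   attribute.
#' @export
binarize <- function(prob, threshold = 0.5, min_hole_px = 0) {
  stopifnot(inherits(prob, "prob_map"))
  if (threshold <= 0 || threshold >= 1)
    abort("binarize: threshold must be in (0, 1)")
  mask <- prob$p[, , "CELL"] >= threshold
  if (min_hole_px > 0) mask <- fill_small_holes(mask, min_hole_px)
  structure(mask, class = c("binary_mask", class(mask)),
            pixel_size = prob$pixel_size)
}

# fill enclosed off-components (4-connectivity) smaller than max_px
#' @noRd
fill_small_holes <- function(mask, max_px) {
  holes <- EBImage::bwlabel(!mask)
  if (max(holes) == 0) return(mask)
  border <- unique(c(holes[1, ], holes[nrow(holes), ],
                     holes[, 1], holes[, ncol(holes)]))
  sizes <- tabulate(holes[holes > 0], nbins = max(holes))
  fill <- setdiff(which(sizes > 0 & sizes < max_px), border)
  if (length(fill) > 0) mask[holes %in% fill] <- TRUE
  mask
}
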