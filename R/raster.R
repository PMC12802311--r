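#' Grayscale raster with a physical pixel size
#'
#' The basic image carrier of the pipeline: a numeric matrix of intensities
#' (rows are image rows, top to bottom) plus the pixel size in micrometres
#' per pixel. Phase-contrast and fluorescence channels both use it.
#'
#' @param pixels numeric matrix of finite intensities (arbitrary units).
#' @param pixel_size physical pixel size, um/px (> 0).
#' @return an object of class `raster_image`.
#' @export
raster_image <- function(pixels, pixel_size) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort("raster_image: pixels must be a numeric matrix")
  if (any(!is.finite(pixels)))
    abort("raster_image: all intensities must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    abort("raster_image: pixel_size must be a single positive number")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' Integer-labelled connected components over a binary mask
#'
#' @param labels integer matrix; 0 is background, positive values are
#'   particle ids.
#' @param pixel_size um/px.
#' @return an object of class `label_image`.
#' @export
label_image <- function(labels, pixel_size) {
  if (!is.matrix(labels)) abort("label_image: labels must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE)) abort("label_image: negative labels")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    abort("label_image: pixel_size must be positive")
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  ids <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("<label_image> %d x %d px, %.4g um/px, %d particles\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size, length(ids)))
  invisible(x)
}

#' Crop a rectangular region from a raster
#'
#' Replaces interactive cropping of multilayered or oversaturated regions:
#' returns the sub-raster, preserving the pixel size.
#'
#' @param image a [raster_image()] or [label_image()].
#' @param rect integer vector `c(row, col, height, width)`, 1-based
#'   top-left corner plus extent, in pixels.
#' @return object of the same class as `image`.
#' @examples
#' img <- raster_image(matrix(runif(400), 20, 20), 0.1)
#' crop_region(img, c(5, 5, 10, 10))
#' @export
crop_region <- function(image, rect) {
  stopifnot(inherits(image, c("raster_image", "label_image")))
  if (length(rect) != 4 || any(rect[3:4] < 1))
    abort("crop_region: rect must be c(row, col, height, width)")
  m <- if (inherits(image, "raster_image")) image$pixels else image$labels
  r0 <- rect[1]; c0 <- rect[2]
  r1 <- r0 + rect[3] - 1; c1 <- c0 + rect[4] - 1
  if (r0 < 1 || c0 < 1 || r1 > nrow(m) || c1 > ncol(m))
    abort("crop_region: rectangle [%d:%d, %d:%d] outside %d x %d image",
          r0, r1, c0, c1, nrow(m), ncol(m))
  sub <- m[r0:r1, c0:c1, drop = FALSE]
  if (inherits(image, "raster_image")) raster_image(sub, image$pixel_size)
  else label_image(sub, image$pixel_size)
}

#' Read / write single-channel rasters as TIFF
#'
#' Thin wrappers around EBImage I/O. Intensities are stored scaled to the
#' file's bit depth; `scale` states the intensity that maps to full scale.
#'
#' @param path file path.
#' @param pixel_size um/px to attach on read.
#' @param image a [raster_image()].
#' @param bits 8 or 16 bit output.
#' @param scale intensity mapped to white (default 1).
#' @return `read_raster` returns a [raster_image()]; `write_raster`
#'   invisibly returns `path`.
#' @export
read_raster <- function(path, pixel_size) {
  px <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(px)) > 2) px <- px[, , 1]
  # EBImage stores x (columns) in dim 1; transpose to row-major convention
  raster_image(t(px), pixel_size)
}

#' @rdname read_raster
#' @export
write_raster <- function(image, path, bits = 16, scale = 1) {
  stopifnot(inherits(image, "raster_image"))
  px <- pmin(pmax(image$pixels / scale, 0), 1)
  EBImage::writeImage(EBImage::Image(t(px)), path, type = "tiff",
                      bits.per.sample = as.integer(bits))
  invisible(path)
}

#' @rdname read_raster
#' @export
write_label_tiff <- function(image, path) {
  stopifnot(inherits(image, "label_image"))
  mx <- max(image$labels)
  if (mx > 65535) abort("write_label_tiff: more than 65535 labels")
  EBImage::writeImage(EBImage::Image(t(image$labels) / 65535), path,
                      type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' @rdname read_raster
#' @export
read_label_tiff <- function(path, pixel_size) {
  px <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(px)) > 2) px <- px[, , 1]
  label_image(matrix(as.integer(round(t(px) * 65535)),
                     ncol(px), nrow(px)), pixel_size)
}
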