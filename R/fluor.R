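# per-cell fluorescence quantification with background-box normalization

#' Estimate background fluorescence from random cell-free boxes
#'
#' Places `n_boxes` square boxes of side `box_size` um uniformly at random
#' among all positions that contain no labelled cell pixel, and averages
#' their mean intensities. "Cell-free" is defined against the label image,
#' not against raw intensity, so the estimate is reproducible and
#' auditable. Boxes are sampled without replacement and non-overlapping
#' placements are preferred; overlap is permitted only if non-overlapping
#' placement fails, and that fallback is recorded.
#'
#' @param fluor fluorescence [raster_image()].
#' @param labels [label_image()] aligned with `fluor` (same shape and
#'   pixel size).
#' @param box_size box side, um (default 5).
#' @param n_boxes number of boxes (default 4).
#' @param seed RNG seed.
#' @return object of class `background_estimate`: `box_size`, `n_boxes`,
#'   `box_positions` (top-left corners, um), `box_means`,
#'   `mean_background`, `seed`, `overlap_allowed`.
#' @export
estimate_background <- function(fluor, labels, box_size = 5, n_boxes = 4,
                                seed = 1L) {
  stopifnot(inherits(fluor, "raster_image"), inherits(labels, "label_image"))
  if (!all(dim(fluor$pixels) == dim(labels$labels)) ||
      abs(fluor$pixel_size - labels$pixel_size) > 1e-9)
    abort("estimate_background: fluorescence and label rasters not aligned")
  ps <- fluor$pixel_size
  b <- max(1L, as.integer(round(box_size / ps)))
  H <- nrow(fluor$pixels); W <- ncol(fluor$pixels)
  if (b > H || b > W)
    abort("estimate_background: %g um box exceeds the image", box_size)
  # summed-area tables for O(1) box sums
  sat <- function(m) {
    s <- apply(m, 2, cumsum)
    t(apply(s, 1, cumsum))
  }
  S_cell <- sat(matrix(as.numeric(labels$labels > 0), H, W))
  S_flu <- sat(fluor$pixels)
  rr <- seq_len(H - b + 1); cc <- seq_len(W - b + 1)
  # vectorized box sums over all top-left positions
  block <- function(S) {
    A <- S[rr + b - 1, cc + b - 1, drop = FALSE]
    B <- matrix(0, length(rr), length(cc))
    if (rr[length(rr)] > 1) B[-1, ] <- S[rr[-length(rr)], cc + b - 1]
    C <- matrix(0, length(rr), length(cc))
    if (cc[length(cc)] > 1) C[, -1] <- S[rr + b - 1, cc[-length(cc)]]
    D <- matrix(0, length(rr), length(cc))
    if (length(rr) > 1 && length(cc) > 1)
      D[-1, -1] <- S[rr[-length(rr)], cc[-length(cc)]]
    A - B - C + D
  }
  cellsum <- block(S_cell)
  valid <- which(cellsum == 0)
  if (length(valid) < n_boxes)
    abort(paste0("estimate_background: only %d cell-free %g um box ",
                 "positions available, %d required"),
          length(valid), box_size, n_boxes)
  flusum <- block(S_flu)
  nr <- length(rr)
  with_seed(seed, {
    order_valid <- sample(valid)
    chosen <- integer(0)
    overlap_allowed <- FALSE
    for (v in order_valid) {
      r <- ((v - 1L) %% nr) + 1L; c <- ((v - 1L) %/% nr) + 1L
      ok <- TRUE
      for (u in chosen) {
        ru <- ((u - 1L) %% nr) + 1L; cu <- ((u - 1L) %/% nr) + 1L
        if (abs(r - ru) < b && abs(c - cu) < b) { ok <- FALSE; break }
      }
      if (ok) chosen <- c(chosen, v)
      if (length(chosen) == n_boxes) break
    }
    if (length(chosen) < n_boxes) {
      overlap_allowed <- TRUE
      extra <- setdiff(order_valid, chosen)
      chosen <- c(chosen, extra[seq_len(n_boxes - length(chosen))])
    }
    pr <- ((chosen - 1L) %% nr) + 1L
    pc <- ((chosen - 1L) %/% nr) + 1L
    means <- flusum[cbind(pr, pc)] / b^2
    structure(list(box_size = box_size, n_boxes = n_boxes,
                   box_positions = cbind(row_um = (pr - 1) * ps,
                                         col_um = (pc - 1) * ps),
                   box_px = cbind(row = pr, col = pc, side = b),
                   box_means = means,
                   mean_background = mean(means),
                   seed = seed, overlap_allowed = overlap_allowed),
              class = "background_estimate")
  })
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("<background_estimate> %d boxes of %g um, mean %.4g a.u.%s\n",
              x$n_boxes, x$box_size, x$mean_background,
              if (x$overlap_allowed) " (overlap fallback used)" else ""))
  invisible(x)
}

#' Background-normalized per-cell mean fluorescence
#'
#' Subtracts the estimated mean background from the fluorescence channel
#' and averages over each cell's pixels. Cells dimmer than background get
#' negative values (preserved, not clipped).
#'
#' @param fluor fluorescence [raster_image()].
#' @param labels aligned [label_image()].
#' @param background a [estimate_background()] result.
#' @param records optional `cell_records` table to augment; its ids must
#'   all be present in `labels`.
#' @return if `records` is given, the table with `mean_intensity` set;
#'   otherwise a data.frame `id, mean_intensity`.
#' @export
measure_intensity <- function(fluor, labels, background, records = NULL) {
  stopifnot(inherits(fluor, "raster_image"), inherits(labels, "label_image"),
            inherits(background, "background_estimate"))
  if (!all(dim(fluor$pixels) == dim(labels$labels)))
    abort("measure_intensity: rasters not aligned")
  lv <- as.vector(labels$labels)
  on <- lv > 0L
  sums <- rowsum(as.vector(fluor$pixels)[on], lv[on])
  cnts <- tabulate(lv[on])
  ids <- as.integer(rownames(sums))
  mi <- data.frame(id = ids,
                   mean_intensity = sums[, 1] / cnts[ids] -
                     background$mean_background)
  if (is.null(records)) return(mi)
  missing <- setdiff(records$id, mi$id)
  if (length(missing) > 0)
    abort("measure_intensity: label(s) %s absent from raster",
          paste(utils::head(missing, 5), collapse = ", "))
  records$mean_intensity <- mi$mean_intensity[match(records$id, mi$id)]
  records
}
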