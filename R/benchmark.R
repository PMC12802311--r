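# ground-truth matching and the end-to-end detection benchmark

#' Match detected particles to ground-truth cells by IoU
#'
#' Computes, for every ground-truth cell, the best
#' intersection-over-union against the detected particles (restricted to
#' `keep_ids` when given, e.g. filter survivors). A cell counts as
#' recovered when its best IoU reaches `iou_min`.
#'
#' @param truth_labels ground-truth [label_image()].
#' @param pred_labels detected [label_image()] (same shape).
#' @param truth_ids ids in `truth_labels` to evaluate (default: all).
#' @param keep_ids detected ids eligible for matching (default: all).
#' @param iou_min matching threshold (default 0.5).
#' @return data.frame `truth_id, pred_id, iou, matched`.
#' @export
match_cells <- function(truth_labels, pred_labels, truth_ids = NULL,
                        keep_ids = NULL, iou_min = 0.5) {
  stopifnot(inherits(truth_labels, "label_image"),
            inherits(pred_labels, "label_image"))
  tl <- as.vector(truth_labels$labels)
  pl <- as.vector(pred_labels$labels)
  if (length(tl) != length(pl)) abort("match_cells: rasters not aligned")
  if (is.null(truth_ids))
    truth_ids <- sort(setdiff(unique(tl), 0L))
  t_sizes <- tabulate(tl)
  p_sizes <- tabulate(pl)
  sel <- tl > 0L & pl > 0L
  if (!is.null(keep_ids)) sel <- sel & pl %in% keep_ids
  best_iou <- setNames(rep(0, length(truth_ids)), truth_ids)
  best_pred <- setNames(rep(NA_integer_, length(truth_ids)), truth_ids)
  if (any(sel)) {
    ov <- table(truth = tl[sel], pred = pl[sel])
    tids <- as.integer(rownames(ov)); pids <- as.integer(colnames(ov))
    for (i in seq_along(tids)) {
      ti <- tids[i]
      if (!ti %in% truth_ids) next
      inter <- as.numeric(ov[i, ])
      iou <- inter / (t_sizes[ti] + p_sizes[pids] - inter)
      j <- which.max(iou)
      key <- as.character(ti)
      best_iou[key] <- iou[j]
      best_pred[key] <- pids[j]
    }
  }
  data.frame(truth_id = truth_ids, pred_id = unname(best_pred),
             iou = unname(best_iou), matched = unname(best_iou) >= iou_min)
}

#' Calibrate the binarization threshold on annotated training frames
#'
#' The interactive workflow this package automates adjusts the mask
#' threshold per condition by eye; this is the reproducible counterpart.
#' For each candidate threshold the full detection chain (binarize, label,
#' measure, filter) runs on the supplied training scenes, and the
#' threshold with the highest mean ground-truth recovery (IoU >= 0.5) is
#' returned. Only frames whose truth the annotator used for training
#' should be supplied; held-out frames stay untouched.
#'
#' @param classifier a trained `pixel_classifier`.
#' @param scenes list of `swarm_scene` training frames.
#' @param grid candidate thresholds.
#' @param iou_min matching threshold.
#' @param filters a [filter_config()].
#' @return the selected threshold, with the per-threshold recovery grid as
#'   attribute `"recovery"`.
#' @export
calibrate_threshold <- function(classifier, scenes,
                                grid = c(0.4, 0.5, 0.6, 0.7),
                                iou_min = 0.5, filters = filter_config()) {
  stopifnot(length(scenes) >= 1)
  rec <- matrix(0, length(scenes), length(grid))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    pm <- predict_probabilities(classifier, sc$phase)
    for (j in seq_along(grid)) {
      mask <- binarize(pm, threshold = grid[j], min_hole_px = 40)
      labs <- label_particles(mask, sc$phase$pixel_size)
      surv <- apply_filters(measure_all(labs), filters)
      m <- match_cells(sc$truth$label_image, labs,
                       truth_ids = sc$truth$cells$id,
                       keep_ids = surv$id, iou_min = iou_min)
      rec[i, j] <- mean(m$matched)
    }
  }
  means <- colMeans(rec)
  out <- grid[which.max(means)]
  attr(out, "recovery") <- stats::setNames(means, grid)
  out
}

#' End-to-end detection benchmark on synthetic dense monolayers
#'
#' Generates seeded dense scenes from the timecourse presets, trains the
#' three-class pixel classifier on truth-derived annotations from a few
#' frames, runs segmentation, particle measurement and the debris-filter
#' cascade on every frame, and reports the fraction of ground-truth cells
#' recovered (best IoU >= `iou_min` against a filter survivor).
#'
#' @param hours timecourse hours, one scene per entry (default
#'   `c(2, 4, 5, 6, 7)`).
#' @param n_cells cells per frame (default 650).
#' @param n_train number of frames whose annotations train the classifier
#'   (default 4, the upper end of the two-to-four annotated images the
#'   workflow assumes).
#' @param n_trees forest size (default 50).
#' @param threshold binarization threshold; `NULL` (default) calibrates it
#'   on the densest training frame via [calibrate_threshold()].
#' @param iou_min matching threshold (default 0.5).
#' @param seed master seed; per-frame seeds are derived from it.
#' @param filters a [filter_config()].
#' @param verbose print per-frame recovery.
#' @return list: `recovery` (overall matched fraction), `per_frame`
#'   data.frame, `n_truth`, `n_matched`, and the trained classifier.
#' @export
detection_benchmark <- function(hours = c(2, 4, 5, 6, 7), n_cells = 650,
                                n_train = 4, n_trees = 50, threshold = NULL,
                                iou_min = 0.5, seed = 1L,
                                filters = filter_config(),
                                verbose = FALSE) {
  seeds <- seed * 101L + seq_along(hours)
  scenes <- mapply(function(h, s) generate_scene(
    timecourse_presets(h, n_cells = n_cells, seed = s)),
    hours, seeds, SIMPLIFY = FALSE)
  tr <- seq_len(min(n_train, length(scenes)))
  anns <- lapply(scenes[tr], annotate_scene, n_per_class = 4000,
                 seed = seed + 7L)
  cl <- train_classifier(lapply(scenes[tr], `[[`, "phase"), anns,
                         n_trees = n_trees, seed = seed)
  if (is.null(threshold)) {
    dense <- tr[which.max(vapply(scenes[tr], function(s)
      s$config$long_fraction, numeric(1)))]
    threshold <- calibrate_threshold(cl, scenes[dense], filters = filters,
                                     iou_min = iou_min)
    if (verbose)
      message(sprintf("calibrated threshold: %.2f", threshold))
  }
  per_frame <- list()
  n_truth <- 0; n_matched <- 0
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    pm <- predict_probabilities(cl, sc$phase)
    mask <- binarize(pm, threshold = threshold, min_hole_px = 40)
    labs <- label_particles(mask, sc$phase$pixel_size)
    recs <- measure_all(labs)
    surv <- apply_filters(recs, filters)
    mm <- match_cells(sc$truth$label_image, labs,
                      truth_ids = sc$truth$cells$id,
                      keep_ids = surv$id, iou_min = iou_min)
    per_frame[[i]] <- data.frame(hour = hours[i],
                                 n_truth = nrow(mm),
                                 n_matched = sum(mm$matched),
                                 recovery = mean(mm$matched))
    n_truth <- n_truth + nrow(mm)
    n_matched <- n_matched + sum(mm$matched)
    if (verbose)
      message(sprintf("frame %d (hour %d): %d/%d recovered (%.1f%%)",
                      i, hours[i], sum(mm$matched), nrow(mm),
                      100 * mean(mm$matched)))
  }
  list(recovery = n_matched / n_truth,
       per_frame = do.call(rbind, per_frame),
       n_truth = n_truth, n_matched = n_matched, classifier = cl)
}
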