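# end-to-end batch pipeline and overlay rendering

#' Render an overlay of detected particles on the phase image
#'
#' `length_type` mode fills short (<= 4 um) cells green and long (> 4 um)
#' cells blue over the grayscale phase image; `outline` mode draws each
#' particle's boundary pixels in yellow.
#'
#' @param phase [raster_image()] phase channel.
#' @param records `cell_records` with `type` set (for `length_type`).
#' @param labels aligned [label_image()].
#' @param mode `"length_type"` or `"outline"`.
#' @param file optional PNG path to write.
#' @return H x W x 3 RGB array in \[0, 1\], invisibly when written.
#' @export
render_overlay <- function(phase, records, labels,
                           mode = c("length_type", "outline"),
                           file = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(phase, "raster_image"), inherits(labels, "label_image"))
  if (!all(dim(phase$pixels) == dim(labels$labels)))
    abort("render_overlay: rasters not aligned")
  base <- pmin(pmax(phase$pixels, 0), 1)
  rgb <- array(rep(base, 3), dim = c(dim(base), 3))
  lab <- labels$labels
  if (nrow(records) > 0) {
    if (mode == "length_type") {
      if (all(is.na(records$type)))
        abort("render_overlay: records have no type; run classify_length()")
      cols <- list(SHORT = c(0, 0.8, 0.2), LONG = c(0.1, 0.3, 1))
      for (ty in c("SHORT", "LONG")) {
        ids <- records$id[records$type == ty]
        if (length(ids) == 0) next
        sel <- which(matrix(lab %in% ids, nrow(lab), ncol(lab)))
        for (ch in 1:3)
          rgb[sel + (ch - 1) * length(lab)] <- cols[[ty]][ch]
      }
    } else {
      boundary <- matrix(FALSE, nrow(lab), ncol(lab))
      for (k in seq_len(nrow(neigh8))) {
        nb <- shift_mat(lab, neigh8[k, 1], neigh8[k, 2], fill = 0L)
        boundary <- boundary | (lab > 0L & nb != lab)
      }
      boundary <- boundary & matrix(lab %in% records$id,
                                    nrow(lab), ncol(lab))
      sel <- which(boundary)
      rgb[sel] <- 1; rgb[sel + length(lab)] <- 1
      rgb[sel + 2 * length(lab)] <- 0
    }
  }
  if (!is.null(file)) {
    img <- EBImage::Image(aperm(rgb, c(2, 1, 3)), colormode = "Color")
    EBImage::writeImage(img, file, type = "png")
    return(invisible(rgb))
  }
  rgb
}

#' Run the full synthetic pipeline from one declarative configuration
#'
#' Replaces the interactive GUI workflow with a reproducible batch run:
#' simulate -> train -> segment -> measure/filter -> fluorescence ->
#' population analysis, writing all intermediate artifacts plus a JSON
#' manifest (package version, per-stage seeds, counts, timings, and every
#' file written). Stages run only if their config section is present;
#' re-running with identical config and seeds reproduces identical tables.
#'
#' @param config nested list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{out_dir}{output directory (required).}
#'     \item{simulate}{list: `hours` (vector, one scene per entry) or a
#'       full [scene_config()] argument list; `n_cells`; `seed`.}
#'     \item{train}{list: `n_train` frames, `n_per_class`, `n_trees`,
#'       `seed`. Requires `simulate`.}
#'     \item{segment}{list: `threshold`, `min_hole_px`.}
#'     \item{filters}{[filter_config()] argument list.}
#'     \item{fluor}{list: `box_size`, `n_boxes`, `seed`.}
#'     \item{analyze}{list: `n_boot`, `seed`.}
#'   }
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) abort("run_pipeline: out_dir required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "swarmetrics",
                   version = as.character(utils::packageVersion("swarmetrics")),
                   stages = list(), files = character(0))
  t_start <- proc.time()[3]
  add_stage <- function(name, info) {
    info$elapsed_s <- round(proc.time()[3] - t_start, 2)
    manifest$stages[[name]] <<- info
  }
  add_files <- function(f) manifest$files <<- c(manifest$files, f)
  out <- function(...) file.path(config$out_dir, sprintf(...))

  scenes <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    seed0 <- if (is.null(sim$seed)) 1L else as.integer(sim$seed)
    hours <- sim$hours
    if (!is.null(hours)) {
      extra <- sim[setdiff(names(sim), c("seed", "hours", "n_cells"))]
      scenes <- lapply(seq_along(hours), function(i)
        generate_scene(do.call(timecourse_presets, c(list(
          hours[i], n_cells = if (is.null(sim$n_cells)) 650 else sim$n_cells,
          seed = seed0 * 101L + i), extra))))
      names(scenes) <- sprintf("hour%d_f%d", hours, seq_along(hours))
    } else {
      args <- sim[setdiff(names(sim), c("seed", "hours"))]
      args$seed <- seed0
      scenes <- list(scene1 = do.call(scene_config, args))
      scenes <- lapply(scenes, generate_scene)
    }
    for (nm in names(scenes))
      add_files(write_scene(scenes[[nm]], file.path(config$out_dir, nm)))
    add_stage("simulate", list(n_scenes = length(scenes), seed = seed0,
                               n_cells = vapply(scenes, function(s)
                                 nrow(s$truth$cells), numeric(1))))
  }

  classifier <- NULL
  if (!is.null(config$train)) {
    if (is.null(scenes)) abort("run_pipeline: train requires simulate")
    tr <- config$train
    n_train <- min(if (is.null(tr$n_train)) 3 else tr$n_train,
                   length(scenes))
    seed <- if (is.null(tr$seed)) 1L else as.integer(tr$seed)
    anns <- lapply(scenes[seq_len(n_train)], annotate_scene,
                   n_per_class = if (is.null(tr$n_per_class)) 3000
                                 else tr$n_per_class,
                   seed = seed + 7L)
    classifier <- train_classifier(
      lapply(scenes[seq_len(n_train)], `[[`, "phase"), anns,
      n_trees = if (is.null(tr$n_trees)) 100 else tr$n_trees, seed = seed)
    f <- out("classifier.rds")
    save_classifier(classifier, f); add_files(f)
    add_stage("train", list(n_train = n_train, seed = seed,
                            accuracy = classifier$meta$training_accuracy))
  }

  tables <- NULL
  if (!is.null(config$segment) && !is.null(classifier)) {
    sg <- config$segment
    thr <- if (is.null(sg$threshold)) 0.5 else sg$threshold
    hole <- if (is.null(sg$min_hole_px)) 40 else sg$min_hole_px
    fcfg <- do.call(filter_config,
                    if (is.null(config$filters)) list() else config$filters)
    counts <- list()
    tables <- list()
    for (nm in names(scenes)) {
      sc <- scenes[[nm]]
      pm <- predict_probabilities(classifier, sc$phase)
      mask <- binarize(pm, threshold = thr, min_hole_px = hole)
      labs <- label_particles(mask, sc$phase$pixel_size)
      recs <- measure_all(labs)
      surv <- classify_length(apply_filters(recs, fcfg))
      if (!is.null(sc$fluor) && !is.null(config$fluor)) {
        fl <- config$fluor
        bg <- estimate_background(
          sc$fluor, labs,
          box_size = if (is.null(fl$box_size)) 5 else fl$box_size,
          n_boxes = if (is.null(fl$n_boxes)) 4 else fl$n_boxes,
          seed = if (is.null(fl$seed)) 1L else as.integer(fl$seed))
        surv <- measure_intensity(sc$fluor, labs, bg, surv)
        jf <- out("%s_background.json", nm)
        jsonlite::write_json(list(
          mean_background = bg$mean_background,
          box_means = bg$box_means,
          box_positions_um = as.data.frame(bg$box_positions),
          overlap_allowed = bg$overlap_allowed, seed = bg$seed),
          jf, auto_unbox = TRUE, digits = NA)
        add_files(jf)
      }
      fm <- out("%s_mask.tif", nm)
      write_raster(raster_image(mask * 1, sc$phase$pixel_size), fm)
      fl2 <- out("%s_pred_labels.tif", nm)
      write_label_tiff(labs, fl2)
      fc <- out("%s_cells.csv", nm)
      utils::write.csv(surv, fc, row.names = FALSE)
      fo <- out("%s_overlay.png", nm)
      render_overlay(sc$phase, surv, labs, "length_type", file = fo)
      add_files(c(fm, fl2, fc, fo))
      surv$frame <- nm
      tables[[nm]] <- surv
      counts[[nm]] <- list(particles = nrow(recs), survivors = nrow(surv))
    }
    add_stage("segment_measure", list(threshold = thr, counts = counts))
  }

  if (!is.null(config$analyze) && !is.null(tables)) {
    an <- config$analyze
    all_cells <- do.call(rbind, tables)
    summ <- summarize_population(
      all_cells, group_key = "frame", feature = "length",
      n_boot = if (is.null(an$n_boot)) 1000 else an$n_boot,
      seed = if (is.null(an$seed)) 1L else as.integer(an$seed))
    fs <- out("summary.csv")
    utils::write.csv(summ, fs, row.names = FALSE)
    ft <- out("trajectory.csv")
    utils::write.csv(subpopulation_trajectory(summ), ft, row.names = FALSE)
    add_files(c(fs, ft))
    if (length(tables) >= 2) {
      pw <- pairwise_wilcoxon(all_cells, "frame", "length")
      fp <- out("pairwise_tests.csv")
      utils::write.csv(pw, fp, row.names = FALSE)
      add_files(fp)
    }
    if (any(!is.na(all_cells$mean_intensity))) {
      rg <- regress_intensity_on_length(all_cells)
      fr <- out("regression.json")
      jsonlite::write_json(unclass(rg), fr, auto_unbox = TRUE, digits = NA)
      add_files(fr)
    }
    add_stage("analyze", list(n_groups = nrow(summ),
                              n_cells = nrow(all_cells)))
  }

  manifest$files <- unname(manifest$files)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
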