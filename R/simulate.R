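#' Configuration for a synthetic dense-swarm scene
#'
#' Describes one phase-contrast-like frame of a swarming monolayer: dark,
#' bent or S-shaped rod cells on a gray agar background, touching cells
#' separated by a thin lighter seam (the "intercellular space" signal),
#' faint flagella-like filaments, sub-micron debris, and optionally a
#' fluorescence channel whose per-cell intensity is weakly linearly coupled
#' to cell length.
#'
#' Lengths are split at the biological doubling boundary: short cells are
#' > 1 um and at most 4 um long, long cells exceed 4 um, and debris is at
#' most 1 um. `long_fraction` sets the proportion of long cells.
#'
#' The fluorescence model draws each cell's mean intensity as
#' `slope * length + intercept + e`, with `Var(e)` calibrated from the
#' population length variance so the population R-squared of intensity on
#' length converges to `r_squared_target`:
#' `sigma^2 = slope^2 * Var(length) * (1 - r) / r`.
#'
#' The default width distribution is a placeholder (no measured width
#' parameters are available for the organism's swarm strains beyond the
#' observation that width changes little); adjust it for other systems.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param pixel_size um/px. Default 0.1 gives ~8 px across a typical cell.
#' @param n_cells number of cells to place.
#' @param long_fraction proportion of long (> 4 um) cells, in \[0, 1\].
#' @param short_length_dist,long_length_dist,width_dist,sinuosity_dist,debris_length_dist
#'   [dist_spec()] objects in um (sinuosity dimensionless, >= 1).
#' @param n_debris number of sub-micron debris particles.
#' @param filament_density flagella-like filaments per 100 um^2.
#' @param cell_overlap maximal fraction of a cell's pixels allowed to
#'   overlap previously placed cells (the earlier cell keeps the contested
#'   pixels, so touching cells share a contact surface); 0 gives
#'   non-touching scenes.
#' @param fluorescence_model `NULL`, or
#'   `list(slope, intercept, r_squared_target)` (a.u./um, a.u., proportion).
#' @param noise_sd additive Gaussian pixel noise, a.u.
#' @param psf_sigma Gaussian point-spread blur, px.
#' @param seed integer RNG seed; identical seeds give identical scenes.
#' @param levels rendering gray levels: named list with `background`,
#'   `cell`, `seam`, `filament`, `fluor_background` (a.u. in \[0, 1\] for
#'   the phase channel).
#' @return an object of class `scene_config`.
#' @seealso [generate_scene()], [timecourse_presets()]
#' @export
scene_config <- function(image_size = c(1024, 1024),
                         pixel_size = 0.1,
                         n_cells = 650,
                         long_fraction = 0.3,
                         short_length_dist = dist_spec("normal", mean = 2.6,
                                                       sd = 0.7, min = 1.05,
                                                       max = 4),
                         long_length_dist = dist_spec("lognormal",
                                                      meanlog = log(6.5),
                                                      sdlog = 0.35,
                                                      min = 4.05, max = 20),
                         width_dist = dist_spec("normal", mean = 0.8,
                                                sd = 0.05, min = 0.6,
                                                max = 1.0),
                         sinuosity_dist = dist_spec("normal", mean = 1.07,
                                                    sd = 0.07, min = 1,
                                                    max = 1.5),
                         n_debris = 60,
                         debris_length_dist = dist_spec("uniform",
                                                        min = 0.25, max = 1),
                         filament_density = 0.4,
                         cell_overlap = 0.1,
                         fluorescence_model = NULL,
                         noise_sd = 0.03,
                         psf_sigma = 1,
                         seed = 1L,
                         levels = list(background = 0.55, cell = 0.15,
                                       seam = 0.75, filament = 0.68,
                                       fluor_background = 0.5)) {
  cfg <- structure(list(
    image_size = as.integer(image_size), pixel_size = pixel_size,
    n_cells = as.integer(n_cells), long_fraction = long_fraction,
    short_length_dist = short_length_dist,
    long_length_dist = long_length_dist,
    width_dist = width_dist, sinuosity_dist = sinuosity_dist,
    n_debris = as.integer(n_debris),
    debris_length_dist = debris_length_dist,
    filament_density = filament_density,
    cell_overlap = cell_overlap,
    fluorescence_model = fluorescence_model,
    noise_sd = noise_sd, psf_sigma = psf_sigma,
    seed = as.integer(seed), levels = levels), class = "scene_config")
  validate_scene_config(cfg)
  cfg
}

#' Validate a scene configuration
#'
#' Checks geometric and categorical invariants: positive pixel size, the
#' 4 um short/long category boundary, the 1 um debris bound, sinuosity
#' >= 1, and a well-formed fluorescence model.
#'
#' @param config a [scene_config()].
#' @return `config`, invisibly; errors describe the violated invariant.
#' @export
validate_scene_config <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with(config, {
    if (length(image_size) != 2 || any(image_size < 8))
      abort("scene_config: image_size must be c(H, W), each >= 8 px")
    if (pixel_size <= 0) abort("scene_config: pixel_size must be > 0")
    if (n_cells < 0 || n_debris < 0) abort("scene_config: negative counts")
    if (!is_prob(long_fraction))
      abort("scene_config: long_fraction must be in [0, 1]")
    s <- dist_support(short_length_dist)
    if (s[1] <= 1 || s[2] > 4)
      abort("scene_config: short lengths must lie in (1, 4] um")
    l <- dist_support(long_length_dist)
    if (l[1] <= 4) abort("scene_config: long lengths must be > 4 um")
    d <- dist_support(debris_length_dist)
    if (d[2] > 1) abort("scene_config: debris lengths must be <= 1 um")
    if (d[1] <= 0) abort("scene_config: debris lengths must be > 0")
    if (dist_support(sinuosity_dist)[1] < 1)
      abort("scene_config: sinuosity must be >= 1")
    if (dist_support(width_dist)[1] <= 0)
      abort("scene_config: widths must be > 0")
    if (!is.null(fluorescence_model)) {
      fm <- fluorescence_model
      if (!all(c("slope", "intercept", "r_squared_target") %in% names(fm)))
        abort("scene_config: fluorescence_model needs slope, intercept, r_squared_target")
      if (fm$r_squared_target <= 0 || fm$r_squared_target > 1)
        abort("scene_config: r_squared_target must be in (0, 1]")
    }
    if (noise_sd < 0 || psf_sigma < 0)
      abort("scene_config: noise_sd and psf_sigma must be >= 0")
  })
  invisible(config)
}

# --- population sampling (shared by rendering and by desk-scale studies) ---

#' Sample a synthetic cell population without rendering it
#'
#' Draws per-cell ground-truth attributes (length, width, sinuosity, and,
#' if the configuration carries a fluorescence model, mean intensity) from
#' the same generative model [generate_scene()] renders. Useful for
#' population-scale studies (e.g. intensity-length regression at thousands
#' of cells) where rasterization is unnecessary.
#'
#' @param n number of cells.
#' @param config a [scene_config()]; only the distributional fields are
#'   used.
#' @param seed RNG seed (defaults to the config's seed).
#' @return data.frame with columns `id`, `true_length`, `true_width`,
#'   `true_sinuosity`, and `true_mean_intensity` when a fluorescence model
#'   is present.
#' @export
sample_cell_population <- function(n, config = scene_config(),
                                   seed = config$seed) {
  validate_scene_config(config)
  with_seed(seed, sample_cells_impl(n, config))
}

#' @noRd
sample_cells_impl <- function(n, config) {
  if (n == 0) {
    return(data.frame(id = integer(0), true_length = numeric(0),
                      true_width = numeric(0), true_sinuosity = numeric(0)))
  }
  is_long <- stats::runif(n) < config$long_fraction
  len <- numeric(n)
  len[is_long] <- sample_dist(config$long_length_dist, sum(is_long))
  len[!is_long] <- sample_dist(config$short_length_dist, sum(!is_long))
  wid <- sample_dist(config$width_dist, n)
  sin <- sample_dist(config$sinuosity_dist, n)
  out <- data.frame(id = seq_len(n), true_length = len, true_width = wid,
                    true_sinuosity = sin)
  fm <- config$fluorescence_model
  if (!is.null(fm)) out$true_mean_intensity <- sample_fluorescence(len, fm)
  out
}

#' Draw per-cell fluorescence intensities from the length-coupled model
#'
#' Each cell's mean intensity is `slope * length + intercept + e` with
#' `e ~ N(0, sigma)` and `sigma^2 = slope^2 * Var(length) * (1 - r) / r`
#' (the standard R-squared identity for simple linear regression), so the
#' population R-squared of intensity on length converges to the target `r`
#' as the population grows. `Var(length)` is the sample variance of the
#' lengths supplied, so the calibration refers to the population the model
#' is applied to — pool lengths first when emulating a pooled data set.
#'
#' @param lengths cell lengths, um.
#' @param model `list(slope, intercept, r_squared_target)`.
#' @return numeric vector of intensities (a.u.).
#' @export
sample_fluorescence <- function(lengths, model) {
  n <- length(lengths)
  mu <- model$slope * lengths + model$intercept
  r <- model$r_squared_target
  sigma2 <- if (r >= 1 || n < 2) 0 else
    model$slope^2 * stats::var(lengths) * (1 - r) / r
  mu + stats::rnorm(n, 0, sqrt(sigma2))
}

# --- backbone geometry ---

# Build a bounded-curvature random-walk backbone of arc length `arc_um`
# aiming at `target_sin` sinuosity (arc/chord): the heading increments are
# drawn once and globally scaled (monotone bisection). Curvature is
# physically bounded — the bend radius never drops below 1.2 cell widths
# and the total turn is capped — so very short cells stay nearly straight
# no matter what sinuosity was drawn; the realized arc/chord ratio is
# returned alongside the polyline and recorded as ground truth.
#' @noRd
make_backbone <- function(arc_um, target_sin, width_um = 0.8,
                          step_um = 0.1) {
  n_step <- max(2L, as.integer(round(arc_um / step_um)))
  step <- arc_um / n_step
  theta0 <- stats::runif(1, 0, 2 * pi)
  # constant bias gives C shapes, the noise term S shapes
  incr <- stats::rnorm(1, 0, 0.6) + stats::rnorm(n_step, 0, 0.8)
  # curvature bound: bend radius >= 1.2 widths, total turn <= 2.2 rad
  max_incr <- step / (1.2 * width_um)
  phi_max <- min(arc_um / (2 * 1.2 * width_um), 2.2 / 2)
  sin_max <- if (phi_max < 1e-3) 1 else phi_max / sin(phi_max)
  target_sin <- min(target_sin, sin_max)
  build <- function(c_scale) {
    d <- pmin(pmax(incr * c_scale, -max_incr), max_incr)
    th <- theta0 + c(0, cumsum(d[-1]))
    cbind(x = cumsum(step * cos(th)), y = cumsum(step * sin(th)))
  }
  result <- function(c_scale) {
    p <- rbind(c(0, 0), build(c_scale))
    chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    list(poly = p, sinuosity = arc_um / max(chord, 1e-9))
  }
  if (target_sin <= 1.0005) return(result(0))
  sin_of <- function(c_scale) result(c_scale)$sinuosity
  hi <- 0.02
  while (sin_of(hi) < target_sin && hi < 50) hi <- hi * 2
  c_star <- if (sin_of(hi) < target_sin) hi else
    stats::uniroot(function(cc) sin_of(cc) - target_sin,
                   c(0, hi), tol = 1e-6)$root
  result(c_star)
}

# Pixels within w/2 of a polyline (coords in px, 1-based, x = col, y = row)
#' @noRd
polyline_pixels <- function(poly, half_w, H, W) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  c0 <- max(1L, floor(xr[1] - half_w - 1)); c1 <- min(W, ceiling(xr[2] + half_w + 1))
  r0 <- max(1L, floor(yr[1] - half_w - 1)); r1 <- min(H, ceiling(yr[2] + half_w + 1))
  if (c0 > c1 || r0 > r1) return(integer(0))
  cs <- c0:c1; rs <- r0:r1
  px <- cbind(x = rep(cs, each = length(rs)), y = rep(rs, length(cs)))
  dmin <- rep(Inf, nrow(px))
  # thin the polyline for distance evaluation (segments ~2 px long)
  keep <- unique(c(seq(1, nrow(poly), by = 2), nrow(poly)))
  p <- poly[keep, , drop = FALSE]
  for (i in seq_len(nrow(p) - 1)) {
    a <- p[i, ]; b <- p[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-12) {
      d2 <- (px[, 1] - a[1])^2 + (px[, 2] - a[2])^2
    } else {
      t <- ((px[, 1] - a[1]) * ab[1] + (px[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px[, 1] - (a[1] + t * ab[1]))^2 +
            (px[, 2] - (a[2] + t * ab[2]))^2
    }
    dmin <- pmin(dmin, d2)
  }
  sel <- dmin <= half_w^2
  (px[sel, 1] - 1L) * H + px[sel, 2]  # linear indices, column-major
}

# --- scene generation ---

#' Generate a synthetic dense-swarm scene with ground truth
#'
#' Renders one phase-contrast-like frame: dark rods with hemispherical
#' caps on a gray background, a 1-px lighter seam where cells touch
#' (giving the intercellular-space class a real signal), faint filaments,
#' sub-micron debris, Gaussian point-spread blur and additive Gaussian
#' noise. Cells are placed wholly inside the field of view by rejection
#' sampling; modest overlap (<= 10% of a cell's pixels) is allowed so that
#' cells touch as they do in a crowded monolayer.
#'
#' A cell's physical length is its backbone arc length plus one width
#' (half a width per pole cap), so the rendered extent matches the
#' recorded `true_length`.
#'
#' @param config a [scene_config()].
#' @return a list of class `swarm_scene` with elements `phase`
#'   ([raster_image()]), `fluor` ([raster_image()] or `NULL`), and `truth`
#'   (list: `cells` data.frame with backbones, `debris` data.frame,
#'   `label_image` ([label_image()]), `interspace` and `filament` logical
#'   masks), plus the `config`.
#' @examples
#' sc <- generate_scene(scene_config(image_size = c(128, 128), n_cells = 4,
#'                                   n_debris = 2, seed = 3))
#' nrow(sc$truth$cells)
#' @export
generate_scene <- function(config) {
  validate_scene_config(config)
  with_seed(config$seed, generate_scene_impl(config))
}

#' @noRd
generate_scene_impl <- function(config) {
  H <- config$image_size[1]; W <- config$image_size[2]
  ps <- config$pixel_size
  lab <- matrix(0L, H, W)
  cells <- sample_cells_impl(config$n_cells, config)
  backbones <- vector("list", config$n_cells)
  npx_cell <- integer(config$n_cells)

  place_object <- function(poly_um, half_w_um, id, max_overlap = 0.10,
                           attempts = 600L) {
    # poly in um relative coords; translate randomly until it fits
    half_w_px <- half_w_um / ps
    poly_px <- poly_um / ps
    ext_x <- range(poly_px[, 1]); ext_y <- range(poly_px[, 2])
    margin <- half_w_px + 2
    lo_x <- 1 + margin - ext_x[1]; hi_x <- W - margin - ext_x[2]
    lo_y <- 1 + margin - ext_y[1]; hi_y <- H - margin - ext_y[2]
    if (lo_x > hi_x || lo_y > hi_y)
      abort("generate_scene: object of extent %.1f x %.1f px cannot fit",
            diff(ext_x), diff(ext_y))
    for (k in seq_len(attempts)) {
      ox <- stats::runif(1, lo_x, hi_x); oy <- stats::runif(1, lo_y, hi_y)
      shifted <- cbind(poly_px[, 1] + ox, poly_px[, 2] + oy)
      idx <- polyline_pixels(shifted, half_w_px, H, W)
      if (length(idx) == 0) next
      overlap <- sum(lab[idx] != 0L)
      if (overlap <= max_overlap * length(idx)) {
        free <- idx[lab[idx] == 0L]
        # contact with earlier cells is allowed, but the retained pixel
        # set must stay connected (cells touch, they do not cross)
        if (overlap > 0) {
          fr <- ((free - 1L) %% H) + 1L; fc <- ((free - 1L) %/% H) + 1L
          sm <- matrix(0, max(fr) - min(fr) + 1L, max(fc) - min(fc) + 1L)
          sm[cbind(fr - min(fr) + 1L, fc - min(fc) + 1L)] <- 1
          if (max(EBImage::bwlabel(sm)) > 1) next
        }
        lab[free] <<- id
        return(list(idx = free, poly = shifted))
      }
    }
    abort(paste0("generate_scene: could not place object %d after %d ",
                 "attempts; scene density is infeasible"), id, attempts)
  }

  # place the largest cells first: greatly improves packing feasibility
  # at swarm densities without changing any cell's identity
  for (i in order(cells$true_length, decreasing = TRUE)) {
    arc <- cells$true_length[i] - cells$true_width[i]
    arc <- max(arc, 0.2)
    bb <- make_backbone(arc, cells$true_sinuosity[i],
                        width_um = cells$true_width[i])
    cells$true_sinuosity[i] <- bb$sinuosity  # realized arc/chord
    res <- place_object(bb$poly, cells$true_width[i] / 2, i,
                        max_overlap = config$cell_overlap)
    npx_cell[i] <- length(res$idx)
    backbones[[i]] <- res$poly * ps  # um, image coords (x = col, y = row)
  }

  # debris: tiny roundish rods, ids continue after the cells
  n_deb <- config$n_debris
  debris <- data.frame(id = integer(0), true_length = numeric(0))
  if (n_deb > 0) {
    dl <- sample_dist(config$debris_length_dist, n_deb)
    for (j in seq_len(n_deb)) {
      id <- config$n_cells + j
      w <- 0.8 * dl[j]
      arc <- max(dl[j] - w, 0.05)
      th <- stats::runif(1, 0, pi)
      bb <- rbind(c(0, 0), c(arc * cos(th), arc * sin(th)))
      place_object(bb, w / 2, id, max_overlap = 0)
    }
    debris <- data.frame(id = config$n_cells + seq_len(n_deb),
                         true_length = dl)
  }

  # seam: cell pixels 8-adjacent to a *smaller* different label (1 px wide)
  seam <- matrix(FALSE, H, W)
  if (config$n_cells > 1) {
    for (k in seq_len(nrow(neigh8))) {
      nb <- shift_mat(lab, neigh8[k, 1], neigh8[k, 2], fill = 0L)
      seam <- seam | (lab > 0L & nb > 0L & nb < lab)
    }
  }

  # filaments: faint wavy lines over background only
  fil <- matrix(FALSE, H, W)
  area_um2 <- H * W * ps^2
  n_fil <- round(config$filament_density * area_um2 / 100)
  for (f in seq_len(n_fil)) {
    flen <- stats::runif(1, 4, 12)
    bb <- make_backbone(flen, stats::runif(1, 1.05, 1.3), width_um = 1)$poly
    ctr <- c(stats::runif(1, 1, W), stats::runif(1, 1, H))
    poly <- sweep(bb / ps, 2, ctr - colMeans(bb / ps), "+")
    idx <- polyline_pixels(poly, 0.8, H, W)
    idx <- idx[lab[idx] == 0L]
    fil[idx] <- TRUE
  }

  # phase rendering
  lv <- config$levels
  phase <- matrix(lv$background, H, W)
  cell_jitter <- stats::rnorm(config$n_cells + n_deb, 0, 0.02)
  on <- which(lab != 0L)
  phase[on] <- lv$cell + cell_jitter[lab[on]]
  phase[fil] <- lv$filament
  phase[seam] <- lv$seam
  if (config$psf_sigma > 0)
    phase <- gauss_smooth(phase, config$psf_sigma)
  if (config$noise_sd > 0)
    phase <- phase + stats::rnorm(length(phase), 0, config$noise_sd)
  phase <- pmin(pmax(phase, 0), 1)

  # fluorescence rendering: per-cell uniform level on a flat background
  fluor <- NULL
  if (!is.null(config$fluorescence_model)) {
    fl <- matrix(lv$fluor_background, H, W)
    intens <- c(cells$true_mean_intensity, rep(0, n_deb))
    fl[on] <- lv$fluor_background + intens[lab[on]]
    if (config$noise_sd > 0)
      fl <- fl + stats::rnorm(length(fl), 0, config$noise_sd)
    fluor <- raster_image(fl, ps)
  }

  cells$n_pixels <- npx_cell
  truth <- list(cells = cells, debris = debris,
                label_image = label_image(lab, ps),
                interspace = seam, filament = fil,
                backbones = backbones)
  structure(list(phase = raster_image(phase, ps), fluor = fluor,
                 truth = truth, config = config),
            class = "swarm_scene")
}

#' @export
print.swarm_scene <- function(x, ...) {
  cat(sprintf("<swarm_scene> %d x %d px, %d cells, %d debris%s\n",
              nrow(x$phase$pixels), ncol(x$phase$pixels),
              nrow(x$truth$cells), nrow(x$truth$debris),
              if (is.null(x$fluor)) "" else ", fluorescence channel"))
  invisible(x)
}

#' Scene presets emulating the swarm development cycle
#'
#' Returns a [scene_config()] for an "hour" of the swarm cycle. The long
#' (> 4 um) subpopulation fraction rises with time, becomes the majority
#' at hour 6 — the peak of collective migration — and falls again during
#' consolidation; the long-cell length scale follows the same rise and
#' fall. The numeric fractions are qualitative emulations of that trend,
#' not measured values.
#'
#' @param hour integer in 2..8.
#' @param n_cells cells per frame (default 650).
#' @param seed RNG seed for the returned config.
#' @param ... further arguments passed to [scene_config()].
#' @return a [scene_config()].
#' @examples
#' timecourse_presets(6)$long_fraction  # > 0.5: majority long at hour 6
#' @export
timecourse_presets <- function(hour, n_cells = 650, seed = 1L, ...) {
  if (!is_count(hour) || hour < 2 || hour > 8)
    abort("timecourse_presets: hour must be an integer in 2..8")
  lf <- c(`2` = 0.08, `3` = 0.18, `4` = 0.32, `5` = 0.45,
          `6` = 0.58, `7` = 0.38, `8` = 0.27)
  lscale <- c(`2` = 5.5, `3` = 6.0, `4` = 7.0, `5` = 8.0,
              `6` = 9.0, `7` = 7.0, `8` = 6.5)
  h <- as.character(hour)
  scene_config(n_cells = n_cells,
               long_fraction = unname(lf[h]),
               long_length_dist = dist_spec("lognormal",
                                            meanlog = log(lscale[[h]]),
                                            sdlog = 0.30,
                                            min = 4.05, max = 22),
               seed = seed, ...)
}

#' Derive sparse training annotations from a synthetic scene
#'
#' Emulates manual tracing for classifier training: samples pixel
#' positions of known class from the scene's ground truth — cell interiors
#' (CELL), seams and filaments (INTERSPACE), and free agar (BACKGROUND).
#'
#' @param scene a `swarm_scene` from [generate_scene()].
#' @param n_per_class pixels sampled per class.
#' @param seed RNG seed.
#' @return an [annotation_set()].
#' @export
annotate_scene <- function(scene, n_per_class = 3000, seed = 1L) {
  stopifnot(inherits(scene, "swarm_scene"))
  lab <- scene$truth$label_image$labels
  seam <- scene$truth$interspace
  fil <- scene$truth$filament
  cell_idx <- which(lab > 0L & !seam)
  seam_idx <- which(seam)
  fil_idx <- which(fil & !seam)
  bg_idx <- which(lab == 0L & !fil)
  if (length(seam_idx) + length(fil_idx) == 0)
    abort("annotate_scene: scene has no interspace/filament pixels")
  with_seed(seed, {
    pick <- function(idx, n) idx[sample.int(length(idx),
                                            min(n, length(idx)))]
    # balance the interspace class between the scarce seams (which drive
    # cell separation) and the abundant filament clutter
    inter <- c(pick(seam_idx, ceiling(n_per_class / 2)),
               pick(fil_idx, floor(n_per_class / 2)))
    idx <- c(pick(cell_idx, n_per_class), pick(bg_idx, n_per_class),
             inter)
    cls <- rep(c("CELL", "BACKGROUND", "INTERSPACE"),
               c(min(n_per_class, length(cell_idx)),
                 min(n_per_class, length(bg_idx)),
                 length(inter)))
    H <- nrow(lab)
    annotation_set(row = ((idx - 1L) %% H) + 1L,
                   col = ((idx - 1L) %/% H) + 1L,
                   class = cls, image_ref = "synthetic",
                   dim = dim(lab))
  })
}

#' Write a scene to disk
#'
#' Writes the phase (and fluorescence) channel as single-channel TIFF, the
#' label image as 16-bit TIFF, and the ground-truth table as CSV with
#' columns `id, kind, length_um, width_um, sinuosity, mean_intensity_au`.
#'
#' @param scene a `swarm_scene`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "swarm_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, c("phase.tif", "labels.tif", "truth.csv"))
  write_raster(scene$phase, files[1])
  write_label_tiff(scene$truth$label_image, files[2])
  tc <- scene$truth$cells
  td <- scene$truth$debris
  tab <- data.frame(
    id = c(tc$id, td$id),
    kind = rep(c("cell", "debris"), c(nrow(tc), nrow(td))),
    length_um = c(tc$true_length, td$true_length),
    width_um = c(tc$true_width, rep(NA, nrow(td))),
    sinuosity = c(tc$true_sinuosity, rep(NA, nrow(td))),
    mean_intensity_au = c(
      if (!is.null(tc$true_mean_intensity)) tc$true_mean_intensity
      else rep(NA, nrow(tc)), rep(NA, nrow(td))))
  utils::write.csv(tab, files[3], row.names = FALSE)
  if (!is.null(scene$fluor)) {
    f <- file.path(dir, "fluor.tif")
    write_raster(scene$fluor, f, scale = max(scene$fluor$pixels, 1))
    files <- c(files, f)
  }
  invisible(files)
}
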