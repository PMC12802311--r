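# particle extraction and medial-axis morphometry of curved rods

#' Label connected particles in a binary mask
#'
#' Connected-component labelling with deterministic label order: particles
#' are numbered by their first pixel in row-major order. 8-connectivity
#' (the default) keeps thin diagonal cell bodies connected.
#'
#' @param mask logical/0-1 matrix (e.g. from [binarize()]).
#' @param pixel_size um/px; taken from the mask's attribute when present.
#' @param connectivity 4 or 8.
#' @return a [label_image()].
#' @export
label_particles <- function(mask, pixel_size = attr(mask, "pixel_size"),
                            connectivity = 8) {
  if (is.null(pixel_size)) abort("label_particles: pixel_size required")
  if (!connectivity %in% c(4, 8))
    abort("label_particles: connectivity must be 4 or 8")
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))  # 4-connected
  storage.mode(lab) <- "integer"
  if (connectivity == 8 && max(lab) > 1) {
    # merge 4-components that touch diagonally
    pairs <- list()
    for (d in list(c(-1, -1), c(-1, 1))) {
      nb <- shift_mat(lab, d[1], d[2], fill = 0L)
      sel <- lab > 0L & nb > 0L & nb != lab
      if (any(sel)) pairs[[length(pairs) + 1]] <- cbind(lab[sel], nb[sel])
    }
    if (length(pairs) > 0) {
      e <- unique(do.call(rbind, pairs))
      g <- igraph::graph_from_edgelist(matrix(as.character(e), ncol = 2),
                                       directed = FALSE)
      comp <- igraph::components(g)
      map <- seq_len(max(lab))
      ids <- as.integer(igraph::V(g)$name)
      grp <- comp$membership
      for (k in unique(grp)) {
        members <- ids[grp == k]
        map[members] <- min(members)
      }
      lab[lab > 0L] <- map[lab[lab > 0L]]
    }
  }
  # renumber by row-major first pixel
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (length(ids) > 0) {
    H <- nrow(lab)
    idx <- which(lab > 0L)
    rowmaj <- (((idx - 1L) %% H)) * ncol(lab) + ((idx - 1L) %/% H)
    first <- tapply(rowmaj, lab[idx], min)
    ord <- as.integer(names(sort(first)))
    map2 <- integer(max(ids)); map2[ord] <- seq_along(ord)
    lab[idx] <- map2[lab[idx]]
  }
  label_image(lab, pixel_size)
}

# --- skeletonization (Zhang-Suen thinning, vectorized) ---

#' Morphological thinning of a binary mask to a 1-px skeleton
#'
#' Vectorized Guo-Hall thinning (two-subiteration parallel thinning with a
#' connectivity-number deletion test), used to measure length along curved
#' cell bodies. Chosen over Zhang-Suen, which over-erodes diagonally
#' oriented bands.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same size.
#' @export
skeletonize <- function(mask) {
  p <- mask > 0
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # clockwise from north: P2..P9
      P2 <- shift_mat(p, 1, 0, FALSE);  P3 <- shift_mat(p, 1, -1, FALSE)
      P4 <- shift_mat(p, 0, -1, FALSE); P5 <- shift_mat(p, -1, -1, FALSE)
      P6 <- shift_mat(p, -1, 0, FALSE); P7 <- shift_mat(p, -1, 1, FALSE)
      P8 <- shift_mat(p, 0, 1, FALSE);  P9 <- shift_mat(p, 1, 1, FALSE)
      C <- (!P2 & (P3 | P4)) + (!P4 & (P5 | P6)) +
           (!P6 & (P7 | P8)) + (!P8 & (P9 | P2))
      N1 <- (P9 | P2) + (P3 | P4) + (P5 | P6) + (P7 | P8)
      N2 <- (P2 | P3) + (P4 | P5) + (P6 | P7) + (P8 | P9)
      N <- pmin(N1, N2)
      m <- if (sub == 1) (P6 | P7 | !P9) & P8 else (P2 | P3 | !P5) & P4
      cond <- p & C == 1 & N >= 2 & N <= 3 & !m
      if (any(cond)) {
        p[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p
}

# weighted diameter path through a skeleton's pixel graph; returns the
# pixel indices (into the skeleton coordinate list) of the principal
# geodesic and its length in px units
#' @noRd
skeleton_path <- function(coords) {
  n <- nrow(coords)
  if (n == 1) return(list(path = 1L, length = 0))
  # edges between 8-adjacent skeleton pixels (4 unique directions)
  Mr <- max(coords[, 1]) + 2
  key <- coords[, 1] + (coords[, 2] - 1) * Mr
  from <- integer(0); to <- integer(0); w <- numeric(0)
  dirs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (k in seq_len(nrow(dirs))) {
    nk <- (coords[, 1] + dirs[k, 1]) + (coords[, 2] + dirs[k, 2] - 1) * Mr
    j <- match(nk, key)
    sel <- which(!is.na(j))
    if (length(sel) > 0) {
      from <- c(from, sel); to <- c(to, j[sel])
      w <- c(w, rep(if (sum(abs(dirs[k, ])) == 2) sqrt(2) else 1,
                    length(sel)))
    }
  }
  if (length(from) == 0) return(list(path = 1L, length = 0))
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w
  comp <- igraph::components(g)
  main <- which.max(tabulate(comp$membership))
  vs <- which(comp$membership == main)
  d1 <- igraph::distances(g, v = vs[1], to = vs)
  u <- vs[which.max(d1)]
  d2 <- igraph::distances(g, v = u, to = vs)
  v <- vs[which.max(d2)]
  sp <- igraph::shortest_paths(g, from = u, to = v, output = "vpath")
  list(path = as.integer(sp$vpath[[1]]), length = max(d2))
}

# arc length of a pixel path after box-filter smoothing (window in px).
# Raw 8-connected chain length overestimates oblique straight lines by up
# to 8%; averaging the coordinates over a small window removes the
# staircase while barely cutting corners at biological curvatures.
# Endpoints are kept anchored.
#' @noRd
smooth_arc_length <- function(P, window = 5) {
  n <- nrow(P)
  if (n < 2) return(0)
  if (n < 4) {
    d <- P[-1, , drop = FALSE] - P[-n, , drop = FALSE]
    return(sum(sqrt(rowSums(d^2))))
  }
  half <- floor(min(window, n) / 2)
  cs <- rbind(c(0, 0), apply(P, 2, cumsum))
  lo <- pmax(1, seq_len(n) - half); hi <- pmin(n, seq_len(n) + half)
  S <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  S[1, ] <- P[1, ]; S[n, ] <- P[n, ]
  d <- S[-1, , drop = FALSE] - S[-n, , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# corner-corrected chain length (px) of a pixel path: 0.980 axial +
# 1.406 diagonal - 0.091 per direction change. Local, so it does not
# flatten curvature, but it underestimates axis-aligned lines by ~2%;
# paired with smooth_arc_length via max() in measure_one.
#' @noRd
vs_chain_length <- function(P) {
  n <- nrow(P)
  if (n < 2) return(0)
  d <- P[-1, , drop = FALSE] - P[-n, , drop = FALSE]
  st <- abs(d[, 1]) + abs(d[, 2])
  a <- sum(st == 1); b <- sum(st >= 2)
  corners <- if (n > 2)
    sum(d[-1, 1] != d[-(n - 1), 1] | d[-1, 2] != d[-(n - 1), 2]) else 0
  0.980 * a + 1.406 * b - 0.091 * corners
}

# continue a path end through the pole cap by arc length t_len, following
# the local end curvature (circular extrapolation); reconstructs the
# backbone tip so arc/chord ratios refer to the whole backbone, not the
# cap-retracted medial axis
#' @noRd
extrapolate_tip <- function(path, t_len, from_start = TRUE,
                            kappa_max = 0.1) {
  np <- nrow(path)
  a_raw <- if (from_start) path[1, ] else path[np, ]
  # unanchored running mean suppresses staircase/hook jitter before the
  # local tangent and curvature are read off
  if (np >= 5) {
    half <- 2
    cs <- rbind(c(0, 0), apply(path, 2, cumsum))
    lo <- pmax(1, seq_len(np) - half); hi <- pmin(np, seq_len(np) + half)
    path <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1)
  }
  k2 <- min(12L, np)
  pick <- function(i) if (from_start) path[i, ] else path[np - i + 1, ]
  a <- pick(1); b <- pick(ceiling((k2 + 1) / 2)); cc <- pick(k2)
  v1 <- a - b; v2 <- b - cc
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9) return(a)
  u <- v1 / n1
  # the cap ray starts at the raw endpoint; add its lead over the
  # smoothed endpoint so the reconstructed tip is not pulled inboard
  t_len <- t_len + max(0, sum((a_raw - a) * u))
  if (n2 < 1e-9 || k2 < 8) return(a + t_len * u)
  cosang <- sum(v1 * v2) / (n1 * n2)
  ang <- acos(min(max(cosang, -1), 1))
  sgn <- sign(v2[1] * v1[2] - v2[2] * v1[1])
  d_ac <- sqrt(sum((a - cc)^2))
  kappa <- if (d_ac > 0) 2 * ang / d_ac else 0
  kappa <- min(kappa, kappa_max)
  if (kappa < 1e-4 || sgn == 0) return(a + t_len * u)
  nv <- sgn * c(-u[2], u[1])
  a + (sin(kappa * t_len) / kappa) * u +
    ((1 - cos(kappa * t_len)) / kappa) * nv
}

# distance (px) from point p to the mask edge along direction u
#' @noRd
ray_to_edge <- function(sub, p, u, step = 0.25, max_px = 60) {
  nrm <- sqrt(sum(u^2))
  if (nrm < 1e-9) return(0)
  u <- u / nrm
  t <- 0
  while (t < max_px) {
    t2 <- t + step
    q <- round(p + t2 * u)
    if (q[1] < 1 || q[2] < 1 || q[1] > nrow(sub) || q[2] > ncol(sub) ||
        !sub[q[1], q[2]]) return(t)
    t <- t2
  }
  t
}

# perimeter (px) from the Moore contour: arc length of the circularly
# smoothed boundary-pixel-centre polygon, plus pi for the half-pixel inset
# of pixel centres relative to the true outline (2*pi*0.5 around a closed
# convex boundary). Unbiased on rasterized disks; the smoothing removes
# the staircase overestimate of the raw chain.
#' @noRd
contour_perimeter <- function(submask) {
  oc <- EBImage::ocontour(EBImage::Image(submask * 1))
  if (length(oc) == 0) return(NA_real_)
  pts <- oc[[1]]
  n <- nrow(pts)
  if (n < 3) {
    # tiny particle: perimeter of the equal-area disk
    return(2 * sqrt(pi * sum(submask)))
  }
  if (n >= 8) {
    S <- pts
    for (d in c(-2, -1, 1, 2))
      S <- S + pts[((seq_len(n) + d - 1) %% n) + 1, , drop = FALSE]
    S <- S / 5
    dd <- S - S[c(2:n, 1), , drop = FALSE]
    return(sum(sqrt(rowSums(dd^2))) + pi)
  }
  d <- abs(pts - pts[c(2:n, 1), , drop = FALSE])
  steps <- rowSums(d)
  0.948 * sum(steps == 1) + 1.340 * sum(steps >= 2) + pi
}

#' Morphometrics for every particle in a label image
#'
#' For each particle: area (pixel count x pixel_size^2), perimeter
#' (corner-corrected chain length of the outer contour), width (twice the
#' mean distance-transform value along the central portion of the pruned
#' skeleton), length (pruned-skeleton geodesic length plus one width — the
#' cap correction for hemispherical poles), sinuosity (skeleton geodesic /
#' Euclidean distance between its endpoints; 1 for particles below
#' resolution), circularity (`min(1, 4*pi*area/perimeter^2)`), centroid,
#' and an edge flag. Each particle is processed on its own padded crop, so
#' touching particles with distinct labels do not interfere.
#'
#' @param labels a [label_image()].
#' @return data.frame of class `cell_records`, one row per label, ordered
#'   by id: columns `id, length, width, area, perimeter, sinuosity,
#'   circularity, centroid_row, centroid_col, touches_edge,
#'   mean_intensity, type` (lengths in um, areas in um^2).
#' @export
measure_all <- function(labels) {
  stopifnot(inherits(labels, "label_image"))
  lab <- labels$labels; ps <- labels$pixel_size
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  recs <- lapply(ids, function(id) measure_one(lab, id, ps))
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(id = integer(0), length = numeric(0),
                      width = numeric(0), area = numeric(0),
                      perimeter = numeric(0), sinuosity = numeric(0),
                      circularity = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), touches_edge = logical(0),
                      mean_intensity = numeric(0), type = character(0))
  }
  class(out) <- c("cell_records", "data.frame")
  out
}

#' Morphometrics for one particle
#'
#' @param labels a [label_image()].
#' @param id particle id present in `labels`.
#' @return one-row data.frame, see [measure_all()].
#' @export
measure_particle <- function(labels, id) {
  stopifnot(inherits(labels, "label_image"))
  if (!any(labels$labels == id))
    abort("measure_particle: id %d not present", id)
  out <- measure_one(labels$labels, id, labels$pixel_size)
  class(out) <- c("cell_records", "data.frame")
  out
}

#' @noRd
measure_one <- function(lab, id, ps) {
  idx <- which(lab == id)
  H <- nrow(lab); W <- ncol(lab)
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  touches <- any(rows == 1L | rows == H | cols == 1L | cols == W)
  r0 <- min(rows); c0 <- min(cols)
  sub <- matrix(FALSE, max(rows) - r0 + 3L, max(cols) - c0 + 3L)
  sub[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- TRUE
  npx <- length(idx)
  area <- npx * ps^2
  per_px <- contour_perimeter(sub)
  perimeter <- per_px * ps
  dm <- EBImage::imageData(EBImage::distmap(sub * 1))
  skel <- skeletonize(sub)
  sk_idx <- which(skel)
  geodesic_px <- 0; sinuosity <- 1; caps_px <- 2 * max(dm)
  if (length(sk_idx) >= 2) {
    coords <- cbind(((sk_idx - 1L) %% nrow(sub)) + 1L,
                    ((sk_idx - 1L) %/% nrow(sub)) + 1L)
    spr <- skeleton_path(coords)
    path_px <- coords[spr$path, , drop = FALSE]
    # clip hook artifacts at the path ends: the medial axis is unstable
    # inside the pole caps (always drop 2 px per end, plus any pixels
    # whose medial radius falls well below the typical half-width); the
    # ray-based cap correction below rebuilds the poles from the clipped
    # endpoints
    pdm <- dm[path_px]
    thr <- 0.7 * stats::median(pdm)
    lo <- 1; hi <- nrow(path_px)
    if (hi - lo >= 9) { lo <- lo + 3; hi <- hi - 3 }
    else if (hi - lo >= 7) { lo <- lo + 2; hi <- hi - 2 }
    while (hi - lo >= 3 && pdm[lo] < thr) lo <- lo + 1
    while (hi - lo >= 3 && pdm[hi] < thr) hi <- hi - 1
    path_px <- path_px[lo:hi, , drop = FALSE]
    geodesic_px <- max(smooth_arc_length(path_px),
                       vs_chain_length(path_px))
    np <- nrow(path_px)
    if (np >= 2 && geodesic_px > 0) {
      chord <- sqrt(sum((path_px[np, ] - path_px[1, ])^2))
      if (chord > 0) sinuosity <- max(1, geodesic_px / chord)
    }
    dvals <- dm[cbind(path_px[, 1], path_px[, 2])]
    if (np >= 3) {
      # pole caps: ray from each skeleton endpoint along the outward
      # tangent to the mask edge
      k0 <- min(np, 6)
      u1 <- path_px[1, ] - colMeans(path_px[2:k0, , drop = FALSE])
      u2 <- path_px[np, ] -
        colMeans(path_px[(np - k0 + 1):(np - 1), , drop = FALSE])
      t1 <- ray_to_edge(sub, path_px[1, ], u1)
      t2 <- ray_to_edge(sub, path_px[np, ], u2)
      caps_px <- t1 + t2
      if (caps_px <= 0) caps_px <- 2 * mean(dvals)
      # sinuosity over the reconstructed backbone: the medial axis stops
      # one cap radius short of each pole, and a sub-arc of a bent
      # backbone is less sinuous than the whole, so both poles are
      # rebuilt by curvature-following extrapolation
      # physical curvature bound: bend radius of a rod is at least about
      # one cell width (half-width = median of the distance transform)
      kmax <- 1 / (2.4 * max(stats::median(dvals), 1))
      tip1 <- extrapolate_tip(path_px, t1, from_start = TRUE,
                              kappa_max = kmax)
      tip2 <- extrapolate_tip(path_px, t2, from_start = FALSE,
                              kappa_max = kmax)
      tipdist <- sqrt(sum((tip1 - tip2)^2))
      if (tipdist > 0) {
        sin_tip <- (geodesic_px + caps_px) / tipdist
        # the retracted-chord ratio underestimates a bent backbone, the
        # reconstructed-tip ratio slightly overestimates it; an even
        # blend cancels most of both biases. Short skeletons carry too
        # much chord noise, so their weight shifts toward the tip ratio.
        a <- 0.5 * min(1, np / (4 * stats::median(dvals)))
        sinuosity <- max(1, a * sinuosity + (1 - a) * sin_tip)
      }
    } else caps_px <- 2 * mean(dvals)
  } else {
    path_px <- NULL
    dvals <- max(dm)
  }
  # width from the central portion of the path (pole caps excluded)
  k <- round(stats::median(dvals))
  if (!is.null(path_px) && nrow(path_px) > 2 * k + 1) {
    core <- dvals[(k + 1):(length(dvals) - k)]
  } else core <- dvals
  # distance-transform values run from pixel centre to the first
  # background pixel centre; half a pixel of that is outside the particle
  width <- max(2 * mean(core) - 0.5, 1) * ps
  width <- min(width, sqrt(area))  # guard: never wider than a square of same area
  len <- (geodesic_px + caps_px) * ps
  # area-based floor: a stadium of area A and width w has length
  # A/w + w(1 - pi/4); with a deliberately generous width (2 max of the
  # distance transform) this underestimates for true rods, so it only
  # takes over where thinning under-recovers (short, strongly bent cells)
  w_up <- 2 * max(dm) * ps
  len <- max(len, area / w_up + w_up * (1 - pi / 4), width)
  circ <- min(1, 4 * pi * area / perimeter^2)
  data.frame(id = as.integer(id), length = len, width = width, area = area,
             perimeter = perimeter, sinuosity = sinuosity,
             circularity = circ,
             centroid_row = mean(rows) * ps, centroid_col = mean(cols) * ps,
             touches_edge = touches, mean_intensity = NA_real_,
             type = NA_character_)
}

#' Debris-filter configuration
#'
#' The automated replacement for by-hand curation: particles survive only
#' if area >= `min_area` (um^2), circularity within `circularity_range`
#' (both bounds inclusive), length strictly greater than `min_length`
#' (um; objects of 1 um or less are debris), and — when `exclude_edges` —
#' not touching the raster border.
#'
#' @param min_area um^2, default 1.
#' @param circularity_range inclusive `[lo, hi]`, default `c(0, 0.9)`.
#' @param min_length exclusive lower bound, um, default 1.
#' @param exclude_edges drop border-touching particles, default TRUE.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_area = 1, circularity_range = c(0, 0.9),
                          min_length = 1, exclude_edges = TRUE) {
  if (min_area < 0 || min_length < 0)
    abort("filter_config: bounds must be non-negative")
  if (length(circularity_range) != 2 ||
      circularity_range[1] > circularity_range[2])
    abort("filter_config: circularity_range must be ordered c(lo, hi)")
  structure(list(min_area = min_area,
                 circularity_range = circularity_range,
                 min_length = min_length, exclude_edges = exclude_edges),
            class = "filter_config")
}

#' Apply the debris-filter cascade
#'
#' @param records a `cell_records` table from [measure_all()].
#' @param config a [filter_config()].
#' @return the surviving records, order preserved; the ids of rejected
#'   records are attached as attribute `"rejected_ids"`.
#' @export
apply_filters <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(records) == 0) return(records)
  keep <- records$area >= config$min_area &
    records$circularity >= config$circularity_range[1] &
    records$circularity <= config$circularity_range[2] &
    records$length > config$min_length
  if (config$exclude_edges) keep <- keep & !records$touches_edge
  out <- records[keep, , drop = FALSE]
  attr(out, "rejected_ids") <- records$id[!keep]
  out
}

#' Assign length-based subpopulation types
#'
#' Cells at most `split` um long are SHORT (a cell doubling or less);
#' cells longer than `split` um are LONG (elongated beyond doubling).
#'
#' @param records a `cell_records` table.
#' @param split boundary in um, default 4.
#' @return `records` with the `type` column set to `"SHORT"`/`"LONG"`.
#' @export
classify_length <- function(records, split = 4) {
  if (nrow(records) > 0 && any(records$length <= 0))
    abort("classify_length: lengths must be positive")
  records$type <- ifelse(records$length > split, "LONG", "SHORT")
  records
}
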