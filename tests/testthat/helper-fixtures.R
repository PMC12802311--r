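# fixtures built in code: rasterized rods, disks, and small scenes

# stadium-shaped rod of nominal length L um and width w um at angle `ang`
# degrees, rasterized at `ps` um/px
make_rod_label <- function(L, ang = 0, w = 0.8, ps = 0.1, n = NULL) {
  if (is.null(n)) n <- ceiling(L / ps) + 40
  th <- ang * pi / 180
  arc <- (L - w) / ps
  hw <- w / 2 / ps
  lab <- matrix(0L, n, n)
  a <- c(n / 2 - arc / 2 * cos(th), n / 2 - arc / 2 * sin(th))
  b <- c(n / 2 + arc / 2 * cos(th), n / 2 + arc / 2 * sin(th))
  px <- expand.grid(r = seq_len(n), c = seq_len(n))
  ab <- b - a
  t <- pmin(pmax(((px$c - a[1]) * ab[1] + (px$r - a[2]) * ab[2]) /
                   sum(ab^2), 0), 1)
  d2 <- (px$c - (a[1] + t * ab[1]))^2 + (px$r - (a[2] + t * ab[2]))^2
  lab[d2 < hw^2] <- 1L
  label_image(lab, ps)
}

make_disk_label <- function(r_px = 20, ps = 0.1) {
  n <- 2 * r_px + 20
  lab <- matrix(0L, n, n)
  px <- expand.grid(r = seq_len(n), c = seq_len(n))
  lab[(px$r - n / 2)^2 + (px$c - n / 2)^2 <= r_px^2] <- 1L
  label_image(lab, ps)
}

# small clean scene for fast end-to-end tests
small_scene <- function(n_cells = 12, seed = 5, noise_sd = 0.02, ...) {
  generate_scene(scene_config(image_size = c(256, 256), n_cells = n_cells,
                              n_debris = 3, filament_density = 0.2,
                              noise_sd = noise_sd, seed = seed, ...))
}

# brute-force rank-sum permutation oracle: two-sided p by symmetric
# deviation counting over all assignments of the pooled values
perm_ranksum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  mu <- n1 * (length(pooled) + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  combos <- utils::combn(length(pooled), n1)
  devs <- abs(colSums(matrix(r[combos], nrow = n1)) - mu)
  mean(devs >= obs - 1e-9)
}
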