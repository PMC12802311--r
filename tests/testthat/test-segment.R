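test_that("feature bank behaves analytically on constant and ramp images", {
  const <- raster_image(matrix(100, 32, 32), 0.1)
  fs <- compute_features(const, sigma_ladder = c(0, 1, 2))
  for (nm in fs$names) {
    v <- fs$values[, nm]
    if (startsWith(nm, "gauss")) expect_true(all(abs(v - 100) < 1e-6),
                                             info = nm)
    else expect_true(all(abs(v) < 1e-6), info = nm)
  }
  # ramp along columns, slope 2 per px: interior gradient magnitude = 2
  ramp <- raster_image(matrix(rep(2 * (1:40), each = 40), 40, 40), 0.1)
  fr <- compute_features(ramp, sigma_ladder = c(0, 1))
  g <- matrix(fr$values[, "grad_s1"], 40, 40)
  expect_true(all(abs(g[10:30, 10:30] - 2) < 1e-6))
  # sigma 0 rung reproduces the input exactly
  noise <- raster_image(matrix(runif(100), 10, 10), 0.1)
  f0 <- compute_features(noise, sigma_ladder = c(0, 1))
  expect_equal(matrix(f0$values[, "gauss_s0"], 10, 10), noise$pixels)
})

# three-level intensity fixture: cells dark, background mid, seams bright,
# well separated relative to the noise
make_threeclass_fixture <- function(seed = 1, noise = 0.02) {
  set.seed(seed)
  img <- matrix(0.5, 96, 96)
  img[20:40, 20:60] <- 0.2           # cell block
  img[60:80, 30:50] <- 0.2
  img[45:47, 10:90] <- 0.8           # seam stripe
  img <- img + rnorm(length(img), 0, noise)
  lab <- matrix(0L, 96, 96)
  lab[22:38, 22:58] <- 1L
  lab[62:78, 32:48] <- 1L
  lab[46, 12:88] <- 3L
  lab[5:15, 5:90] <- 2L
  idx <- which(lab > 0)
  ann <- annotation_set(row = ((idx - 1L) %% 96) + 1L,
                        col = ((idx - 1L) %/% 96) + 1L,
                        class = c("CELL", "BACKGROUND",
                                  "INTERSPACE")[lab[idx]],
                        dim = c(96, 96))
  list(image = raster_image(img, 0.1), ann = ann, lab = lab, idx = idx)
}

test_that("training on well-separated classes beats the centroid oracle bar", {
  fx <- make_threeclass_fixture()
  # nearest-class-centroid oracle on raw intensity
  cls <- c("CELL", "BACKGROUND", "INTERSPACE")[fx$lab[fx$idx]]
  cent <- tapply(fx$image$pixels[fx$idx], cls, mean)
  oracle_pred <- names(cent)[apply(
    abs(outer(fx$image$pixels[fx$idx], cent, `-`)), 1, which.min)]
  expect_gt(mean(oracle_pred == cls), 0.95)  # the bar itself is attainable
  cl <- train_classifier(fx$image, fx$ann, n_trees = 30, seed = 1)
  expect_gt(cl$meta$training_accuracy, 0.95)
})

test_that("training errors name a missing class", {
  fx <- make_threeclass_fixture()
  keep <- fx$ann$class != "INTERSPACE"
  ann2 <- annotation_set(fx$ann$row[keep], fx$ann$col[keep],
                         as.character(fx$ann$class[keep]), dim = c(96, 96))
  expect_error(train_classifier(fx$image, ann2, n_trees = 10, seed = 1),
               "INTERSPACE")
})

test_that("training is reproducible and classifiers round-trip to disk", {
  fx <- make_threeclass_fixture()
  probe <- make_threeclass_fixture(seed = 2)$image
  cl1 <- train_classifier(fx$image, fx$ann, n_trees = 20, seed = 3)
  cl2 <- train_classifier(fx$image, fx$ann, n_trees = 20, seed = 3)
  p1 <- predict_probabilities(cl1, probe)
  p2 <- predict_probabilities(cl2, probe)
  expect_identical(p1$p, p2$p)
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(cl1, path)
  p3 <- predict_probabilities(load_classifier(path), probe)
  expect_identical(p1$p, p3$p)
})

test_that("probability maps are normalized and consistent on training data", {
  fx <- make_threeclass_fixture()
  cl <- train_classifier(fx$image, fx$ann, n_trees = 30, seed = 1)
  pm <- predict_probabilities(cl, fx$image)
  sums <- apply(pm$p, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # a pure-class image: mean CELL probability dominates
  pure <- raster_image(matrix(0.2 + rnorm(96 * 96, 0, 0.02), 96, 96), 0.1)
  pp <- predict_probabilities(cl, pure)
  means <- apply(pp$p, 3, mean)
  expect_equal(names(which.max(means)), "CELL")
  expect_error(predict_probabilities(cl, raster_image(matrix(numeric(0),
                                                             0, 0), 0.1)))
})

test_that("binarization thresholds the CELL probability and fills holes", {
  mk_pm <- function(pc) {
    p <- array(0, dim = c(dim(pc), 3),
               dimnames = list(NULL, NULL,
                               c("CELL", "BACKGROUND", "INTERSPACE")))
    p[, , "CELL"] <- pc
    p[, , "BACKGROUND"] <- 1 - pc
    structure(list(p = p, pixel_size = 0.1), class = "prob_map")
  }
  expect_true(all(binarize(mk_pm(matrix(1, 8, 8)), 0.5)))
  expect_false(any(binarize(mk_pm(matrix(0.4, 8, 8)), 0.5)))
  # blob with a 3-px interior hole
  pc <- matrix(0, 20, 20)
  pc[5:15, 5:15] <- 1
  pc[9, 9:11] <- 0
  expect_equal(sum(binarize(mk_pm(pc), 0.5, min_hole_px = 10)), 11 * 11)
  expect_equal(sum(binarize(mk_pm(pc), 0.5, min_hole_px = 1)), 11 * 11 - 3)
  expect_error(binarize(mk_pm(matrix(0.5, 4, 4)), 1.5), "threshold")
})

test_that("raising the threshold never adds on-pixels", {
  fx <- make_threeclass_fixture()
  cl <- train_classifier(fx$image, fx$ann, n_trees = 20, seed = 1)
  pm <- predict_probabilities(cl, fx$image)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8),
                   function(t) sum(binarize(pm, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("sparse low-noise scenes segment to one component per cell", {
  sc <- generate_scene(scene_config(image_size = c(320, 320), n_cells = 10,
                                    n_debris = 0, filament_density = 0.2,
                                    cell_overlap = 0, noise_sd = 0.02,
                                    seed = 21))
  ann <- annotate_scene(sc, n_per_class = 2000, seed = 2)
  cl <- train_classifier(sc$phase, ann, n_trees = 40, seed = 1)
  mask <- binarize(predict_probabilities(cl, sc$phase), 0.5,
                   min_hole_px = 40)
  labs <- label_particles(mask, sc$phase$pixel_size)
  m <- match_cells(sc$truth$label_image, labs,
                   truth_ids = sc$truth$cells$id)
  expect_true(all(m$matched))
  expect_equal(anyDuplicated(m$pred_id), 0)
})
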