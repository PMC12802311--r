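test_that("scene configuration enforces the category boundaries", {
  expect_error(scene_config(short_length_dist =
                              dist_spec("uniform", min = 0.5, max = 3)),
               "short lengths")
  expect_error(scene_config(long_length_dist =
                              dist_spec("uniform", min = 3, max = 8)),
               "long lengths")
  expect_error(scene_config(debris_length_dist =
                              dist_spec("uniform", min = 0.5, max = 2)),
               "debris")
  expect_error(scene_config(sinuosity_dist =
                              dist_spec("uniform", min = 0.8, max = 1.2)),
               "sinuosity")
  expect_error(scene_config(long_fraction = 1.4), "long_fraction")
  expect_error(scene_config(pixel_size = 0), "pixel_size")
})

test_that("sampled distributions respect their supports", {
  specs <- list(dist_spec("uniform", min = 0.25, max = 1),
                dist_spec("normal", mean = 2.6, sd = 0.7,
                          min = 1.05, max = 4),
                dist_spec("lognormal", meanlog = log(6.5), sdlog = 0.35,
                          min = 4.05, max = 20),
                dist_spec("fixed", value = 3))
  set.seed(1)
  for (sp in specs) {
    x <- sample_dist(sp, 2000)
    s <- swarmetrics::sample_dist(sp, 0)
    expect_length(s, 0)
    lo_hi <- if (sp$kind == "fixed") c(3, 3) else c(sp$min, sp$max)
    expect_true(all(x >= lo_hi[1] & x <= lo_hi[2]))
  }
})

test_that("an empty scene is a uniform background with no truth entries", {
  sc <- generate_scene(scene_config(image_size = c(64, 64), n_cells = 0,
                                    n_debris = 0, filament_density = 0,
                                    noise_sd = 0, psf_sigma = 0, seed = 1))
  expect_equal(nrow(sc$truth$cells), 0)
  expect_equal(nrow(sc$truth$debris), 0)
  expect_true(all(sc$phase$pixels == sc$phase$pixels[1, 1]))
  expect_equal(max(sc$truth$label_image$labels), 0)
})

test_that("a degenerate sinuosity draw gives a straight backbone", {
  sc <- generate_scene(scene_config(
    image_size = c(128, 128), n_cells = 1, n_debris = 0,
    filament_density = 0,
    sinuosity_dist = dist_spec("fixed", value = 1), seed = 2))
  expect_equal(sc$truth$cells$true_sinuosity, 1, tolerance = 1e-6)
  bb <- sc$truth$backbones[[1]]
  arc <- sum(sqrt(rowSums(diff(bb)^2)))
  chord <- sqrt(sum((bb[nrow(bb), ] - bb[1, ])^2))
  expect_equal(arc / chord, 1, tolerance = 1e-6)
})

test_that("identical seeds reproduce bit-identical scenes", {
  cfg <- scene_config(image_size = c(256, 256), n_cells = 50, n_debris = 10,
                      seed = 7,
                      fluorescence_model = list(slope = 0.0276,
                                                intercept = 0.84336,
                                                r_squared_target = 0.3177))
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$phase$pixels, b$phase$pixels)
  expect_identical(a$fluor$pixels, b$fluor$pixels)
  expect_identical(a$truth$label_image$labels, b$truth$label_image$labels)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("the label image carries exactly the configured objects", {
  sc <- generate_scene(scene_config(image_size = c(640, 640), n_cells = 200,
                                    n_debris = 15, seed = 3))
  ids <- setdiff(unique(as.vector(sc$truth$label_image$labels)), 0L)
  expect_setequal(ids, 1:215)
  expect_equal(nrow(sc$truth$cells), 200)
  expect_equal(nrow(sc$truth$debris), 15)
  # category soundness
  expect_true(all(sc$truth$cells$true_length > 1))
  expect_true(all(sc$truth$debris$true_length <= 1))
  expect_true(all(sc$truth$cells$true_sinuosity >= 1))
})

test_that("rasterized cell areas agree with the analytic stadium area", {
  sc <- generate_scene(scene_config(image_size = c(640, 640), n_cells = 80,
                                    n_debris = 0, filament_density = 0,
                                    cell_overlap = 0, seed = 9))
  tc <- sc$truth$cells
  analytic <- (tc$true_length - tc$true_width) * tc$true_width +
    pi * tc$true_width^2 / 4
  ratio <- tc$n_pixels * sc$config$pixel_size^2 / analytic
  expect_true(all(abs(ratio - 1) <= 0.15))
})

test_that("population R-squared of intensity on length converges to target", {
  cfg <- scene_config(fluorescence_model = list(slope = 0.0276,
                                                intercept = 0.84336,
                                                r_squared_target = 0.3177))
  pop <- sample_cell_population(6000, cfg, seed = 4)
  fit <- stats::lm(true_mean_intensity ~ true_length, data = pop)
  expect_equal(summary(fit)$r.squared, 0.3177, tolerance = 0.05 / 0.3177)
})

test_that("timecourse presets emulate the swarm development cycle", {
  lf <- vapply(2:8, function(h) timecourse_presets(h)$long_fraction,
               numeric(1))
  expect_lt(lf[1], lf[5])           # hour 2 below hour 6
  expect_gt(lf[5], 0.5)             # long cells the majority at hour 6
  expect_equal(which.max(lf), 5)    # maximum at hour 6
  expect_true(all(diff(lf[1:5]) > 0) && all(diff(lf[5:7]) < 0))
  for (h in 2:8)
    expect_silent(validate_scene_config(timecourse_presets(h)))
  expect_error(timecourse_presets(9), "hour")
  expect_error(timecourse_presets(1), "hour")
})

test_that("infeasible densities raise an explicit error", {
  expect_error(generate_scene(scene_config(image_size = c(64, 64),
                                           n_cells = 400, seed = 1)),
               "density|fit")
})

test_that("scenes round-trip through the TIFF/CSV writers", {
  sc <- small_scene(n_cells = 6, seed = 13)
  dir <- withr::local_tempdir()
  files <- write_scene(sc, dir)
  expect_true(all(file.exists(files)))
  ph <- read_raster(file.path(dir, "phase.tif"), 0.1)
  expect_equal(dim(ph$pixels), dim(sc$phase$pixels))
  expect_lt(max(abs(ph$pixels - sc$phase$pixels)), 1 / 65535 + 1e-6)
  lab <- read_label_tiff(file.path(dir, "labels.tif"), 0.1)
  expect_identical(lab$labels, sc$truth$label_image$labels)
  tab <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(tab), nrow(sc$truth$cells) + nrow(sc$truth$debris))
  expect_setequal(unique(tab$kind), c("cell", "debris"))
})
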