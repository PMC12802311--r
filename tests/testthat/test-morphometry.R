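test_that("particle labelling is deterministic and connectivity-aware", {
  expect_equal(max(label_particles(matrix(FALSE, 10, 10), 0.1)$labels), 0)
  two <- matrix(FALSE, 12, 12)
  two[2:4, 2:4] <- TRUE; two[8:10, 8:10] <- TRUE
  expect_equal(max(label_particles(two, 0.1)$labels), 2)
  # diagonal-touching blobs: 2 components under 4-connectivity, 1 under 8
  diag2 <- matrix(FALSE, 10, 10)
  diag2[2:4, 2:4] <- TRUE; diag2[5:7, 5:7] <- TRUE
  expect_equal(max(label_particles(diag2, 0.1, connectivity = 4)$labels), 2)
  expect_equal(max(label_particles(diag2, 0.1, connectivity = 8)$labels), 1)
  # label order follows the row-major first pixel
  lab <- label_particles(two, 0.1)
  expect_equal(lab$labels[2, 2], 1L)
  expect_equal(lab$labels[8, 8], 2L)
})

test_that("a horizontal rod measures to its nominal geometry", {
  r <- measure_particle(make_rod_label(4, ang = 0), 1L)
  expect_equal(r$length, 4, tolerance = 0.2 / 4)
  expect_equal(r$width, 0.8, tolerance = 0.1 / 0.8)
  expect_equal(r$sinuosity, 1, tolerance = 0.02)
  expect_false(r$touches_edge)
  # perimeter of the 4 x 0.8 um stadium: 2(L-w) + pi w = 8.91 um
  expect_equal(r$perimeter, 2 * 3.2 + pi * 0.8, tolerance = 0.08)
})

test_that("straight rods are accurate across lengths and orientations", {
  for (L in c(2, 5, 11, 20)) {
    for (ang in c(0, 22.5, 45, 70)) {
      r <- measure_particle(make_rod_label(L, ang), 1L)
      expect_lt(abs(r$length - L), max(0.2, 0.03 * L))
      expect_lt(abs(r$sinuosity - 1), 0.02)
      expect_lt(abs(r$width - 0.8), 0.1)
      expect_gte(r$sinuosity, 1)
    }
  }
})

test_that("a rasterized disk has circularity in [0.9, 1]", {
  r <- measure_particle(make_disk_label(20), 1L)
  expect_gte(r$circularity, 0.9)
  expect_lte(r$circularity, 1)
  expect_equal(r$length, r$width, tolerance = 0.2)
})

test_that("S-shaped cells recover the backbone arc/chord ratio", {
  sc <- generate_scene(scene_config(
    image_size = c(720, 720), n_cells = 15, n_debris = 0,
    filament_density = 0, cell_overlap = 0, noise_sd = 0, seed = 31,
    long_fraction = 1,
    long_length_dist = dist_spec("uniform", min = 5, max = 11),
    sinuosity_dist = dist_spec("uniform", min = 1.15, max = 1.4)))
  recs <- measure_all(sc$truth$label_image)
  m <- merge(recs, sc$truth$cells, by = "id")
  expect_true(all(abs(m$sinuosity / m$true_sinuosity - 1) <= 0.05))
})

test_that("border-touching particles are flagged", {
  lab <- matrix(0L, 10, 10)
  lab[1, 3:6] <- 1L; lab[5:6, 5:6] <- 2L
  li <- label_image(lab, 0.1)
  recs <- measure_all(li)
  expect_true(recs$touches_edge[recs$id == 1])
  expect_false(recs$touches_edge[recs$id == 2])
  expect_error(measure_particle(li, 9L), "not present")
})

test_that("measure_all is complete, ordered, and deterministic", {
  lab <- matrix(0L, 30, 30)
  lab[3:6, 3:12] <- 1L; lab[10:13, 15:25] <- 2L; lab[20:23, 4:10] <- 3L
  li <- label_image(lab, 0.1)
  a <- measure_all(li)
  expect_equal(a$id, 1:3)
  expect_identical(a, measure_all(li))
  expect_true(all(a$length >= a$width & a$width > 0))
  expect_true(all(a$area > 0 & a$perimeter > 0))
  expect_true(all(a$sinuosity >= 1))
  expect_true(all(a$circularity > 0 & a$circularity <= 1))
})

test_that("scene-scale measurements match ground truth", {
  sc <- generate_scene(scene_config(image_size = c(1024, 1024),
                                    n_cells = 200, n_debris = 0,
                                    filament_density = 0, cell_overlap = 0,
                                    noise_sd = 0, seed = 17))
  recs <- measure_all(sc$truth$label_image)
  expect_equal(nrow(recs), 200)
  m <- merge(recs, sc$truth$cells, by = "id")
  err <- abs(m$length - m$true_length)
  expect_gt(mean(err <= pmax(0.2, 0.05 * m$true_length)), 0.95)
  expect_lt(median(err), 0.1)
  expect_lt(median(abs(m$width - m$true_width)), 0.08)
})

test_that("the filter cascade equals brute-force rule application", {
  set.seed(8)
  n <- 60
  toy <- data.frame(id = 1:n,
                    length = runif(n, 0.5, 6),
                    area = runif(n, 0.3, 4),
                    circularity = runif(n, 0.05, 1),
                    touches_edge = runif(n) < 0.25)
  cfg <- filter_config()
  out <- apply_filters(toy, cfg)
  brute <- toy[toy$area >= 1 & toy$circularity >= 0 &
                 toy$circularity <= 0.9 & toy$length > 1 &
                 !toy$touches_edge, ]
  expect_equal(out$id, brute$id)
  # conservation: survivors and rejects partition the input
  expect_setequal(c(out$id, attr(out, "rejected_ids")), toy$id)
  expect_length(intersect(out$id, attr(out, "rejected_ids")), 0)
})

test_that("filter boundaries follow the stated semantics", {
  rec <- function(len, circ = 0.5, area = 2, edge = FALSE)
    data.frame(id = 1L, length = len, area = area, circularity = circ,
               touches_edge = edge)
  expect_equal(nrow(apply_filters(rec(0.9))), 0)    # 1 um or less: debris
  expect_equal(nrow(apply_filters(rec(1.0))), 0)    # bound is exclusive
  expect_equal(nrow(apply_filters(rec(1.01))), 1)
  expect_equal(nrow(apply_filters(rec(3, circ = 0.95))), 0)
  expect_equal(nrow(apply_filters(rec(3, circ = 0.9))), 1)  # inclusive
  expect_equal(nrow(apply_filters(rec(3, area = 1))), 1)    # inclusive
  expect_equal(nrow(apply_filters(rec(3, edge = TRUE))), 0)
  expect_equal(nrow(apply_filters(rec(3, edge = TRUE),
                                  filter_config(exclude_edges = FALSE))), 1)
  empty <- apply_filters(data.frame(id = integer(0), length = numeric(0),
                                    area = numeric(0),
                                    circularity = numeric(0),
                                    touches_edge = logical(0)))
  expect_equal(nrow(empty), 0)
})

test_that("tightening any single bound never increases survivors", {
  set.seed(9)
  n <- 80
  toy <- data.frame(id = 1:n, length = runif(n, 0.5, 6),
                    area = runif(n, 0.3, 4),
                    circularity = runif(n, 0.05, 1),
                    touches_edge = runif(n) < 0.25)
  base <- nrow(apply_filters(toy, filter_config()))
  expect_lte(nrow(apply_filters(toy, filter_config(min_area = 1.5))), base)
  expect_lte(nrow(apply_filters(toy, filter_config(min_length = 1.5))),
             base)
  expect_lte(nrow(apply_filters(toy, filter_config(
    circularity_range = c(0, 0.7)))), base)
  expect_gte(nrow(apply_filters(toy, filter_config(
    exclude_edges = FALSE))), base)
})

test_that("length typing splits exactly at 4 um", {
  recs <- data.frame(id = 1:4, length = c(4.0, 4.1, 1.2, 12))
  typed <- classify_length(recs)
  expect_equal(typed$type, c("SHORT", "LONG", "SHORT", "LONG"))
  expect_equal(mean(classify_length(
    data.frame(id = 1:3, length = c(1, 2, 3)))$type == "LONG"), 0)
  expect_error(classify_length(data.frame(id = 1, length = -1)),
               "positive")
})
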