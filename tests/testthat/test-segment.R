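test_that("labeling is 8-connected with consecutive ids", {
  m <- matrix(FALSE, 8, 8)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE           # diagonal contact: one object
  m[6, 6] <- TRUE; m[8, 8] <- TRUE           # gap: separate objects
  lab <- label_components(m)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_true(lab[6, 6] != lab[8, 8])
  expect_setequal(unique(lab[lab > 0]), seq_len(max(lab)))
})

test_that("a constant image segments to zero droplets with a warning", {
  img <- matrix(5000, 64, 64)
  # both the intensity and the gradient threshold warn
  expect_warning(expect_warning(
    res <- segment_droplets(img, segmentation_config(), 0.325),
    "constant image"), "constant image")
  expect_equal(max(res$labels), 0)
})

test_that("a noiseless rendered disc is recovered as one label of the right area", {
  st <- disc_image(radius_px = 20)
  cfg <- segmentation_config(gaussian_sigma_px = 1,
                             intensity_threshold = "fixed:11000",
                             gradient_threshold = "fixed:60000",
                             min_droplet_area_um2 = 1)
  res <- segment_droplets(st$blue, cfg, 0.325)
  expect_equal(max(res$labels), 1)
  expect_equal(sum(res$labels == 1) * 0.325^2, pi * 20^2 * 0.325^2,
               tolerance = 0.1)
})

test_that("two well-separated discs give two labels; automatic thresholds work", {
  spec <- scene_spec(field_width_um = 83.2, field_height_um = 83.2,
                     pixel_size_um = 0.325, n_aggregates = 0, noise_sd = 0,
                     seed = 1L)
  scene <- sample_scene(spec)
  scene$droplets <- data.frame(id = 1:2, x_um = c(20, 62), y_um = c(20, 62),
                               area_um2 = pi * 36, radius_um = 6)
  st <- render_channels(scene, spec)
  res <- segment_droplets(st$blue, segmentation_config(), 0.325)
  expect_equal(max(res$labels), 2)
})

test_that("segmentation is idempotent on a binary rendering of its own mask", {
  st <- disc_image(radius_px = 15)
  cfg <- segmentation_config(gaussian_sigma_px = 0,
                             intensity_threshold = "fixed:11000",
                             gradient_threshold = "fixed:1e9",
                             min_droplet_area_um2 = 0)
  first <- segment_droplets(st$blue, cfg, 0.325)
  rerendered <- matrix(2000, nrow(first$labels), ncol(first$labels))
  rerendered[first$labels > 0] <- 20000
  second <- segment_droplets(rerendered, cfg, 0.325)
  expect_identical(second$labels > 0, first$labels > 0)
})

test_that("hole filling never shrinks components; size filtering never adds them", {
  spec <- tiny_spec(seed = 21, noise_sd = 2000)
  st <- render_channels(sample_scene(spec), spec)
  cfg_nofill <- segmentation_config(fill_holes = FALSE)
  cfg_fill <- segmentation_config(fill_holes = TRUE)
  a <- segment_droplets(st$blue, cfg_nofill, 0.325)
  b <- segment_droplets(st$blue, cfg_fill, 0.325)
  expect_gte(sum(b$labels > 0), sum(a$labels > 0))
  cfg_min <- segmentation_config(min_droplet_area_um2 = 20)
  c0 <- segment_droplets(st$blue, segmentation_config(min_droplet_area_um2 = 0),
                         0.325)
  c1 <- segment_droplets(st$blue, cfg_min, 0.325)
  expect_lte(max(c1$labels), max(c0$labels))
})

test_that("cell segmentation separates live and dead and applies the ratio rule", {
  # blank channels: two empty masks
  blank <- matrix(1000, 64, 64)
  expect_warning(expect_warning(
    res <- segment_cells(blank, blank, segmentation_config(), 0.325)))
  expect_false(any(res$live) || any(res$dead))
  # rendered scene, noiseless: component counts match the ground truth split
  spec <- scene_spec(field_width_um = 130, field_height_um = 130,
                     pixel_size_um = 0.325, n_aggregates = 0, noise_sd = 0,
                     seed = 2L)
  scene <- sample_scene(spec)
  xs <- seq(15, 115, length.out = 15)
  scene$cells <- data.frame(id = 1:15, x_um = xs,
                            y_um = rep(c(30, 65, 100), 5),
                            area_um2 = 1.5,
                            live = rep(c(TRUE, FALSE, TRUE), 5),
                            host_droplet = NA_integer_, aggregate_id = 1:15)
  st <- render_channels(scene, spec)
  cfg <- segmentation_config(gaussian_sigma_px = 1,
                             cell_threshold = "fixed:11000")
  res <- segment_cells(st$green, st$red, cfg, 0.325)
  live_lab <- label_components(res$live)
  dead_lab <- label_components(res$dead)
  expect_equal(max(live_lab), 10)
  expect_equal(max(dead_lab), 5)
  expect_false(any(res$live & res$dead))
  # ratio rule: green at twice red, both suprathreshold -> live
  g <- matrix(100, 32, 32); r <- matrix(100, 32, 32)
  g[10:12, 10:12] <- 30000; r[10:12, 10:12] <- 15000
  res <- segment_cells(g, r, segmentation_config(
    gaussian_sigma_px = 0, cell_threshold = "fixed:10000"), 0.325)
  expect_true(all(res$live[10:12, 10:12]))
  expect_false(any(res$dead))
})

test_that("mismatched cell-channel dimensions are an error", {
  expect_error(segment_cells(matrix(0, 4, 4), matrix(0, 5, 5),
                             segmentation_config(), 0.325), "4x4.*5x5")
})

test_that("droplet detection on the synthetic benchmark is accurate", {
  # 6 seeded scenes at signal/noise 5; the 20-scene version runs in the
  # acceptance suite
  f1 <- errs <- c()
  for (seed in 1:6) {
    spec <- benchmark_scene_spec(seed)
    scene <- sample_scene(spec)
    st <- render_channels(scene, spec)
    res <- segment_droplets(st$blue, benchmark_seg_config(),
                            spec$pixel_size_um)
    m <- match_droplets(scene, res)
    f1 <- c(f1, m$f1)
    errs <- c(errs, m$area_rel_err)
  }
  expect_gte(mean(f1), 0.9)
  expect_lte(mean(errs), 0.15)
})
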