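rec <- function(area, live, dead, field = "1")
  data.frame(droplet_id = seq_along(area),
             field_id = rep_len(field, length(area)), area_um2 = area,
             cell_area_um2 = live + dead, live_area_um2 = live,
             dead_area_um2 = dead)

test_that("size distribution normalizes by scanned area and pools fields", {
  b <- bin_spec(edges = c(1, 1e4))
  r <- rec(rep(100, 100), 0, 0)
  expect_equal(size_distribution(r, 10, b)$count_per_mm2, 10)
  # two fields with 10 and 20 droplets/mm2: mean 15, SEM 5
  r2 <- rec(rep(100, 30), 0, 0, field = rep(c("a", "b"), c(10, 20)))
  sd2 <- size_distribution(r2, 2, b)
  expect_equal(sd2$count_per_mm2, 15)
  expect_equal(sd2$sem, 5)
  expect_error(size_distribution(r, 0, b), "scanned_area")
  # empty input is valid and all-zero
  expect_equal(size_distribution(rec(numeric(0), numeric(0), numeric(0)),
                                 5, b)$count_per_mm2, 0)
})

test_that("size distribution equals the direct ground-truth histogram", {
  scene <- sample_scene(tiny_spec(seed = 41, n_aggregates = 30))
  r <- scene_records(scene)$droplets
  bins <- bin_spec(lo = 10, hi = 1000, n = 6)
  got <- size_distribution(r, 1, bins)$count_per_mm2
  oracle <- graphics::hist(scene$droplets$area_um2, breaks = unclass(bins),
                           plot = FALSE)$counts
  expect_equal(got, oracle)
})

test_that("binned means and SEMs follow the definitions", {
  b <- bin_spec(edges = c(1, 100))
  c1 <- binned_mean_curve(c(10, 20), c(2, 4), b)
  expect_equal(c1$mean, 3)
  expect_equal(c1$sem, 1)
  expect_equal(c1$bin_center, 10)  # geometric mean of edges
  # constant y: SEM 0 in every occupied bin
  c2 <- binned_mean_curve(10^runif(50, 0, 2), rep(7, 50),
                          bin_spec(lo = 1, hi = 100, n = 4))
  expect_true(all(c2$sem[c2$n > 0] == 0))
  # empty bins flagged with n = 0, not dropped
  c3 <- binned_mean_curve(c(2, 3), c(1, 1), bin_spec(lo = 1, hi = 1000, n = 3))
  expect_equal(nrow(c3), 3)
  expect_true(any(c3$n == 0 & is.na(c3$mean)))
  expect_error(binned_mean_curve(1:3, 1:2), "length")
})

test_that("survival curve handles the documented edge cases", {
  b <- bin_spec(lo = 1, hi = 1e4, n = 4)
  one <- rec(50, live = 5, dead = 0)
  expect_equal(survival_vs_droplet_size(one, b)$mean[2], 1.0)
  two <- rec(c(40, 60), live = c(0, 3), dead = c(3, 0))
  cur <- survival_vs_droplet_size(two, b)
  expect_equal(cur$mean[2], 0.5)
  expect_equal(cur$sem[2], 0.5)
  # droplets with no cells are excluded, empty curve warns
  expect_warning(empty <- survival_vs_droplet_size(rec(100, 0, 0), b),
                 "no droplets")
  expect_true(all(empty$n == 0))
  # pooled variant: area-weighted ratio
  pool <- survival_vs_droplet_size(rec(c(40, 60), c(10, 0), c(0, 30)), b,
                                   pooled = TRUE)
  expect_equal(pool$mean[2], 0.25)
})

test_that("survival curve is invariant to a common rescaling of all areas", {
  scene <- sample_scene(tiny_spec(seed = 43, n_aggregates = 40))
  r <- scene_records(scene)$droplets
  b <- bin_spec(lo = 10, hi = 1000, n = 5)
  base <- survival_vs_droplet_size(r, b)
  k <- 3.7
  r2 <- r
  r2$area_um2 <- r2$area_um2 * k
  b2 <- bin_spec(edges = unclass(b) * k)
  expect_equal(survival_vs_droplet_size(r2, b2)$mean, base$mean)
  expect_equal(survival_vs_droplet_size(r2, b2)$n, base$n)
})

test_that("survival curve recovers the generator logistic", {
  spec <- scene_spec(field_width_um = 3328, field_height_um = 3328,
                     pixel_size_um = 0.65, n_aggregates = 800, seed = 47L)
  scene <- sample_scene(spec)
  r <- scene_records(scene)$droplets
  bins <- bin_spec(lo = 10, hi = 1e4, n = 6)
  cur <- survival_vs_droplet_size(r, bins, pooled = TRUE)
  foot <- spec$aggregate_area_params$cell_footprint_um2
  for (i in which(cur$n >= 30)) {
    sel <- r$area_um2 >= cur$bin_lo[i] & r$area_um2 < cur$bin_hi[i] &
      r$cell_area_um2 > 0
    expected <- stats::weighted.mean(
      dropsurv:::survival_prob(r$area_um2[sel], spec), r$cell_area_um2[sel])
    n_cells <- sum(r$cell_area_um2[sel]) / foot
    ci <- 2.58 * sqrt(expected * (1 - expected) / n_cells)
    expect_lt(abs(cur$mean[i] - expected), ci + 0.02)
  }
})

test_that("population by droplet size conserves total cell area", {
  scene <- sample_scene(tiny_spec(seed = 45, n_aggregates = 25))
  r <- scene_records(scene)$droplets
  b <- bin_spec(lo = 1, hi = 1e4, n = 8)
  pop <- population_by_droplet_size(r, b)
  expect_equal(sum(pop$live_area_per_mm2) + sum(pop$dead_area_per_mm2),
               sum(r$cell_area_um2))
  # all cells in one droplet: one occupied bin holds everything
  one <- rec(500, live = 12, dead = 8)
  p1 <- population_by_droplet_size(one, b)
  expect_equal(sum(p1$live_area_per_mm2 > 0 | p1$dead_area_per_mm2 > 0), 1)
  expect_equal(max(p1$live_area_per_mm2 + p1$dead_area_per_mm2), 20)
})

test_that("2-D survival grid summarizes per-object survival", {
  objs <- data.frame(aggregate_id = 1, field_id = "1", area_um2 = 5,
                     host_droplet_id = 1, host_droplet_area_um2 = 200,
                     live_area_um2 = 4, dead_area_um2 = 1,
                     survival_rate = 0.8)
  g <- survival_2d(objs)
  occupied <- !is.na(g$mean_survival)
  expect_equal(sum(occupied), 1)
  expect_equal(g$mean_survival[occupied], 0.8)
  empty <- survival_2d(objs[0, ])
  expect_true(all(is.na(empty$mean_survival)))
  expect_true(all(empty$n == 0))
})

test_that("2-D grid rows are flat when survival depends on droplet size only", {
  spec <- scene_spec(field_width_um = 3328, field_height_um = 3328,
                     pixel_size_um = 0.65, n_aggregates = 600,
                     coupling_noise_sd = 1.2, seed = 49L)
  scene <- sample_scene(spec)
  objs <- scene_records(scene)$objects
  g <- survival_2d(objs, droplet_bins = bin_spec(lo = 10, hi = 1e4, n = 4),
                   aggregate_bins = bin_spec(lo = 0.5, hi = 1e3, n = 4))
  for (dc in unique(g$droplet_bin_center)) {
    row <- g[g$droplet_bin_center == dc & g$n >= 25, ]
    if (nrow(row) >= 2) {
      spread <- diff(range(row$mean_survival))
      expect_lt(spread, 3 * sqrt(sum(row$sem^2) / nrow(row)) + 0.1)
    }
  }
})

test_that("population-above-size curve is a proper survival-style tail", {
  r <- rec(c(50, 500, 5000), live = c(1, 2, 3), dead = c(1, 0, 1))
  cur <- population_above_size(r, thresholds = c(10, 100, 1000, 10000))
  expect_equal(cur$fraction_above[1], 1.0)
  expect_equal(cur$fraction_above[4], 0.0)
  expect_true(all(diff(cur$fraction_above) <= 0))
  expect_equal(cur$fraction_above[2], 6 / 8)  # droplets >= 100 um2
  expect_error(population_above_size(rec(10, 0, 0)), "zero")
  # aggregated scenes dominate solitary scenes at large thresholds
  agg <- sample_scene(scene_spec(field_width_um = 1664, field_height_um = 1664,
                                 pixel_size_um = 0.65, n_aggregates = 300,
                                 droplet_area_min_um2 = 10,
                                 droplet_area_max_um2 = 1e4, seed = 51L))
  sol <- sample_scene(scene_spec(field_width_um = 1664, field_height_um = 1664,
                                 pixel_size_um = 0.65, n_aggregates = 300,
                                 droplet_area_min_um2 = 2,
                                 droplet_area_max_um2 = 100, seed = 52L))
  th <- 10^seq(1.5, 3.5, length.out = 20)
  fa <- population_above_size(scene_records(agg)$droplets, th)$fraction_above
  fs <- population_above_size(scene_records(sol)$droplets, th)$fraction_above
  expect_true(all(fa >= fs))
  expect_gt(mean(fa - fs), 0.2)
})

test_that("overall survival pools areas", {
  expect_equal(overall_survival(rec(c(10, 20), c(5, 15), c(0, 0))), 1.0)
  expect_equal(overall_survival(rec(100, 20, 80)), 0.2)
  expect_error(overall_survival(rec(100, 0, 0)), "no cell area")
})

test_that("contribution model weighs droplet size over aggregate size when it should", {
  spec <- scene_spec(field_width_um = 6656, field_height_um = 6656,
                     pixel_size_um = 0.65, n_aggregates = 3000,
                     coupling_noise_sd = 1.0, seed = 53L)
  scene <- sample_scene(spec)
  objs <- scene_records(scene)$objects
  fit <- fit_contribution(objs)
  expect_equal(fit$dominant, "droplet")
  expect_gt(abs(fit$coefficients["droplet"]),
            abs(fit$coefficients["aggregate"]))
  # aggregate CI covers 0
  expect_true(fit$ci["aggregate", "lo"] <= 0 && fit$ci["aggregate", "hi"] >= 0)
  # constant survival: both coefficients near zero
  flat <- scene_spec(field_width_um = 3328, field_height_um = 3328,
                     pixel_size_um = 0.65, n_aggregates = 800,
                     survival_slope = 0, survival_s_min = 0.4,
                     survival_s_max = 0.4, seed = 54L)
  f2 <- fit_contribution(scene_records(sample_scene(flat))$objects)
  expect_true(all(f2$ci[, "lo"] <= 0 & f2$ci[, "hi"] >= 0))
  expect_error(fit_contribution(objs[1, ]), "fewer than 2")
})
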