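test_that("cellular-object labeling follows 8-connectivity of the mask union", {
  live <- matrix(FALSE, 10, 10); dead <- matrix(FALSE, 10, 10)
  expect_equal(max(label_aggregates(live, dead, 0.25)$labels), 0)
  live[2, 2] <- TRUE; dead[3, 3] <- TRUE    # touching diagonally: one object
  live[7, 7] <- TRUE; live[7, 9] <- TRUE    # gap: two objects
  lab <- label_aggregates(live, dead, 0.25)$labels
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[7, 7] != lab[7, 9])
  expect_equal(max(lab), 3)
  expect_error(label_aggregates(live, matrix(FALSE, 9, 10), 0.25),
               "dimensions differ")
})

test_that("host assignment picks the maximum-overlap droplet", {
  ol <- matrix(0L, 12, 12); dl <- matrix(0L, 12, 12)
  dl[1:6, ] <- 1L; dl[7:12, ] <- 2L
  ol[2:3, 2:3] <- 1L                        # fully inside droplet 1
  ol[5:8, 1:6] <- 2L                        # straddles: 12 px in 1, 12 in 2
  obj <- label_image(ol, 1); drp <- label_image(dl, 1)
  host <- assign_to_droplets(obj, drp)
  expect_equal(host[1], 1L)
  expect_equal(host[2], 1L)                 # tie broken to smaller id
  # 10 px vs 14 px overlap: the larger wins
  ol2 <- matrix(0L, 12, 12)
  ol2[5:8, 1:6] <- 1L
  dl2 <- matrix(0L, 12, 12); dl2[1:6, 1:6] <- 1L; dl2[7:12, 1:6] <- 2L
  dl2[6, 1:2] <- 2L                         # shift 2 px: overlaps 10 vs 14
  host2 <- assign_to_droplets(label_image(ol2, 1), label_image(dl2, 1))
  expect_equal(host2[1], 2L)
  # object on background only is dry
  ol3 <- matrix(0L, 12, 12); ol3[1, 12] <- 1L
  dl3 <- matrix(0L, 12, 12); dl3[6, 6] <- 1L
  expect_true(is.na(assign_to_droplets(label_image(ol3, 1),
                                       label_image(dl3, 1))[1]))
})

test_that("host assignment equals the brute-force pixel-overlap oracle", {
  set.seed(99)
  for (rep in 1:20) {
    dl <- matrix(sample(0:4, 64 * 64, replace = TRUE, prob = c(.6, rep(.1, 4))),
                 64, 64)
    ol <- matrix(sample(0:5, 64 * 64, replace = TRUE, prob = c(.7, rep(.06, 5))),
                 64, 64)
    # oracle: vectorized exhaustive overlap count (independent of the
    # implementation's table-based path)
    n_obj <- max(ol)
    expected <- rep(NA_integer_, n_obj)
    for (o in seq_len(n_obj)) {
      d <- dl[ol == o]
      d <- d[d > 0]
      if (length(d)) {
        counts <- tabulate(d, nbins = max(dl))
        expected[o] <- which.max(counts)    # which.max takes the smallest tie
      }
    }
    got <- assign_to_droplets(label_image(ol, 1), label_image(dl, 1))
    expect_identical(got, expected)
  }
})

test_that("record tables have the documented arithmetic and invariants", {
  dl <- matrix(0L, 20, 20); dl[3:12, 3:12] <- 1L; dl[15:18, 15:18] <- 2L
  live <- matrix(FALSE, 20, 20); dead <- matrix(FALSE, 20, 20)
  live[4:8, 4:11] <- TRUE                   # 40 px, all live, inside droplet 1
  ol <- matrix(0L, 20, 20); ol[live] <- 1L
  tabs <- build_tables(label_image(dl, 0.5), label_image(ol, 0.5), live, dead,
                       assign_to_droplets(label_image(ol, 0.5),
                                          label_image(dl, 0.5)),
                       pixel_size_um = 0.5)
  expect_equal(tabs$droplets$live_area_um2[1], 40 * 0.25)
  expect_equal(tabs$objects$survival_rate[1], 1.0)
  # droplet 2 holds no cells
  expect_equal(tabs$droplets$cell_area_um2[2], 0)
  expect_equal(tabs$droplets$dead_area_um2[2], 0)
  # invariants
  expect_true(all(tabs$droplets$live_area_um2 + tabs$droplets$dead_area_um2 ==
                    tabs$droplets$cell_area_um2))
  expect_true(all(tabs$droplets$cell_area_um2 <= tabs$droplets$area_um2))
  expect_error(build_tables(label_image(dl, 0.5), label_image(ol, 0.5), live,
                            dead, integer(0), 0.5), "assignment covers")
})

test_that("cell area is conserved between masks and tables (wet + dry)", {
  spec <- tiny_spec(seed = 31, n_aggregates = 15, noise_sd = 2000)
  scene <- sample_scene(spec)
  st <- render_channels(scene, spec)
  px <- spec$pixel_size_um
  dl <- segment_droplets(st$blue, benchmark_seg_config(), px)
  cm <- segment_cells(st$green, st$red, benchmark_seg_config(), px)
  ol <- label_aggregates(cm$live, cm$dead, px)
  asg <- assign_to_droplets(ol, dl)
  tabs <- build_tables(dl, ol, cm$live, cm$dead, asg, px)
  dry_live <- sum(cm$live & dl$labels == 0) * px^2
  expect_equal(sum(tabs$droplets$live_area_um2) + dry_live,
               sum(cm$live) * px^2, tolerance = 1e-9)
  dry_dead <- sum(cm$dead & dl$labels == 0) * px^2
  expect_equal(sum(tabs$droplets$dead_area_um2) + dry_dead,
               sum(cm$dead) * px^2, tolerance = 1e-9)
})

test_that("recovered droplet areas track ground truth across scenes", {
  rho <- c()
  for (seed in 1:5) {
    spec <- benchmark_scene_spec(seed)
    scene <- sample_scene(spec)
    st <- render_channels(scene, spec)
    dl <- segment_droplets(st$blue, benchmark_seg_config(), spec$pixel_size_um)
    m <- match_droplets(scene, dl)
    px <- spec$pixel_size_um
    seg_area <- tabulate(dl$labels[dl$labels > 0]) * px^2
    lab_at <- dl$labels[cbind(
      pmin(pmax(round(scene$droplets$x_um / px), 1), nrow(dl$labels)),
      pmin(pmax(round(scene$droplets$y_um / px), 1), ncol(dl$labels)))]
    ok <- lab_at > 0
    rho <- c(rho, stats::cor(seg_area[lab_at[ok]],
                             scene$droplets$area_um2[ok],
                             method = "spearman"))
  }
  expect_gte(mean(rho), 0.95)
})
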