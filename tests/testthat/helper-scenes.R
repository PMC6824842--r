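# Shared fixtures, all generated in code.

# small, fast scene: 166.4 x 166.4 um at 0.325 um/px (512 px), droplets
# [10, 800] um^2, noiseless unless asked
tiny_spec <- function(seed = 1L, ...) {
  args <- list(field_width_um = 166.4, field_height_um = 166.4,
               pixel_size_um = 0.325, n_aggregates = 12,
               droplet_area_max_um2 = 800, noise_sd = 0, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(scene_spec, args)
}

# render a single ideal disc (radius in px) on a square raster, no noise
disc_image <- function(radius_px, size_px = 128, bg = 2000, sig = 20000,
                       px = 0.325) {
  spec <- scene_spec(field_width_um = size_px * px,
                     field_height_um = size_px * px, pixel_size_um = px,
                     n_aggregates = 0, noise_sd = 0,
                     background_level = bg, signal_level = sig, seed = 1L)
  r_um <- radius_px * px
  c_um <- size_px * px / 2
  scene <- sample_scene(spec)
  scene$droplets <- data.frame(id = 1L, x_um = c_um, y_um = c_um,
                               area_um2 = pi * r_um^2, radius_um = r_um)
  render_channels(scene, spec)
}

# brute-force pixel-overlap oracle for host assignment
assign_oracle <- function(objects, droplets) {
  ol <- objects$labels; dl <- droplets$labels
  n_obj <- max(ol)
  host <- rep(NA_integer_, n_obj)
  for (o in seq_len(n_obj)) {
    counts <- integer(max(dl, 1))
    for (i in seq_len(nrow(ol))) for (j in seq_len(ncol(ol))) {
      if (ol[i, j] == o && dl[i, j] > 0)
        counts[dl[i, j]] <- counts[dl[i, j]] + 1L
    }
    if (any(counts > 0)) host[o] <- which.max(counts)  # ties: smaller id
  }
  host
}

# ground-truth record tables straight from a scene (no imaging), for
# statistics tests: one droplet row and one object row per aggregate
scene_records <- function(scene) {
  foot <- scene$spec$aggregate_area_params$cell_footprint_um2
  live <- tapply(scene$cells$live, scene$cells$host_droplet, sum)
  live <- ifelse(is.na(live), 0, live) * foot
  n_cells <- tapply(scene$cells$id, scene$cells$host_droplet, length)
  total <- ifelse(is.na(n_cells), 0, n_cells) * foot
  d <- scene$droplets
  drops <- data.frame(droplet_id = d$id, field_id = "1", area_um2 = d$area_um2,
                      cell_area_um2 = total[as.character(d$id)],
                      live_area_um2 = live[as.character(d$id)],
                      dead_area_um2 = (total - live)[as.character(d$id)])
  drops[is.na(drops)] <- 0
  objs <- data.frame(aggregate_id = d$id, field_id = "1",
                     area_um2 = drops$cell_area_um2,
                     host_droplet_id = d$id,
                     host_droplet_area_um2 = d$area_um2,
                     live_area_um2 = drops$live_area_um2,
                     dead_area_um2 = drops$dead_area_um2,
                     survival_rate = ifelse(drops$cell_area_um2 > 0,
                                            drops$live_area_um2 /
                                              drops$cell_area_um2, NA))
  list(droplets = drops, objects = objs)
}
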