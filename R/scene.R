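#' Specification of a synthetic drying-surface scene
#'
#' A `scene_spec` collects every parameter of the synthetic-scene generator:
#' the field geometry, the truncated power law governing droplet areas, the
#' coupling between droplet area and the cell-covered area inside it, the
#' logistic dependence of per-cell survival probability on log10 droplet
#' area, and the rendering intensities. Defaults reproduce the statistical
#' structure observed on bacteria-colonized glass drying at moderate
#' humidity: droplet areas `p(A) ~ A^-1.2` over `[10, 1e4]` um^2, cell
#' coverage rising roughly linearly with droplet area, and survival climbing
#' from a few percent in the smallest droplets to a majority in droplets
#' above 1e4 um^2.
#'
#' @param field_width_um,field_height_um field of view, um.
#' @param pixel_size_um pixel pitch, um/px (0.1625 matches a 40x objective on
#'   a common sCMOS sensor).
#' @param n_aggregates number of cellular objects (solitary cells count as
#'   aggregates of one); one droplet forms around each.
#' @param aggregate_area_params list with `cell_footprint_um2` (projected area
#'   of a single cell) and `max_fill_fraction` (cap on cell-covered fraction
#'   of a droplet).
#' @param droplet_exponent_gamma density exponent of droplet areas (< 0).
#' @param droplet_area_min_um2,droplet_area_max_um2 truncation bounds, um^2.
#' @param coupling_coeff,coupling_noise_sd expected cell-covered area is
#'   `coupling_coeff * A` perturbed by lognormal noise with this sd (on the
#'   log scale), clipped to `max_fill_fraction * A`.
#' @param survival_s_min,survival_s_max floor and ceiling of the per-cell
#'   survival probability.
#' @param survival_log_midpoint,survival_slope logistic midpoint and slope on
#'   log10(droplet area): `s(A) = s_min + (s_max - s_min) *
#'   plogis(survival_slope * (log10(A) - survival_log_midpoint))`.
#' @param background_level,signal_level,noise_sd rendering intensities on the
#'   16-bit scale.
#' @param seed integer seed; the scene and its rendering are a pure function
#'   of the spec.
#' @return object of class `"scene_spec"`.
#' @export
scene_spec <- function(field_width_um = 332.8, field_height_um = 332.8,
                       pixel_size_um = 0.1625,
                       n_aggregates = 40,
                       aggregate_area_params = list(cell_footprint_um2 = 1.0,
                                                    max_fill_fraction = 0.6),
                       droplet_exponent_gamma = -1.2,
                       droplet_area_min_um2 = 10,
                       droplet_area_max_um2 = 1e4,
                       coupling_coeff = 0.12, coupling_noise_sd = 0.4,
                       survival_s_min = 0.02, survival_s_max = 0.8,
                       survival_log_midpoint = 3, survival_slope = 2.2,
                       background_level = 2000, signal_level = 20000,
                       noise_sd = 800,
                       seed = 1L) {
  spec <- list(field_width_um = field_width_um, field_height_um = field_height_um,
               pixel_size_um = pixel_size_um, n_aggregates = n_aggregates,
               aggregate_area_params = aggregate_area_params,
               droplet_exponent_gamma = droplet_exponent_gamma,
               droplet_area_min_um2 = droplet_area_min_um2,
               droplet_area_max_um2 = droplet_area_max_um2,
               coupling_coeff = coupling_coeff,
               coupling_noise_sd = coupling_noise_sd,
               survival_s_min = survival_s_min, survival_s_max = survival_s_max,
               survival_log_midpoint = survival_log_midpoint,
               survival_slope = survival_slope,
               background_level = background_level, signal_level = signal_level,
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

#' Validate a scene specification
#'
#' Checks every invariant of [scene_spec()] and stops with a message naming
#' the first violated one.
#' @param spec a `scene_spec`.
#' @return the spec, invisibly.
#' @export
validate_scene_spec <- function(spec) {
  fail <- function(what) stop("invalid scene_spec: ", what, call. = FALSE)
  if (!(spec$droplet_exponent_gamma < 0)) fail("droplet_exponent_gamma must be < 0")
  if (!(spec$droplet_area_min_um2 > 0 &&
        spec$droplet_area_max_um2 > spec$droplet_area_min_um2))
    fail("need 0 < droplet_area_min_um2 < droplet_area_max_um2")
  if (!(spec$survival_s_min >= 0 && spec$survival_s_min <= spec$survival_s_max &&
        spec$survival_s_max <= 1))
    fail("need 0 <= survival_s_min <= survival_s_max <= 1")
  if (!(spec$survival_slope >= 0)) fail("survival_slope must be >= 0")
  if (!(spec$pixel_size_um > 0)) fail("pixel_size_um must be > 0")
  px <- c(spec$field_width_um, spec$field_height_um) / spec$pixel_size_um
  if (any(px <= 0) || any(abs(px - round(px)) > 1e-6))
    fail("field dimensions must be positive multiples of pixel_size_um")
  if (spec$n_aggregates < 0) fail("n_aggregates must be >= 0")
  if (!(spec$coupling_noise_sd >= 0)) fail("coupling_noise_sd must be >= 0")
  if (!(spec$noise_sd >= 0)) fail("noise_sd must be >= 0")
  invisible(spec)
}

# survival probability as a function of droplet area (um^2)
survival_prob <- function(area_um2, spec) {
  spec$survival_s_min + (spec$survival_s_max - spec$survival_s_min) *
    stats::plogis(spec$survival_slope *
                    (log10(area_um2) - spec$survival_log_midpoint))
}

# place n discs of radius r (um) in the field, rejecting overlaps on a grid
# hash; falls back to overlapping placement after `attempts` failures so that
# large statistical draws never abort. `margin` (um) keeps droplets apart so
# rendered droplets stay resolvable as separate objects after blurring.
.place_discs <- function(r, W, H, attempts = 40L, margin = 3) {
  r <- r + margin / 2
  if (sum(pi * r^2) > 0.3 * W * H) attempts <- 1L  # crowded: don't thrash
  n <- length(r)
  cx <- numeric(n); cy <- numeric(n)
  cell <- max(r) * 2 + 1e-9
  grid <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(i, j) paste0(i, ",", j)
  for (k in seq_len(n)) {
    ok <- FALSE
    lo_x <- min(r[k], W / 2); lo_y <- min(r[k], H / 2)
    for (a in seq_len(attempts)) {
      x <- stats::runif(1, lo_x, W - lo_x)
      y <- stats::runif(1, lo_y, H - lo_y)
      gi <- floor(x / cell); gj <- floor(y / cell)
      clash <- FALSE
      for (ii in (gi - 1):(gi + 1)) for (jj in (gj - 1):(gj + 1)) {
        idx <- grid[[key(ii, jj)]]
        if (!is.null(idx) &&
            any((cx[idx] - x)^2 + (cy[idx] - y)^2 < (r[idx] + r[k])^2)) {
          clash <- TRUE; break
        }
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) { # crowded field: accept the last draw, overlaps allowed
      x <- stats::runif(1, lo_x, W - lo_x)
      y <- stats::runif(1, lo_y, H - lo_y)
      gi <- floor(x / cell); gj <- floor(y / cell)
    }
    cx[k] <- x; cy[k] <- y
    grid[[key(gi, gj)]] <- c(grid[[key(gi, gj)]], k)
  }
  cbind(x = cx, y = cy)
}

#' Sample a ground-truth scene
#'
#' Draws a latent scene from a [scene_spec()]: droplet areas are i.i.d. from
#' the truncated power law with exponent `droplet_exponent_gamma` on
#' `[droplet_area_min_um2, droplet_area_max_um2]` (inverse-CDF sampling, so
#' the draw is exact and seedable); the cell-covered area inside each droplet
#' is `coupling_coeff * A` with multiplicative lognormal noise, clipped to at
#' most `max_fill_fraction * A`; that area is split into cells of footprint
#' `cell_footprint_um2` packed single-layered in a disc around the droplet
#' center; each cell is live with probability `s(A)` from the logistic
#' survival law. One cellular object (aggregate) per droplet; solitary cells
#' are aggregates of one. Deterministic given `spec$seed`.
#'
#' @param spec a validated [scene_spec()].
#' @return object of class `"ground_truth_scene"`: list with data frames
#'   `droplets` (id, x_um, y_um, area_um2, radius_um), `cells` (id, x_um,
#'   y_um, area_um2, live, host_droplet, aggregate_id), `aggregates` (id,
#'   n_cells, area_um2, host_droplet), and the `spec`.
#' @export
sample_scene <- function(spec) {
  validate_scene_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_aggregates
  if (n == 0) {
    return(structure(list(
      droplets = data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                            area_um2 = numeric(), radius_um = numeric()),
      cells = data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                         area_um2 = numeric(), live = logical(),
                         host_droplet = integer(), aggregate_id = integer()),
      aggregates = data.frame(id = integer(), n_cells = integer(),
                              area_um2 = numeric(), host_droplet = integer()),
      spec = spec), class = "ground_truth_scene"))
  }

  area <- rplaw_trunc(n, spec$droplet_exponent_gamma,
                      spec$droplet_area_min_um2, spec$droplet_area_max_um2)
  radius <- sqrt(area / pi)
  if (any(2 * radius > min(spec$field_width_um, spec$field_height_um)))
    stop("sample_scene: droplet larger than the field; enlarge the field or ",
         "lower droplet_area_max_um2")
  centers <- .place_discs(radius, spec$field_width_um, spec$field_height_um)

  fill <- spec$aggregate_area_params$max_fill_fraction
  foot <- spec$aggregate_area_params$cell_footprint_um2
  cell_area <- pmin(spec$coupling_coeff * area *
                      exp(stats::rnorm(n, 0, spec$coupling_noise_sd)),
                    fill * area)
  n_cells <- pmax(1L, as.integer(round(cell_area / foot)))
  n_cells <- pmin(n_cells, as.integer(floor(fill * area / foot)))
  n_cells <- pmax(n_cells, 1L)

  p_live <- survival_prob(area, spec)

  cell_list <- vector("list", n)
  for (k in seq_len(n)) {
    m <- n_cells[k]
    # sunflower packing: single layer, roughly uniform over a disc well
    # inside the droplet
    cr <- sqrt(foot / pi)
    pack_r <- max(sqrt(m * foot / (pi * 0.55)), cr * 1.5)
    pack_r <- min(pack_r, radius[k] * 0.85)
    i <- seq_len(m)
    rr <- pack_r * sqrt((i - 0.5) / m)
    th <- i * 2.399963  # golden angle
    cell_list[[k]] <- data.frame(
      x_um = centers[k, "x"] + rr * cos(th),
      y_um = centers[k, "y"] + rr * sin(th),
      area_um2 = foot,
      live = stats::runif(m) < p_live[k],
      host_droplet = k, aggregate_id = k)
  }
  cells <- do.call(rbind, cell_list)
  cells <- cbind(id = seq_len(nrow(cells)), cells)

  structure(list(
    droplets = data.frame(id = seq_len(n), x_um = centers[, "x"],
                          y_um = centers[, "y"], area_um2 = area,
                          radius_um = radius),
    cells = cells,
    aggregates = data.frame(id = seq_len(n), n_cells = n_cells,
                            area_um2 = n_cells * foot,
                            host_droplet = seq_len(n)),
    spec = spec), class = "ground_truth_scene")
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf("ground_truth_scene: %d droplets, %d cells (%.0f%% live), %g x %g um\n",
              nrow(x$droplets), nrow(x$cells),
              if (nrow(x$cells)) 100 * mean(x$cells$live) else 0,
              x$spec$field_width_um, x$spec$field_height_um))
  invisible(x)
}

#' Write / read a ground-truth scene as a flat CSV
#'
#' One row per droplet and one per cell, distinguished by a `kind` column;
#' round-trippable up to numeric print precision (15 significant digits).
#' @param scene a `ground_truth_scene`.
#' @param path output CSV path.
#' @return `write_ground_truth`: the path, invisibly. `read_ground_truth`:
#'   a list with `droplets` and `cells` data frames.
#' @export
write_ground_truth <- function(scene, path) {
  d <- scene$droplets
  nd <- nrow(d)
  drow <- data.frame(kind = rep("droplet", nd), id = d$id,
                     x_um = d$x_um, y_um = d$y_um, area_um2 = d$area_um2,
                     live = rep(NA, nd), host_droplet = rep(NA, nd),
                     aggregate_id = rep(NA, nd))
  cc <- scene$cells
  crow <- data.frame(kind = rep("cell", nrow(cc)), id = cc$id,
                     x_um = cc$x_um, y_um = cc$y_um, area_um2 = cc$area_um2,
                     live = cc$live, host_droplet = cc$host_droplet,
                     aggregate_id = cc$aggregate_id)
  out <- rbind(drow, crow)
  ok <- tryCatch(utils::write.csv(format(out, digits = 15, trim = TRUE,
                                         scientific = FALSE),
                                  path, row.names = FALSE, quote = FALSE),
                 error = function(e) stop("write_ground_truth: cannot write ",
                                          path, ": ", conditionMessage(e)))
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("read_ground_truth: no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- tab[tab$kind == "droplet", c("id", "x_um", "y_um", "area_um2")]
  d$radius_um <- sqrt(d$area_um2 / pi)
  cc <- tab[tab$kind == "cell",
            c("id", "x_um", "y_um", "area_um2", "live", "host_droplet",
              "aggregate_id")]
  cc$live <- as.logical(cc$live)
  rownames(d) <- rownames(cc) <- NULL
  list(droplets = d, cells = cc)
}
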