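#' Multi-channel image stack
#'
#' Container for the four registered 16-bit channels of one field of view:
#' bright field (`bf`), live-cell fluorescence (`green`), dead-cell
#' fluorescence (`red`) and the shorter-wavelength channel that highlights
#' the droplets (`blue`). Matrices are indexed `[x, y]` with intensities in
#' `[0, 65535]`.
#'
#' @param bf,green,red,blue numeric matrices of identical dimensions.
#' @param pixel_size_um pixel pitch, um/px.
#' @param field_id field-of-view identifier (the 'repeat' column of output
#'   tables).
#' @return object of class `"channel_stack"`.
#' @export
channel_stack <- function(bf, green, red, blue, pixel_size_um, field_id = "1") {
  chans <- list(bf = bf, green = green, red = red, blue = blue)
  dims <- lapply(chans, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("channel_stack: channel dimensions differ: ",
         paste(names(chans), vapply(dims, paste, "", collapse = "x"),
               sep = "=", collapse = ", "))
  rng <- range(unlist(lapply(chans, range)))
  if (rng[1] < 0 || rng[2] > 65535)
    stop("channel_stack: intensities outside [0, 65535]: range ",
         rng[1], "..", rng[2])
  structure(c(chans, list(pixel_size_um = pixel_size_um,
                          field_id = as.character(field_id))),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("channel_stack '%s': %d x %d px at %.4f um/px (bf/green/red/blue)\n",
              x$field_id, nrow(x$bf), ncol(x$bf), x$pixel_size_um))
  invisible(x)
}

# paint `signal * profile` of one disc into matrix `m` ([x,y], um grid);
# profile: sigmoid edge falloff of width `edge_um` with a mild radial dome so
# the center is the brightest point and the gradient peaks at the boundary.
.paint_disc <- function(m, cx, cy, r, signal, px, edge_um, dome = 0.1) {
  nx <- nrow(m); ny <- ncol(m)
  ix <- max(1L, floor((cx - r - 4 * edge_um) / px)):
        min(nx, ceiling((cx + r + 4 * edge_um) / px))
  iy <- max(1L, floor((cy - r - 4 * edge_um) / px)):
        min(ny, ceiling((cy + r + 4 * edge_um) / px))
  xs <- (ix - 0.5) * px; ys <- (iy - 0.5) * px
  d <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))
  prof <- stats::plogis((r - d) / edge_um) * (1 - dome * pmin(d / r, 1)^2)
  m[ix, iy] <- pmax(m[ix, iy], signal * prof)
  m
}

# linear indices of pixels whose centers fall in the disc (hard raster)
.disc_indices <- function(cx, cy, r, px, nx, ny) {
  ix <- max(1L, floor((cx - r) / px)):min(nx, ceiling((cx + r) / px))
  iy <- max(1L, floor((cy - r) / px)):min(ny, ceiling((cy + r) / px))
  xs <- (ix - 0.5) * px; ys <- (iy - 0.5) * px
  inside <- which(outer((xs - cx)^2, (ys - cy)^2, "+") <= r^2, arr.ind = TRUE)
  (iy[inside[, 2]] - 1L) * nx + ix[inside[, 1]]
}

#' Render the four channels of a scene
#'
#' Rasterizes a ground-truth scene onto the pixel grid of its spec. The blue
#' channel shows each droplet as a bright interior with a smooth sigmoidal
#' falloff at the boundary (half-maximum at the true radius), so both an
#' intensity threshold and a gradient threshold recover the droplet; green
#' and red channels carry live and dead cell footprints at `signal_level`
#' over `background_level`; bright field is background only. Additive
#' Gaussian noise with sd `noise_sd` is applied to every channel, and values
#' are clipped to the 16-bit range and rounded. Deterministic given
#' `spec$seed`.
#'
#' @param scene a `ground_truth_scene`.
#' @param spec the [scene_spec()] the scene was drawn from (defaults to
#'   `scene$spec`).
#' @param field_id identifier stored on the stack.
#' @return a [channel_stack()].
#' @export
render_channels <- function(scene, spec = scene$spec, field_id = "1") {
  validate_scene_spec(spec)
  px <- spec$pixel_size_um
  nx <- as.integer(round(spec$field_width_um / px))
  ny <- as.integer(round(spec$field_height_um / px))
  W <- spec$field_width_um; H <- spec$field_height_um

  d <- scene$droplets
  if (nrow(d)) {
    out <- d$x_um - d$radius_um < 0 | d$x_um + d$radius_um > W |
           d$y_um - d$radius_um < 0 | d$y_um + d$radius_um > H
    if (any(out))
      stop("render_channels: droplets outside the field: ",
           paste(d$id[out], collapse = ", "))
  }
  cc <- scene$cells
  if (nrow(cc)) {
    cr <- sqrt(cc$area_um2 / pi)
    out <- cc$x_um - cr < 0 | cc$x_um + cr > W |
           cc$y_um - cr < 0 | cc$y_um + cr > H
    if (any(out))
      stop("render_channels: cells outside the field: ",
           paste(cc$id[out], collapse = ", "))
  }

  bg <- spec$background_level; sig <- spec$signal_level
  blank <- matrix(0, nx, ny)
  blue <- blank
  edge_um <- 2 * px
  for (k in seq_len(nrow(d)))
    blue <- .paint_disc(blue, d$x_um[k], d$y_um[k], d$radius_um[k], sig, px,
                        edge_um)
  green <- blank; red <- blank
  if (nrow(cc)) {
    cr <- sqrt(cc$area_um2 / pi)
    idx <- lapply(seq_len(nrow(cc)), function(k)
      .disc_indices(cc$x_um[k], cc$y_um[k], cr[k], px, nx, ny))
    live_idx <- unlist(idx[cc$live]); dead_idx <- unlist(idx[!cc$live])
    if (length(live_idx)) green[live_idx] <- sig
    if (length(dead_idx)) red[dead_idx] <- sig
  }

  set.seed(spec$seed + 7919L)  # separate stream from the scene draw
  finish <- function(m) {
    m <- m + bg
    if (spec$noise_sd > 0)
      m <- m + matrix(stats::rnorm(nx * ny, 0, spec$noise_sd), nx, ny)
    matrix(as.integer(round(pmin(pmax(m, 0), 65535))), nx, ny)
  }
  channel_stack(bf = finish(blank), green = finish(green), red = finish(red),
                blue = finish(blue), pixel_size_um = px, field_id = field_id)
}

#' Write / read a channel stack as 16-bit grayscale TIFFs
#'
#' One file per channel, named `<field_id>_{bf,green,red,blue}.tif`. Values
#' round-trip losslessly.
#'
#' @param stack a [channel_stack()].
#' @param dir output directory (created if needed).
#' @return `write_channel_stack`: named character vector of the four paths,
#'   invisibly.
#' @export
write_channel_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(stack$field_id, "_",
                                 c("bf", "green", "red", "blue"), ".tif"))
  names(paths) <- c("bf", "green", "red", "blue")
  for (ch in names(paths))
    tiff::writeTIFF(t(stack[[ch]]) / 65535, paths[[ch]], bits.per.sample = 16,
                    compression = "none")
  invisible(paths)
}

#' @rdname write_channel_stack
#' @param paths named character vector/list with elements `bf`, `green`,
#'   `red`, `blue` pointing at 16-bit grayscale TIFF files.
#' @param pixel_size_um pixel pitch, um/px.
#' @param field_id field identifier.
#' @export
read_channel_stack <- function(paths, pixel_size_um, field_id = "1") {
  need <- c("bf", "green", "red", "blue")
  missing_ch <- setdiff(need, names(paths))
  if (length(missing_ch))
    stop("read_channel_stack: missing channel(s): ",
         paste(missing_ch, collapse = ", "))
  imgs <- lapply(need, function(ch) {
    p <- paths[[ch]]
    if (!file.exists(p)) stop("read_channel_stack: no such file: ", p)
    img <- tiff::readTIFF(p, as.is = TRUE, info = TRUE)
    bps <- attr(img, "bits.per.sample")
    attributes(img) <- list(dim = dim(img))
    if (!is.null(bps) && bps != 16)
      stop("read_channel_stack: ", p, " is ", bps, "-bit, expected 16-bit ",
           "grayscale; convert it (e.g. rescale to the 0..65535 range) first")
    if (length(dim(img)) != 2)
      stop("read_channel_stack: ", p, " is not single-channel grayscale")
    t(img)
  })
  names(imgs) <- need
  dims <- vapply(imgs, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1)
    stop("read_channel_stack: channel dimensions differ: ",
         paste(need, dims, sep = "=", collapse = ", "))
  channel_stack(bf = imgs$bf, green = imgs$green, red = imgs$red,
                blue = imgs$blue, pixel_size_um = pixel_size_um,
                field_id = field_id)
}
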