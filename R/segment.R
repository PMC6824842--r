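#' Segmentation configuration
#'
#' Parameters of droplet and cell segmentation. Threshold methods are given
#' as tags: `"otsu"` (histogram-based, parameter-free), `"quantile:q"`
#' (q-th quantile of the processed image, `q` in (0,1)), or `"fixed:v"`
#' (absolute value on the processed-image scale). Droplets are segmented on
#' the blue channel by the union of an intensity mask and a gradient-
#' magnitude mask after Gaussian smoothing; cells by per-channel histogram
#' thresholds on green (live) and red (dead).
#'
#' @param gaussian_sigma_px Gaussian pre-smoothing sigma, px.
#' @param intensity_threshold,gradient_threshold,cell_threshold method tags
#'   as above; the gradient default is the 90th percentile of the Sobel
#'   magnitude, the others default to Otsu.
#' @param min_droplet_area_um2,min_cell_area_um2 components smaller than this
#'   are removed (um^2).
#' @param fill_holes fill holes in droplet components.
#' @return object of class `"segmentation_config"`.
#' @export
segmentation_config <- function(gaussian_sigma_px = 2,
                                intensity_threshold = "otsu",
                                gradient_threshold = "quantile:0.9",
                                min_droplet_area_um2 = 1,
                                fill_holes = TRUE,
                                cell_threshold = "otsu",
                                min_cell_area_um2 = 0.25) {
  stopifnot(gaussian_sigma_px >= 0, min_droplet_area_um2 >= 0,
            min_cell_area_um2 >= 0)
  for (m in c(intensity_threshold, gradient_threshold, cell_threshold))
    .parse_threshold(m)  # validate tags early
  structure(list(gaussian_sigma_px = gaussian_sigma_px,
                 intensity_threshold = intensity_threshold,
                 gradient_threshold = gradient_threshold,
                 min_droplet_area_um2 = min_droplet_area_um2,
                 fill_holes = isTRUE(fill_holes),
                 cell_threshold = cell_threshold,
                 min_cell_area_um2 = min_cell_area_um2),
            class = "segmentation_config")
}

.parse_threshold <- function(tag) {
  if (identical(tag, "otsu")) return(list(method = "otsu"))
  if (grepl("^quantile:", tag)) {
    q <- as.numeric(sub("^quantile:", "", tag))
    if (!is.finite(q) || q <= 0 || q >= 1)
      stop("threshold tag '", tag, "': quantile must be in (0,1)")
    return(list(method = "quantile", q = q))
  }
  if (grepl("^fixed:", tag)) {
    v <- as.numeric(sub("^fixed:", "", tag))
    if (!is.finite(v)) stop("threshold tag '", tag, "': bad fixed value")
    return(list(method = "fixed", v = v))
  }
  stop("unknown threshold tag '", tag,
       "'; use 'otsu', 'quantile:q' or 'fixed:v'")
}

# resolve a threshold tag against image values (matrix, any scale);
# returns NA with a warning for degenerate (constant) input under automatic
# methods, which callers turn into an empty mask.
.resolve_threshold <- function(m, tag) {
  p <- .parse_threshold(tag)
  if (p$method == "fixed") return(p$v)
  rng <- range(m)
  if (diff(rng) == 0) {
    warning("automatic threshold on a constant image; returning empty mask",
            call. = FALSE)
    return(NA_real_)
  }
  if (p$method == "quantile") return(unname(stats::quantile(m, p$q)))
  scaled <- (m - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 4096)
  rng[1] + thr * diff(rng)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged via graph connected components (igraph, C speed).
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(imageData(lab)), nrow(mask), ncol(mask))
  nmax <- max(lab)
  if (nmax == 0) return(lab)
  nx <- nrow(lab); ny <- ncol(lab)
  a <- c(lab[-nx, -ny], lab[-1, -ny])   # diagonal and anti-diagonal
  b <- c(lab[-1, -1],  lab[-nx, -1])
  sel <- a > 0 & b > 0 & a != b
  if (!any(sel)) return(lab)
  edges <- unique(cbind(a[sel], b[sel]))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nmax - igraph::vcount(g)))
  memb <- igraph::components(g)$membership[seq_len(nmax)]
  remap <- match(memb, unique(memb))  # consecutive, ordered by first label
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

# drop components with pixel count < min_px and relabel 1..k by first
# appearance in column-major order
.filter_relabel <- function(lab, min_px) {
  if (max(lab) == 0) return(lab)
  cnt <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(cnt >= max(min_px, 1))
  remap <- integer(max(lab))
  remap[keep] <- match(keep, keep)
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Label image
#'
#' Non-negative integer raster (0 = background) on the channel grid, with
#' labels consecutive from 1 and pixel size attached.
#' @param labels integer matrix.
#' @param pixel_size_um pixel pitch.
#' @return object of class `"label_image"`.
#' @export
label_image <- function(labels, pixel_size_um) {
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("label_image: %d x %d px, %d objects\n",
              nrow(x$labels), ncol(x$labels), max(x$labels)))
  invisible(x)
}

# Sobel gradient magnitude of an [x,y] matrix
.sobel_mag <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(EBImage::Image(m), kx)
  gy <- EBImage::filter2(EBImage::Image(m), t(kx))
  sqrt(imageData(gx)^2 + imageData(gy)^2)
}

#' Segment droplets from the blue channel
#'
#' Follows the intensity-plus-gradient scheme: Gaussian smoothing, a mask of
#' pixels above the intensity threshold (droplet interiors are brighter than
#' background), a mask of pixels above the gradient-magnitude threshold (the
#' gradient peaks at the droplet periphery), the union of the two masks, hole
#' filling within connected components, and removal of components smaller
#' than `min_droplet_area_um2`.
#'
#' @param blue numeric matrix (blue channel, `[x, y]`).
#' @param cfg a [segmentation_config()].
#' @param pixel_size_um pixel pitch, um/px.
#' @return a [label_image()] of 8-connected droplet labels.
#' @export
segment_droplets <- function(blue, cfg = segmentation_config(),
                             pixel_size_um) {
  stopifnot(is.matrix(blue), all(is.finite(blue)), length(blue) > 0)
  g <- if (cfg$gaussian_sigma_px > 0)
    imageData(EBImage::gblur(EBImage::Image(blue), cfg$gaussian_sigma_px))
  else blue
  thr_i <- .resolve_threshold(g, cfg$intensity_threshold)
  mask_i <- if (is.na(thr_i)) matrix(FALSE, nrow(g), ncol(g)) else g >= thr_i
  grad <- .sobel_mag(g)
  thr_g <- .resolve_threshold(grad, cfg$gradient_threshold)
  mask_g <- if (is.na(thr_g)) matrix(FALSE, nrow(g), ncol(g)) else grad >= thr_g
  mask <- mask_i | mask_g
  if (cfg$fill_holes) {
    filled <- EBImage::fillHull(EBImage::Image(mask * 1))
    mask <- matrix(imageData(filled) > 0, nrow(mask), ncol(mask))
  }
  lab <- label_components(mask)
  lab <- .filter_relabel(lab, cfg$min_droplet_area_um2 / pixel_size_um^2)
  label_image(lab, pixel_size_um)
}

#' Segment live and dead cells from the green and red channels
#'
#' Histogram-based per-channel thresholds produce a live (green) and a dead
#' (red) binary mask. A pixel above both thresholds is resolved by the ratio
#' rule: it is assigned to the channel with the larger background-normalized
#' intensity (intensity divided by the channel median). Components smaller
#' than `min_cell_area_um2` are removed from each mask.
#'
#' @param green,red numeric matrices of identical dimensions.
#' @param cfg a [segmentation_config()].
#' @param pixel_size_um pixel pitch, um/px.
#' @return list with logical matrices `live` and `dead` (disjoint).
#' @export
segment_cells <- function(green, red, cfg = segmentation_config(),
                          pixel_size_um) {
  if (!identical(dim(green), dim(red)))
    stop("segment_cells: green is ", paste(dim(green), collapse = "x"),
         " but red is ", paste(dim(red), collapse = "x"))
  smooth <- function(m) if (cfg$gaussian_sigma_px > 0)
    imageData(EBImage::gblur(EBImage::Image(m), cfg$gaussian_sigma_px)) else m
  gg <- smooth(green); rr <- smooth(red)
  thr_g <- .resolve_threshold(gg, cfg$cell_threshold)
  thr_r <- .resolve_threshold(rr, cfg$cell_threshold)
  live <- if (is.na(thr_g)) matrix(FALSE, nrow(gg), ncol(gg)) else gg >= thr_g
  dead <- if (is.na(thr_r)) matrix(FALSE, nrow(rr), ncol(rr)) else rr >= thr_r
  both <- live & dead
  if (any(both)) {
    norm_g <- gg / max(stats::median(gg), .Machine$double.eps)
    norm_r <- rr / max(stats::median(rr), .Machine$double.eps)
    take_live <- norm_g >= norm_r
    live[both] <- take_live[both]
    dead[both] <- !take_live[both]
  }
  min_px <- cfg$min_cell_area_um2 / pixel_size_um^2
  clean <- function(m) .filter_relabel(label_components(m), min_px) > 0
  list(live = clean(live), dead = clean(dead))
}
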