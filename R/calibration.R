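#' Build a fluorescence calibration curve
#'
#' Monotone piecewise-linear interpolant through (concentration, intensity)
#' knots, built from standards of known concentration imaged at fixed
#' acquisition settings. Concentrations are expressed in multiples of the
#' reference medium. Construction fails if intensities are not strictly
#' increasing with concentration — a non-monotone curve has no well-defined
#' inverse.
#'
#' @param pairs data frame or 2-column matrix: concentration, intensity.
#' @param solute free-text tag (e.g. "M9", "NaCl").
#' @return object of class `"calibration_curve"`.
#' @examples
#' cal <- build_calibration(data.frame(conc = c(0.05, 0.1, 0.2, 0.5, 1),
#'                                     intensity = c(10, 22, 45, 110, 230)))
#' estimate_concentration(45, cal)
#' @export
build_calibration <- function(pairs, solute = "") {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2 || nrow(pairs) < 2)
    stop("build_calibration: need >= 2 (concentration, intensity) pairs")
  conc <- pairs[[1]]; int <- pairs[[2]]
  o <- order(conc)
  conc <- conc[o]; int <- int[o]
  if (any(diff(conc) <= 0))
    stop("build_calibration: duplicate concentrations at knots ",
         paste(which(diff(conc) <= 0), collapse = ", "))
  bad <- which(diff(int) <= 0)
  if (length(bad))
    stop("build_calibration: intensities not strictly increasing between ",
         "knots ", paste(sprintf("%d-%d", bad, bad + 1), collapse = ", "),
         " (concentrations ",
         paste(sprintf("%g-%g", conc[bad], conc[bad + 1]), collapse = ", "),
         ")")
  structure(list(concentration = conc, intensity = int, solute = solute),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve%s: %d knots, conc %g..%g, intensity %g..%g\n",
              if (nzchar(x$solute)) paste0(" [", x$solute, "]") else "",
              length(x$concentration), min(x$concentration),
              max(x$concentration), min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Dilution-series helper
#'
#' Concentrations of a standard dilution series: a stock at `stock_conc`
#' diluted by each factor. The conventional factors for a ten-point series
#' are 1.11, 1.25, 1.43, 1.6, 2, 2.5, 3.33, 5, 10 and 20.
#'
#' @param stock_conc stock concentration (multiples of reference).
#' @param factors dilution factors.
#' @return numeric vector of concentrations, increasing.
#' @export
dilution_series <- function(stock_conc = 100,
                            factors = c(1.11, 1.25, 1.43, 1.6, 2, 2.5, 3.33,
                                        5, 10, 20)) {
  sort(stock_conc / factors)
}

#' Mean droplet intensity with boundary and bead exclusion
#'
#' Mean intensity over one droplet's pixels after eroding the droplet mask
#' by `ceil(boundary_width_um / pixel_size_um)` pixels (disc structuring
#' element) and removing bead pixels. Excluding an approximately 1 um-wide
#' boundary avoids edge artifacts from the curved droplet surface.
#'
#' @param image numeric matrix.
#' @param droplets a [label_image()].
#' @param droplet_id which droplet to measure.
#' @param bead_mask logical matrix of bead pixels, or NULL.
#' @param boundary_width_um excluded rim width, um (default 1).
#' @return mean intensity (camera units).
#' @export
droplet_mean_intensity <- function(image, droplets, droplet_id,
                                   bead_mask = NULL, boundary_width_um = 1) {
  mask <- droplets$labels == droplet_id
  if (!any(mask))
    stop("droplet_mean_intensity: droplet ", droplet_id, " has no pixels")
  r_px <- ceiling(boundary_width_um / droplets$pixel_size_um)
  if (r_px > 0) {
    brush <- EBImage::makeBrush(2 * r_px + 1, shape = "disc")
    mask <- imageData(EBImage::erode(EBImage::Image(mask * 1), brush)) > 0
  }
  if (!is.null(bead_mask)) mask <- mask & !bead_mask
  if (!any(mask))
    stop("droplet_mean_intensity: droplet ", droplet_id,
         " has no pixels left after boundary/bead exclusion ",
         "(too small to measure)")
  mean(image[mask])
}

#' Estimate concentration from intensity
#'
#' Inverse piecewise-linear lookup on a [build_calibration()] curve.
#' Intensities outside the knot range are linearly extrapolated from the
#' terminal segment and flagged.
#'
#' @param intensity camera units (vectorized).
#' @param curve a `calibration_curve`.
#' @param droplet_id optional id column for the result.
#' @return data frame: `droplet_id`, `mean_intensity`, `concentration`,
#'   `extrapolated`.
#' @export
estimate_concentration <- function(intensity, curve,
                                   droplet_id = seq_along(intensity)) {
  stopifnot(inherits(curve, "calibration_curve"))
  int <- curve$intensity; conc <- curve$concentration
  n <- length(int)
  conc_of <- function(i) {
    if (i <= int[1]) {
      s <- (conc[2] - conc[1]) / (int[2] - int[1])
      conc[1] + s * (i - int[1])
    } else if (i >= int[n]) {
      s <- (conc[n] - conc[n - 1]) / (int[n] - int[n - 1])
      conc[n] + s * (i - int[n])
    } else {
      stats::approx(int, conc, xout = i)$y
    }
  }
  data.frame(droplet_id = droplet_id,
             mean_intensity = intensity,
             concentration = vapply(intensity, conc_of, 1),
             extrapolated = intensity < int[1] | intensity > int[n])
}

#' Summarize concentration estimates
#'
#' Mean and sample SD of the estimated concentration factors relative to the
#' reference medium, plus the factor relative to the starting dilution of
#' the experiment (e.g. droplets at 23.3x the reference that started from a
#' 0.5x dilution are 46.6x more concentrated than the initial medium).
#'
#' @param estimates data frame from [estimate_concentration()], or a numeric
#'   vector of factors.
#' @param reference_dilution starting dilution in multiples of the reference
#'   (default 0.5).
#' @return list: `mean_factor`, `sd`, `n`, `factor_vs_start`.
#' @export
concentration_summary <- function(estimates, reference_dilution = 0.5) {
  x <- if (is.data.frame(estimates)) estimates$concentration else estimates
  if (length(x) < 1) stop("concentration_summary: no estimates")
  m <- mean(x)
  list(mean_factor = m,
       sd = if (length(x) > 1) stats::sd(x) else 0,
       n = length(x),
       factor_vs_start = m / reference_dilution)
}

#' Osmolarity helper
#'
#' Converts a concentration factor to an osmolarity given a user-supplied
#' base osmolarity of the reference medium. No default base is provided:
#' the osmolarity of a growth medium depends on its full recipe and
#' dissociation assumptions, which must come from the user.
#'
#' @param factor concentration factor relative to the reference.
#' @param base_osm_per_l osmolarity of the reference medium, Osm/L.
#' @return osmolarity, Osm/L.
#' @export
osmolarity_from_factor <- function(factor, base_osm_per_l) {
  if (missing(base_osm_per_l))
    stop("osmolarity_from_factor: supply base_osm_per_l explicitly")
  factor * base_osm_per_l
}
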