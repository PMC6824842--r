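#' Logarithmic bin specification
#'
#' Bins for droplet or aggregate areas, evenly spaced on a log10 scale.
#' Either pass explicit `edges` (strictly increasing, >= 2 values) or a rule
#' (`n` bins between `lo` and `hi`). The default droplet binning subdivides
#' each decade from 1 to 1e5 um^2 in two.
#'
#' @param edges strictly increasing numeric vector of bin edges (um^2).
#' @param lo,hi,n rule: `n` bins log-evenly spaced on `[lo, hi]`.
#' @return object of class `"bin_spec"` (numeric edges vector).
#' @export
bin_spec <- function(edges = NULL, lo = 1, hi = 1e5, n = 10) {
  if (is.null(edges)) edges <- 10^seq(log10(lo), log10(hi), length.out = n + 1)
  if (length(edges) < 2 || any(diff(edges) <= 0))
    stop("bin_spec: edges must be strictly increasing with at least 2 values")
  structure(edges, class = "bin_spec")
}

default_droplet_bins <- function() bin_spec(lo = 1, hi = 1e5, n = 10)

.bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1 | i > length(edges) - 1] <- NA_integer_
  i
}

.bin_centers <- function(edges) sqrt(edges[-1] * edges[-length(edges)])

.sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else
  if (length(v) == 1) 0 else NA_real_

#' Binned mean curve
#'
#' Per-bin mean and standard error of `y`, binned by `x` on the log scale.
#' Empty bins are reported with `n = 0` and `NA` mean — never dropped or
#' interpolated. SEM is over the individual observations in the bin.
#'
#' @param x binning variable (areas, um^2).
#' @param y values to average.
#' @param bins a [bin_spec()].
#' @return data frame of class `"binned_curve"`: `bin_lo`, `bin_hi`,
#'   `bin_center` (geometric mean of edges), `mean`, `sem`, `n`.
#' @export
binned_mean_curve <- function(x, y, bins = default_droplet_bins()) {
  if (length(x) != length(y))
    stop("binned_mean_curve: x has length ", length(x), " but y has ",
         length(y))
  edges <- unclass(bins)
  idx <- .bin_index(x, edges)
  k <- length(edges) - 1
  mean_v <- sem_v <- rep(NA_real_, k)
  n_v <- integer(k)
  for (b in seq_len(k)) {
    v <- y[!is.na(idx) & idx == b]
    n_v[b] <- length(v)
    if (length(v)) { mean_v[b] <- mean(v); sem_v[b] <- .sem(v) }
  }
  structure(data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                       bin_center = .bin_centers(edges),
                       mean = mean_v, sem = sem_v, n = n_v),
            class = c("binned_curve", "data.frame"))
}

#' Droplet-size distribution per unit surface area
#'
#' Counts droplets per size bin, normalized by the scanned surface area
#' (per mm^2). With several fields of view ('repeat'), per-field densities
#' are computed on each field's share of the scanned area and the mean and
#' SEM across fields are reported; with a single field SEM is 0 in occupied
#' bins.
#'
#' @param records droplet record data frame (needs `area_um2`, `field_id`).
#' @param scanned_area_mm2 total scanned surface area, mm^2 (all fields).
#' @param bins a [bin_spec()].
#' @return data frame: `bin_lo`, `bin_hi`, `bin_center`,
#'   `count_per_mm2` (mean across fields), `sem`, `n_fields`.
#' @export
size_distribution <- function(records, scanned_area_mm2,
                              bins = default_droplet_bins()) {
  if (!(scanned_area_mm2 > 0)) stop("size_distribution: scanned_area_mm2 <= 0")
  edges <- unclass(bins)
  k <- length(edges) - 1
  fields <- unique(records$field_id)
  if (length(fields) == 0) fields <- "1"
  per_field_area <- scanned_area_mm2 / length(fields)
  dens <- matrix(0, length(fields), k)
  for (f in seq_along(fields)) {
    a <- records$area_um2[records$field_id == fields[f]]
    idx <- .bin_index(a, edges)
    dens[f, ] <- tabulate(idx[!is.na(idx)], nbins = k) / per_field_area
  }
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             bin_center = .bin_centers(edges),
             count_per_mm2 = colMeans(dens),
             sem = apply(dens, 2, .sem),
             n_fields = length(fields))
}

#' Survival as a function of droplet size
#'
#' Per-droplet survival is `live_area / (live_area + dead_area)`; droplets
#' with no cells are excluded. By default the curve is the per-droplet mean
#' (each droplet one observation) with SEM over droplets in the bin;
#' `pooled = TRUE` instead pools areas within each bin
#' (`sum(live) / sum(live + dead)`).
#'
#' @param records droplet record data frame (`area_um2`, `live_area_um2`,
#'   `dead_area_um2`).
#' @param bins a [bin_spec()].
#' @param pooled pool areas within bins instead of averaging droplets.
#' @return a `binned_curve` data frame.
#' @export
survival_vs_droplet_size <- function(records, bins = default_droplet_bins(),
                                     pooled = FALSE) {
  cellular <- records$live_area_um2 + records$dead_area_um2 > 0
  if (!any(cellular)) {
    warning("survival_vs_droplet_size: no droplets with cells")
    return(binned_mean_curve(numeric(0), numeric(0), bins))
  }
  r <- records[cellular, ]
  if (!pooled) {
    surv <- r$live_area_um2 / (r$live_area_um2 + r$dead_area_um2)
    return(binned_mean_curve(r$area_um2, surv, bins))
  }
  edges <- unclass(bins)
  idx <- .bin_index(r$area_um2, edges)
  k <- length(edges) - 1
  mean_v <- rep(NA_real_, k); n_v <- integer(k)
  for (b in seq_len(k)) {
    s <- !is.na(idx) & idx == b
    n_v[b] <- sum(s)
    tot <- sum(r$live_area_um2[s]) + sum(r$dead_area_um2[s])
    if (tot > 0) mean_v[b] <- sum(r$live_area_um2[s]) / tot
  }
  structure(data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                       bin_center = .bin_centers(edges), mean = mean_v,
                       sem = NA_real_, n = n_v),
            class = c("binned_curve", "data.frame"))
}

#' Live/dead population distribution over droplet size
#'
#' Sums live and dead cell areas per droplet-size bin, normalized per mm^2
#' of scanned surface. The grand total across bins (plus any dry objects,
#' which carry no droplet and are excluded here) equals the total cell area.
#'
#' @param records droplet record data frame.
#' @param bins a [bin_spec()].
#' @param scanned_area_mm2 normalizing area; 1 reports raw um^2 totals.
#' @return data frame: `bin_lo`, `bin_hi`, `bin_center`, `live_area_per_mm2`,
#'   `dead_area_per_mm2`, `n_droplets`.
#' @export
population_by_droplet_size <- function(records, bins = default_droplet_bins(),
                                       scanned_area_mm2 = 1) {
  edges <- unclass(bins)
  idx <- .bin_index(records$area_um2, edges)
  k <- length(edges) - 1
  live <- dead <- numeric(k); n <- integer(k)
  for (b in seq_len(k)) {
    s <- !is.na(idx) & idx == b
    live[b] <- sum(records$live_area_um2[s]) / scanned_area_mm2
    dead[b] <- sum(records$dead_area_um2[s]) / scanned_area_mm2
    n[b] <- sum(s)
  }
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             bin_center = .bin_centers(edges),
             live_area_per_mm2 = live, dead_area_per_mm2 = dead,
             n_droplets = n)
}

#' Mean object survival over droplet-size x aggregate-size bins
#'
#' For each (droplet-size, aggregate-size) bin, the mean and SEM of the
#' survival rates of the cellular objects falling in it. Objects without a
#' host droplet or without cells are excluded.
#'
#' @param objects aggregate record data frame (`area_um2`,
#'   `host_droplet_area_um2`, `survival_rate`).
#' @param droplet_bins,aggregate_bins [bin_spec()]s.
#' @return data frame in long form: `droplet_bin_center`,
#'   `aggregate_bin_center`, `mean_survival`, `sem`, `n`.
#' @export
survival_2d <- function(objects, droplet_bins = default_droplet_bins(),
                        aggregate_bins = bin_spec(lo = 10^-0.5, hi = 1e4,
                                                  n = 9)) {
  de <- unclass(droplet_bins); ae <- unclass(aggregate_bins)
  r <- objects[!is.na(objects$host_droplet_area_um2) &
                 !is.na(objects$survival_rate), ]
  di <- .bin_index(r$host_droplet_area_um2, de)
  ai <- .bin_index(r$area_um2, ae)
  dc <- .bin_centers(de); ac <- .bin_centers(ae)
  grid <- expand.grid(d = seq_along(dc), a = seq_along(ac))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    s <- !is.na(di) & !is.na(ai) & di == grid$d[i] & ai == grid$a[i]
    v <- r$survival_rate[s]
    data.frame(droplet_bin_center = dc[grid$d[i]],
               aggregate_bin_center = ac[grid$a[i]],
               mean_survival = if (length(v)) mean(v) else NA_real_,
               sem = .sem(v), n = length(v))
  })
  do.call(rbind, res)
}

#' Relative contribution of droplet and aggregate size to survival
#'
#' Logistic regression of per-object live vs dead outcome (events weighted
#' by cell area) on standardized log10 droplet area and standardized log10
#' aggregate area. Because both predictors are standardized, the absolute
#' coefficient magnitudes are directly comparable: the larger one carries
#' more weight for survival. Perfect separation (exploding coefficients) is
#' flagged and the model refit with a small ridge penalty.
#'
#' @param objects aggregate record data frame; rows with cells and a host
#'   droplet are used.
#' @return object of class `"contribution_model"`: list with `coefficients`
#'   (droplet, aggregate), `stderr`, `ci` (95%), `dominant` ("droplet" or
#'   "aggregate"), `separation` flag, `n`.
#' @export
fit_contribution <- function(objects) {
  r <- objects[!is.na(objects$host_droplet_area_um2) &
                 objects$live_area_um2 + objects$dead_area_um2 > 0, ]
  if (nrow(r) < 2) stop("fit_contribution: fewer than 2 usable objects")
  ld <- log10(r$host_droplet_area_um2)
  la <- log10(r$area_um2)
  if (stats::sd(ld) == 0 || stats::sd(la) == 0)
    stop("fit_contribution: degenerate predictor (no variation)")
  zd <- (ld - mean(ld)) / stats::sd(ld)
  za <- (la - mean(la)) / stats::sd(la)
  w <- r$live_area_um2 + r$dead_area_um2
  y <- r$live_area_um2 / w
  fit <- suppressWarnings(stats::glm(y ~ zd + za, weights = w,
                                     family = stats::quasibinomial()))
  co <- summary(fit)$coefficients
  separation <- !fit$converged || any(abs(co[-1, 1]) > 15)
  if (separation) {
    pen <- glmnet::glmnet(cbind(zd = zd, za = za), y, family = "binomial",
                          weights = w, alpha = 0, lambda = 1e-3,
                          standardize = FALSE)
    beta <- as.numeric(pen$beta)
    coefs <- c(droplet = beta[1], aggregate = beta[2])
    se <- c(droplet = NA_real_, aggregate = NA_real_)
  } else {
    coefs <- c(droplet = co["zd", 1], aggregate = co["za", 1])
    se <- c(droplet = co["zd", 2], aggregate = co["za", 2])
  }
  ci <- cbind(lo = coefs - 1.96 * se, hi = coefs + 1.96 * se)
  structure(list(coefficients = coefs, stderr = se, ci = ci,
                 dominant = names(coefs)[which.max(abs(coefs))],
                 separation = separation, n = nrow(r)),
            class = "contribution_model")
}

#' @export
print.contribution_model <- function(x, ...) {
  cat(sprintf(paste0("contribution_model (n = %d%s):\n",
                     "  droplet size:   %+.3f +/- %.3f\n",
                     "  aggregate size: %+.3f +/- %.3f\n",
                     "  dominant: %s size\n"),
              x$n, if (x$separation) ", separation-regularized" else "",
              x$coefficients["droplet"], x$stderr["droplet"],
              x$coefficients["aggregate"], x$stderr["aggregate"], x$dominant))
  invisible(x)
}

#' Fraction of the population above a droplet size
#'
#' For each threshold, the ratio of cell area residing in droplets at least
#' that large to the total cell area in droplets. Default thresholds: 100
#' log-spaced values from 10^1.5 um^2 to the maximal droplet area.
#'
#' @param records droplet record data frame.
#' @param thresholds droplet-area thresholds, um^2.
#' @return data frame: `threshold_um2`, `fraction_above` (non-increasing).
#' @export
population_above_size <- function(records, thresholds = NULL) {
  total <- sum(records$cell_area_um2)
  if (!(total > 0)) stop("population_above_size: total cell area is zero")
  if (is.null(thresholds))
    thresholds <- 10^seq(1.5, log10(max(records$area_um2)), length.out = 100)
  frac <- vapply(thresholds, function(th)
    sum(records$cell_area_um2[records$area_um2 >= th]) / total, 1)
  data.frame(threshold_um2 = thresholds, fraction_above = frac)
}

#' Overall survival
#'
#' Pooled `sum(live) / sum(live + dead)` over all records (droplets and, if
#' included in the table, dry objects).
#'
#' @param records data frame with `live_area_um2` and `dead_area_um2`.
#' @return fraction in `[0, 1]`.
#' @export
overall_survival <- function(records) {
  tot <- sum(records$live_area_um2) + sum(records$dead_area_um2)
  if (!(tot > 0)) stop("overall_survival: no cell area in records")
  sum(records$live_area_um2) / tot
}
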