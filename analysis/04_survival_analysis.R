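#!/usr/bin/env Rscript
# Survival statistics on the pooled records from 02: survival vs droplet
# size, live/dead population distribution, survival over droplet x
# aggregate size, the contribution model, and the population-above-size
# curve. Outputs under results/survival/.

library(dropsurv)

rec <- read.csv(file.path("results", "records", "droplet_records.csv"))
obj <- read.csv(file.path("results", "records", "aggregate_records.csv"))
out <- file.path("results", "survival")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

bins <- bin_spec(lo = 10, hi = 3000, n = 5)

surv <- survival_vs_droplet_size(rec, bins)
write.csv(surv, file.path(out, "survival_vs_size.csv"), row.names = FALSE)
occ <- surv$n > 0
message("per-droplet mean survival by size bin:")
for (i in which(occ))
  message(sprintf("  %7.0f um^2: %.3f +/- %.3f (n=%d)", surv$bin_center[i],
                  surv$mean[i], surv$sem[i], surv$n[i]))

pop <- population_by_droplet_size(rec, bins,
                                  scanned_area_mm2 = 5 * 0.3328^2)
write.csv(pop, file.path(out, "population_by_size.csv"), row.names = FALSE)

grid <- survival_2d(obj, droplet_bins = bins,
                    aggregate_bins = bin_spec(lo = 0.5, hi = 300, n = 6))
write.csv(grid, file.path(out, "survival_2d.csv"), row.names = FALSE)

fit <- fit_contribution(obj)
print(fit)
write.csv(data.frame(predictor = names(fit$coefficients),
                     coefficient = fit$coefficients, stderr = fit$stderr),
          file.path(out, "contribution_model.csv"), row.names = FALSE)

above <- population_above_size(rec)
write.csv(above, file.path(out, "population_above_size.csv"),
          row.names = FALSE)

message(sprintf("overall survival (pooled live area fraction): %.1f%%",
                100 * overall_survival(rec)))
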