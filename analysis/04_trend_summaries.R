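#!/usr/bin/env Rscript
# Stage 4 — turn the fitted parameters into the quantities a conservation
# reader needs: percentage declines by latitude (annual and over the full
# window), the equal-cell-weight flyway mean trend, typical cross-cell and
# cross-site ranges of annual decline, the intercept-slope correlation, the
# expected trajectories with nested interval bands, and residual/normality
# diagnostics.

suppressPackageStartupMessages(library(gridtrend))
outdir <- "results/analysis"

tab <- read_counts(file.path(outdir, "counts.csv"))
tab <- filter_by_coverage(tab, 7)
tab <- center_years(tab, 2007)
tab <- project_coordinates(tab, "ETRS89-LAEA")
asn <- assign_sites(tab, build_grid(tab, 75000))
fit <- fit_hierarchical(tab, asn)

lats <- c(46, 60)
summ <- do.call(rbind, lapply(lats, function(L) {
  data.frame(latitude = L,
             annual_pct = percent_change(fit$coef["beta0"], fit$coef["gamma"],
                                         L, D = 1),
             annual_se = percent_change_se(fit, L, 1),
             total_pct = percent_change(fit$coef["beta0"], fit$coef["gamma"],
                                        L, D = 11),
             total_se = percent_change_se(fit, L, 11),
             cell_lo = typical_range(fit, L, "cell")[1],
             cell_hi = typical_range(fit, L, "cell")[2],
             site_lo = typical_range(fit, L, "site")[1],
             site_hi = typical_range(fit, L, "site")[2])
}))
rownames(summ) <- NULL
print(round(summ, 2))

fw <- flyway_mean_trend(fit, asn, D = 11)
cat(sprintf("flyway mean: %.1f%%/yr (SE %.1f), total %.1f%% (SE %.1f) over 11 yrs\n",
            fw$annual_pct, fw$annual_se, fw$total_pct, fw$total_se))
cat(sprintf("intercept-slope correlation: R = %.4f\n",
            intercept_slope_correlation(fit)))

traj <- do.call(rbind, lapply(c(46, 50, 55, 60), function(L)
  cbind(latitude = L, expected_trajectory(fit, L, 2002:2012))))
diag <- residual_diagnostics(fit)
print(diag)

write.csv(summ, file.path(outdir, "decline_by_latitude.csv"), row.names = FALSE)
write.csv(traj, file.path(outdir, "trajectory_bands.csv"), row.names = FALSE)
jsonlite::write_json(list(flyway = fw,
                          correlation = intercept_slope_correlation(fit),
                          normality = diag$normality,
                          by_year = diag$by_year),
                     file.path(outdir, "summaries.json"),
                     auto_unbox = TRUE, digits = 10, force = TRUE)
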