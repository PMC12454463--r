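#!/usr/bin/env Rscript
# Cohort tables from the per-acquisition ROI statistics: per-metric cohort
# medians/IQR (repeats averaged within subject), Bland-Altman repeatability
# with the RMS coefficient of repeatability, and inter-reader ICC(2,1).
# Writes results/cohort.csv, results/repeatability.csv,
# results/agreement.csv.
#
# Run analysis/02_fit_maps.R first.

suppressPackageStartupMessages(library(pancdki))

stats_files <- Sys.glob(file.path("results", "*_roi_stats.csv"))
if (length(stats_files) == 0) stop("run analysis/02_fit_maps.R first")
roi_stats <- do.call(rbind, lapply(stats_files, read.csv))

r1 <- roi_stats[roi_stats$reader == "reader1", ]
cohort <- summarize_cohort(data.frame(subject = r1$subject,
                                      metric = r1$map_name,
                                      value = r1$median,
                                      protocol = r1$protocol))
write.csv(cohort, "results/cohort.csv", row.names = FALSE)

rep_rows <- list(); agr_rows <- list()
for (p in unique(roi_stats$protocol)) {
  for (m in unique(roi_stats$map_name)) {
    d <- r1[r1$protocol == p & r1$map_name == m, ]
    w <- reshape(d[, c("subject", "repeat_idx", "median")],
                 direction = "wide", idvar = "subject", timevar = "repeat_idx")
    cc <- w[complete.cases(w), ]
    if (nrow(cc) >= 2 && ncol(cc) >= 3) {
      ba <- bland_altman(cc[[2]], cc[[3]])
      rep_rows[[paste(p, m)]] <- data.frame(
        protocol = p, metric = m, n = ba$n, mean_diff = ba$mean_diff,
        loa_low = ba$loa_low, loa_high = ba$loa_high, r = ba$r)
    }
    d2 <- roi_stats[roi_stats$protocol == p & roi_stats$map_name == m, ]
    per <- aggregate(median ~ subject + reader, data = d2, FUN = mean)
    w2 <- reshape(per, direction = "wide", idvar = "subject",
                  timevar = "reader")
    cc2 <- w2[complete.cases(w2), -1, drop = FALSE]
    if (nrow(cc2) >= 3 && ncol(cc2) >= 2) {
      icc <- icc_absolute_agreement(cc2)
      agr_rows[[paste(p, m)]] <- data.frame(protocol = p, metric = m,
                                            icc = icc$icc,
                                            band = icc$icc_band)
    }
  }
}
repeatability <- do.call(rbind, rep_rows); rownames(repeatability) <- NULL
agreement <- do.call(rbind, agr_rows); rownames(agreement) <- NULL
write.csv(repeatability, "results/repeatability.csv", row.names = FALSE)
write.csv(agreement, "results/agreement.csv", row.names = FALSE)

cat("cohort medians (repeats averaged within subject):\n")
print(cohort, digits = 4)
cat("\nrepeatability coefficients (r = 1.96*sqrt(sum(d^2)/n)):\n")
print(repeatability[, c("protocol", "metric", "r")], digits = 3)
cat("\ninter-reader ICC(2,1):\n")
print(agreement, digits = 4)
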