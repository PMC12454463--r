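#!/usr/bin/env Rscript
# Slice-thickness / SNR trade-off for mean-kurtosis precision: with all
# other acquisition parameters fixed, SNR is proportional to slice
# thickness, and first-order error propagation through the three-shell
# mean-signal DKI fit predicts sd(MK) ~ 1/SNR. Going from 3 mm to 5 mm
# slices therefore predicts a 40% reduction in MK estimation error.
# Monte-Carlo check at the study's acquisition conditions; writes
# results/snr_scaling.csv.

suppressPackageStartupMessages(library(pancdki))

rows <- lapply(1:5, function(seed) {
  r <- snr_scaling_experiment(snr_base = 30, thickness_ratio = 5 / 3,
                              n_voxels = 10000L, seed = seed)
  data.frame(seed = seed, snr_base = r$snr_base, snr_scaled = r$snr_scaled,
             sd_mk_base = r$sd_mk_base, sd_mk_scaled = r$sd_mk_scaled,
             percent_reduction = r$percent_reduction)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/snr_scaling.csv", row.names = FALSE)
print(tab, digits = 4)
cat(sprintf("\nmean reduction over seeds: %.1f%% (first-order prediction: %.0f%%)\n",
            mean(tab$percent_reduction),
            snr_scaling_experiment(n_voxels = 1000L)$theoretical_reduction))
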