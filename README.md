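# pancdki

Diffusion tensor (DTI) and mean-signal diffusion kurtosis (MS-DKI) analysis
for pancreatic diffusion-weighted MRI, built for protocol-comparison and
test–retest repeatability studies.

Abdominal DTI/DKI is hard: low SNR at 3 mm slices, perfusion contamination
at low b-values, Gibbs ringing at sharp fat/tissue edges, and kurtosis
estimates that are notoriously noise-sensitive. This package implements the
full measurement chain as a tested pipeline —

1. **Preprocessing** — Marchenko–Pastur PCA denoising (random-matrix
   classification of the per-window PCA spectrum) and Gibbs unringing by
   local subvoxel shifts.
2. **DTI** — per-voxel weighted-least-squares fit of
   `log S(b, g) = log S0' − b gᵀDg` on the b = 200/1000 s/mm² shells only,
   which suppresses IVIM perfusion effects; eigenvalues λ₁ ≥ λ₂ ≥ λ₃ give
   MD = (λ₁+λ₂+λ₃)/3, AD = λ₁, RD = (λ₂+λ₃)/2 and
   FA = √( 3/2 · Σ(λᵢ−MD)² / Σλᵢ² ).
3. **MS-DKI** — directional averaging per shell, then the mean-signal
   kurtosis model `MS(b) ≈ S0 · exp(−b·MD + (1/6)·b²·MD²·MK)` fitted by
   weighted linear least squares on b = 200/1000/1700 s/mm².
4. **ADC** — clinical two-point monoexponential fit on the first diffusion
   direction, `ADC = ln(S₂₀₀/S₁₀₀₀)/800`.
5. **Quality control** — per-map plausibility masks (negative diffusivity or
   kurtosis, MK > 2.5, FA > 1, diffusivity above the free-water ceiling) and
   whole-pancreas ROI statistics (median, IQR, 10th/90th percentiles,
   excluded-voxel fractions).
6. **Repeatability & agreement** — Bland–Altman limits of agreement, the RMS
   coefficient of repeatability `r = 1.96·√(Σd²/n)`, two-way random
   absolute-agreement ICC(2,1) with conventional interpretation bands, and
   quadratically weighted kappa for ordinal quality scores.
7. **Synthetic phantom** — a pancreas-like crescent with a rotating
   principal diffusion axis, sampled with the study acquisition (6 slices,
   3 mm isotropic, b = 0/200/1000/1700 with 2/4/5 signal averages, 6 or 16
   evenly spread directions, Rician noise, optional IVIM perfusion
   fraction and between-subject variability), so every stage is verifiable
   by parameter recovery.

## Worked example

Simulate a small three-subject test–retest study and run the pipeline
(preprocessing disabled here for speed):

```r
library(pancdki)
spec <- phantom_spec(grid = c(24, 24, 6), n_subjects = 3, n_repeats = 2,
                     subject_cv = 0.08, snr = 30)
out <- run_full_pipeline(pipeline_config(input = spec,
                                         preprocess = list(enabled = FALSE)))
subset(out$cohort, metric %in% c("md", "fa", "mk"))
#>   protocol metric n_subjects   median      iqr      min      max
#> 3     6dir     fa          3 0.203952 8.20e-02 0.197013 0.360974
#> 4     6dir     md          3 0.000878 3.09e-05 0.000847 0.000908
#> 5     6dir     mk          3 0.746451 6.26e-02 0.630216 0.755328
```

The cohort table gives per-metric medians over subjects (repeats averaged
within subject); MD is in mm²/s (0.000878 = 0.878 ×10⁻³ mm²/s), FA and MK
are dimensionless. Repeatability per metric, from the per-subject
differences between the two acquisitions:

```r
out$repeatability[out$repeatability$metric %in% c("md", "mk"),
                  c("metric", "n", "mean_diff", "r")]
#>   metric n mean_diff        r
#> 1     md 3  1.57e-06 3.60e-06
#> 5     mk 3 -9.75e-03 2.41e-02
```

The coefficient of repeatability `r` of MK is orders of magnitude larger
than that of MD relative to their medians — kurtosis is the noise-limited
quantity, which is exactly what motivates the SNR experiment:

```r
res <- snr_scaling_experiment(snr_base = 30, thickness_ratio = 5/3,
                              n_voxels = 10000, seed = 1)
#> sd(MK) at SNR 30: 0.153; at SNR 50: 0.089; reduction 41.7%
```

Raising SNR by the 5 mm / 3 mm slice-thickness ratio shrinks the MK
estimation spread by ≈40%, matching first-order error propagation
(sd(MK) ∝ 1/SNR).

## Study workflow

The numbered drivers under `analysis/` run the full study end to end and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate_study.R     # two-protocol phantom cohort to disk
Rscript analysis/02_fit_maps.R           # preprocess + fit + QC + ROI stats
Rscript analysis/03_cohort_statistics.R  # cohort, repeatability, ICC tables
Rscript analysis/04_snr_scaling.R        # slice-thickness / MK-precision table
```

Each accepts `--quick` for a reduced sanity run.

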