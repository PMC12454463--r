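---
title: "Methods: pancreatic DTI and mean-signal DKI at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pancreatic DTI and mean-signal DKI at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancdki)
```

## The measurement chain

This package models a two-protocol abdominal diffusion acquisition and the
quantitative analysis applied to it. A single acquisition is a 4-D signal
grid over 6 axial slices at 3 mm isotropic voxels, sampled at
b = 0, 200, 1000 and 1700 s/mm² with either 6 or 16 evenly spread diffusion
directions and 2/4/5 scanner signal averages on the weighted shells. Each
stage of the analysis is a pure function of its inputs and a configuration
object, so the whole chain is reproducible from a seed.

### Denoising

`mppca_denoise()` applies principal-component denoising with
Marchenko–Pastur classification: for each voxel, the surrounding
window-by-volume matrix (default 5×5×3 voxels, at least as many window
voxels as the 49 volumes of the 16-direction protocol while fitting the
6-slice stack) is eigen-decomposed, and the noise set is found by
iteratively shrinking the candidate set while its eigenvalue range exceeds
the Marchenko–Pastur bulk width implied by its own mean. Components inside
the bulk are suppressed and only the window's centre voxel is assigned —
the simplest contract, with no overlapping-window averaging. The per-voxel
noise level σ is the square root of the mean noise eigenvalue. With no
spatial redundancy (a 1×1×1 window) classification is impossible; the
routine warns and passes the data through. No Rician-bias correction is
applied after denoising.

Assumptions worth keeping in mind: the MP classification treats the noise
as homoscedastic within a window, while per-shell signal averaging (2/4/5
averages) makes the per-volume noise variance unequal. The estimated σ is
then an average across volumes, which is the expected behaviour, and the
pure-noise recovery test uses homoscedastic noise where σ is well defined.

### Gibbs unringing

`gibbs_unring()` removes truncation ringing slice by slice using subvoxel
shifts. The image is first split in k-space into two parts with the
standard smooth weighting `(1+cos k_y) / ((1+cos k_x) + (1+cos k_y))`, so
that each part rings along only one in-plane axis. Along that axis, 2·20+1
sub-voxel shifts (|t| ≤ 0.5 voxel) are evaluated through Fourier phase
ramps; per voxel, the shift minimising a one-sided finite-difference
oscillation measure (minimum of the left and right neighbourhoods over 3
voxels, excluding the voxel's own step so genuine edges are not penalised)
is selected, and the value is linearly interpolated back to the voxel
centre. The method assumes ringing at the acquisition grid's Nyquist
frequency; data interpolated to a finer grid before unringing will not be
corrected well.

### Perfusion-suppressed DTI

Blood microcirculation mimics fast pseudo-diffusion and inflates
diffusivity estimates when b = 0 enters the fit. The tensor is therefore
fitted on the b = 200 and 1000 s/mm² shells only; the intercept of the
log-linear model is a perfusion-suppressed baseline, not S0.
`fit_dti_wls()` initialises with ordinary least squares on the log-signal
and performs two re-weighted passes with weights equal to the squared
predicted signals — the standard weighting that makes log-domain least
squares approximate signal-domain least squares. Two passes are enough for
convergence at these SNRs (the suite checks agreement with a
Levenberg–Marquardt signal-domain fit to 1e-6 on noiseless tensors); the
pass count is configurable. A single-shell scheme leaves the intercept
collinear with the squared-direction columns, so two shells are a hard
requirement, enforced as a rank check on the design matrix.

Negative eigenvalues are deliberately not clamped at fit time: they are
diagnostic of noise and artefact, and the plausibility stage excludes them
per map. FA uses the standard definition
`FA = sqrt(3/2 · ((λ1−MD)² + (λ2−MD)² + (λ3−MD)²) / (λ1²+λ2²+λ3²))`;
note that any formulation that omits the λ1 deviation term cannot be
correct, since FA must vanish at isotropy.

### Mean-signal DKI and ADC

Kurtosis is estimated on the powder average: per shell, the per-voxel mean
signal over all directions. This sacrifices directional kurtosis
information for robustness — the average over directions has much higher
SNR than any single volume, which matters at 3 mm slices. The model
`MS(b) ≈ S0·exp(−b·MD + (1/6)·b²·MD²·MK)` is linear in
`(log S0, MD, MD²·MK/6)` after taking logs; with exactly three shells
(200/1000/1700) the solution is the exact interpolant and the weighting is
immaterial, but weights ∝ (direction count)·(predicted MS)² over two
passes are implemented for generality with more shells. b = 0 is excluded,
paralleling the DTI perfusion choice; the free S0 absorbs the suppressed
baseline. Voxels with non-positive shell means or MD ≤ 0 get NaN kurtosis
and are left to the QC stage.

The two-point ADC (`compute_adc()`) reproduces the clinical convention:
first listed diffusion direction only, `ADC = ln(S₂₀₀/S₁₀₀₀)/800`. The
direction index is configurable.

### Plausibility rules and ROI statistics

Excluded voxels are encoded as NaN and masks are per map — a voxel can be
implausible in MK yet valid in MD, matching per-map exclusion accounting.
Defaults: kurtosis outside [0, 2.5] (2.5 being the conventional ceiling for
plausible tissue kurtosis), FA outside [0, 1], diffusivity outside
[0, 3.0×10⁻³ mm²/s]. The diffusivity ceiling is the free-water value at
body temperature rather than a literal "1" in reporting units of
10⁻³ mm²/s: a literal cutoff of 1×10⁻³ would discard voxels that healthy
pancreas demonstrably occupies (90th-percentile MD above 1.1×10⁻³), so the
ceiling is treated as under-specified in the literature and left
configurable. ROI statistics use linear-interpolation percentiles (type 7,
the dominant convention in scientific software); cohort summaries average
repeats within subject before taking cohort medians and IQRs.

### Repeatability and agreement

Two summaries of test–retest differences are reported side by side because
they answer different questions: the Bland–Altman limits of agreement use
the sample SD around the mean difference (n−1), while the headline
coefficient of repeatability is the RMS form `r = 1.96·√(Σd²/n)` without
mean-centering, so a systematic shift between acquisitions inflates r but
not the LoA width. Inter-reader agreement uses ICC(2,1) — two-way random,
absolute agreement, single measurement — because absolute agreement is the
semantics of "do two readers produce the same number"; the consistency form
is provided for comparison and is provably larger under a constant reader
offset. Interpretation bands follow the conventional thresholds (< 0.5
poor, 0.5–0.75 moderate, 0.75–0.9 good, > 0.90 excellent); at the printed
boundaries 0.75 and 0.9 the band is "good", since "excellent" is quoted
strictly as > 0.90. Weighted kappa uses quadratic disagreement weights
`(i−j)²/(k−1)²` on the declared ordered category set (integer categories
only; averaged half-step scores are out of scope), with Landis–Koch bands
closed right-continuously so the conventional gaps (e.g. 0.80–0.81) cannot
swallow a value.

## The phantom: what it emulates, what it does not

`simulate_dataset()` builds a pancreas-like crescent (a chain of discs
along an arc, tapering from head to tail, present on all 6 slices) inside
an elliptical body surrounded by air. The principal diffusion axis follows
the crescent tangent, so 6- versus 16-direction sampling is genuinely
exercised; a constant-orientation debug mode exists. Tissue truth defaults
are the healthy-pancreas medians the acquisition is designed around
(AD = 1.3, RD = 0.85 ×10⁻³ mm²/s, hence MD = 1.0 ×10⁻³; MK = 0.66), with a
second, more isotropic background-tissue class. Per voxel the noiseless
signal is

S(b, g) = S0·[(1−f)·exp(−b·D(g) + (1/6)·b²·D(g)²·MK) + f·exp(−b·D*)]

with D(g) = gᵀDg — a single scalar MK applied to the directional apparent
diffusivity (only mean kurtosis is estimated, so no kurtosis tensor is
modelled) — and an optional IVIM term (f, D*) that is off by default. Each
scanner average is an independent Rician draw (magnitude of complex
Gaussian, σ = S0_pancreas/SNR defined at b = 0 and a single average);
delivered volumes are magnitude means over their averages, mirroring
scanner behaviour. Repeats of a subject share the noiseless signal and
differ only in noise; `subject_cv` optionally adds deterministic log-normal
between-subject variation of the tissue parameters (default 0; the study
drivers use 0.08 so that between-subject variance, and hence inter-reader
ICC, is meaningful — with identical subjects ICC is structurally near zero
on phantom data).

Not modelled: respiratory and cardiac motion, bowel gas, EPI distortion and
ghosting, partial-Fourier effects, T1/T2 relaxation weighting, and
registration errors between repeats. Passing recovery tests on this phantom
therefore demonstrates correctness of the estimation chain under Rician
noise, not robustness to physiological artefacts — the factor most likely
to dominate in vivo kurtosis error.

### Estimands versus generative parameters

Two subtleties define what "truth" means in the recovery tests:

* With MK > 0 in the forward signal, a two-shell log-linear tensor fit has
  a deliberate model bias (for MD = 1.0×10⁻³ and MK = 0.66, recovered MD is
  ≈13% lower), exactly as the in-vivo procedure has on real tissue. The
  estimand of the pipeline is therefore the noiseless-pipeline value, and
  noisy-recovery tests compare against a noise-free run recomputed at test
  time, never against stored numbers.
* For anisotropic tensors the powder average of the forward signal is not
  exactly of mean-signal DKI form, so the generator also returns
  closed-form model-implied truth maps (`mk_msdki`, `md_msdki`, `adc`)
  computed analytically from the noiseless shell means, independent of the
  fitting code path. The noiseless end-to-end tests require agreement with
  these to 1e-9 relative.

### The slice-thickness / SNR experiment

With in-plane resolution, averages, bandwidth and directions fixed, SNR is
proportional to slice thickness, and first-order propagation through the
three-shell log-linear fit gives sd(MK) ∝ 1/SNR; moving from 3 mm to 5 mm
slices predicts a 40% error reduction. `snr_scaling_experiment()` checks
this by Monte-Carlo: each simulated voxel's shell mean aggregates all
magnitude samples that enter the powder average — direction count ×
per-shell averages (12/24/30 for the 6-direction protocol) — because that
is the quantity the mean-signal fit consumes. This aggregation matters:
with only the 2/4/5 scanner averages per shell the MK estimator is far into
its nonlinear regime and the measured reduction (~56%) no longer reflects
the first-order prediction, while at the fit's true operating point the
Monte-Carlo lands at ≈41–42%.

## Numerical choices

* Shell membership tolerance ±25 s/mm² (scanners jitter nominal b-values);
  shell values are medians of their group.
* Non-positive signals are clipped to a machine-epsilon-scaled floor before
  logs, with a message reporting the count; all-zero voxel series become
  NaN voxels, never errors.
* Eigenvalues are sorted descending; `eigen(symmetric = TRUE)` provides
  orthonormal vectors, and reconstruction D = VΛVᵀ is verified to 1e-9 in
  the suite.
* The 6-direction scheme is the icosahedral vertex set (minimum folded
  angle 63.43°); larger schemes come from electrostatic-repulsion
  minimisation (point + antipode charges) from a deterministic
  Fibonacci-sphere start, iterated until the Riemannian gradient norm is
  below 1e-8.
* Scalar maps are written as 32-bit float NIfTI-1 with NaN for excluded
  voxels; reading back returns exactly the stored single-precision values.
* Noise seeds derive deterministically from (master seed, subject, repeat),
  kept below 2³¹.

## Problem sizes

The default phantom grid is 64×64×6. The test suite and the validation
scripts run the statistical checks at desk scale chosen for precision per
unit time: the 12-subject × 2-repeat recovery check uses a 32×32×6 grid
(≈500 pancreas voxels per acquisition, ample for median statistics), the
Monte-Carlo SNR experiments use 10⁴–3×10⁴ voxels per condition, and unit
fixtures use the smallest grids that exercise the contract. Acquisition
conditions — shells, averages, direction counts, SNR 30, subject and repeat
counts, tissue truth — are never scaled.

## Known limitations

* Kurtosis estimates are noise-limited; at SNR 30 roughly 10% of single
  voxels fall outside the plausible [0, 2.5] band before denoising, which
  is why exclusion accounting is a first-class output.
* The MP-PCA contract assigns only window centres; overlapping-window
  aggregation would denoise slightly better at the cost of a less
  transparent contract.
* ADC from a single direction is anisotropy-sensitive by design (it mirrors
  a clinical convention); the trace-ADC alternative is not implemented.
* No motion, eddy-current or distortion correction is included; inputs are
  assumed anatomically aligned across volumes and repeats.
* Kappa requires integer ordinal categories; averaged sub-scores must be
  analysed with the ICC instead.
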