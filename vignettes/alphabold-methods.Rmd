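---
title: "Alpha-band power / BOLD coupling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha-band power / BOLD coupling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphabold)
```

`alphabold` estimates where and how strongly the amplitude of the
occipital EEG alpha rhythm couples to the BOLD signal recorded
simultaneously, and whether that coupling differs between groups. This
vignette documents the underlying models, the parameters that matter, the
synthetic-data generator used for validation, and the places where the
method required genuine design decisions.

## The measurement model

The EEG inside the scanner is a sum of brain signal and two large
structured artifacts:

* a **gradient artifact**, locked to the scanner's volume acquisition
  (every TR = 2.6 s) and typically two orders of magnitude larger than
  the EEG;
* a **ballistocardiogram (BCG)**, a pulse-related artifact locked to each
  cardiac R peak with a delay of roughly 0.2 s.

Both are removed with sliding-window **average-artifact subtraction**: an
epoch is cut around each trigger (scanner marker or detected R peak), the
mean over the `n_avg = 21` nearest epochs forms the template, and the
template is subtracted from each epoch. Averaging attenuates everything
not phase-locked to the trigger by roughly `1/n_avg` in power, so the
template converges on the artifact. For the BCG the beat timing is
asynchronous with the sampling grid; templates are therefore built and
subtracted at each beat's fractional phase, and a per-beat
cross-correlation alignment absorbs residual timing error from the R-peak
detector. The aligned candidate is only used when it lowers the residual
energy, so a perfectly phase-locked artifact is still cancelled exactly.

Band power is estimated by **complex demodulation**: the pooled occipital
signal is multiplied by `exp(-2πi f_c t)` at the band center `f_c`,
low-pass filtered at half the bandwidth (4th-order Butterworth, applied
forward and backward so the estimate is zero-phase), and scaled so that a
pure in-band sinusoid of amplitude A yields power A²/2 — the band
variance. Power (not amplitude) is exported; the first and last 2 s are
flagged invalid to cover the filter transients.

The **first-level GLM** regresses each voxel's time course on the
HRF-convolved, mean-centered 1-s power series (sampled at the retained
volume onsets by linear interpolation — 1 s does not divide the 2.6 s TR,
so a common grid does not exist), an unconvolved artifact nuisance
regressor, and a constant. The HRF is the canonical double-gamma
(shapes 6 and 16, rates 1, undershoot ratio 1/6, peak normalized to 1,
peak at ≈ 5 s). Estimation is ordinary least squares without prewhitening:
serial correlation is left unmodeled, a simplification chosen for
determinism (the null calibration below shows its effect is negligible
under the simulated noise; real fMRI noise is autocorrelated and would
make first-level p values optimistic — group-level inference, which treats
subjects as the random unit, is unaffected).

The **second level** operates on the per-subject alpha coefficient maps
(the summary-statistics approach): one-sample t per group and a pooled
two-sample HC > AD contrast, each as a small voxel-wise regression with
mean-centered covariates. Demographic covariates (age, gender, education)
enter here rather than at the first level — within a subject they are
constant and would be collinear with the mean term. Normalized
hippocampal volume is a toggleable additional covariate; both variants
are always produced. Positive and negative associations are separate
one-sided tests, matching the use of signed contrasts.

**Cluster-extent thresholding** retains components of at least k = 50
voxels among voxels with one-sided p < 0.01 (uncorrected) inside a
gray-matter mask (tissue probability ≥ 0.3 — "thresholded at 0.3 and used
as an inclusive mask" is read in the conventional inclusive sense).
Connectivity defaults to 18 (faces + edges), configurable to 6 or 26;
components come from the adjacency graph of suprathreshold voxels.
Ordering is by size, then peak t, then lexicographic peak index.

## Temporal filtering and degrees of freedom

Slow scanner drift is removed by projection onto the orthogonal
complement of a basis of discrete cosines with periods ≥ 128 s plus an
explicit linear trend and the constant. A projection (rather than an IIR
filter) is exactly idempotent and lets the GLM account for the removed
dimensions: `fit_glm(df_drop =)` subtracts the drift dimensions from the
residual df, so under Gaussian noise the first-level t statistic is
exactly Student-t distributed. The null calibration (20 replicate null
cohorts, 160,000 voxel draws) empirically confirms an exceedance of
0.01 ± 0.005 at the p = 0.01 threshold at both analysis levels.

## The synthetic cohort generator

No recordings ship with the package; the generator emulates the
acquisition the pipeline targets and provides ground truth for recovery
metrics:

* **Acquisition defaults**: 32-channel EEG at 5 kHz plus an ECG channel,
  468 s (7.5 min) eyes-closed rest, TR 2.6 s, 180 volumes, 3.5 mm voxels
  on a 20³ common-space grid. (The emulated protocol nominally acquires
  180 volumes although 7.5 min / 2.6 s ≈ 173; 180 is kept as the default
  and markers simply stop at the recording end.)
* **Alpha source**: a rectified AR(1) Gaussian amplitude envelope (mean
  20 µV, sd 12 µV, AR coefficient 0.999 at 250 Hz, i.e. a ~4 s
  fluctuation time scale) modulating a 10 Hz carrier whose phase diffuses
  with ~1 Hz spectral width. The phase diffusion matters: spontaneous
  alpha is not coherent across scanner epochs, and a perfectly coherent
  carrier at 10 Hz would be exactly TR-periodic (26 cycles per 2.6 s) and
  be removed by the AAS template along with the artifact. The source
  projects to the scalp with fixed occipital-dominant weights (alpha is
  best expressed occipitally).
* **Artifacts**: a sawtooth-plus-harmonics gradient template repeated
  exactly every TR (per-epoch amplitude jitter configurable, default 0),
  amplitude 2000 µV; a damped-oscillation BCG template (100 µV, 0.5 s)
  at each R peak + 0.21 s; R peaks at 60 bpm with 3 % RR jitter; white +
  pink background noise at 5 µV.
* **BOLD**: voxel v follows
  `baseline × (1 + c_v · z(t)) + drift + noise`, where `z` is the
  HRF-convolved envelope standardized over the acquired volumes, `c_v` is
  the signed coupling map (groups differ only here), noise is 1 % of
  baseline, drift 1 %. The envelope (amplitude) drives the BOLD while
  the pipeline recovers power (amplitude squared); for the chosen
  envelope parameters the two are correlated at ≈ 0.9, which is part of
  what end-to-end recovery has to overcome.
* **Covariates** are drawn from the cohort characteristics the generator
  emulates (age 75.3 ± 5.7 vs 73.4 ± 3.1; education 14.4 ± 2.7 vs
  13.6 ± 2.8; MMSE 24.6 ± 3.1 vs 28.7 ± 0.8; 4/14 female). For
  normalized hippocampal volume, means 0.0040 ± 0.0007 (AD) vs
  0.0044 ± 0.0005 (HC) were chosen once to give a modest group
  difference that typically does not reach significance at n = 14 —
  hippocampal atrophy present but not the driver of the analysis.

What the generator does **not** emulate: head motion, physiological
noise structure (RETROICOR-type), slice-wise acquisition, realistic
anatomy or spatial normalization (data are born in a common grid),
inter-subject variation in HRF shape, and non-stationary artifact
waveforms. Passing recovery tests therefore demonstrates correctness of
the implemented computations under the stated model, not robustness to
everything real recordings contain.

## The demonstration cohort and problem sizes

The bundled demonstration uses 8 HC and 8 AD subjects on the 20³ grid,
full 468 s sessions, with EEG simulated at 500 Hz and decimated to the
250 Hz working rate — the same decimation factor structure as the
acquisition default at a problem size that keeps the cohort comfortably
runnable on a laptop core; the 5 kHz default remains available in
`sim_config()`. HC subjects carry +2 % coupling in a 125-voxel region A
and −2 % in region B; AD subjects carry none. Recovery is scored by the
Dice coefficient between surviving clusters and the true regions; the
8 mm smoothing kernel (σ ≈ 1 voxel) inflates clusters beyond the
implanted blocks, which is why Dice ≈ 0.4 rather than 1 is the expected
outcome and ≥ 0.3 the acceptance bar.

Artifact-removal quality is quantified on the ground-truth artifact
component (the paired-simulation difference), as attenuation in dB: at
the TR harmonics for the gradient (≈ 50 dB), and in the 1–12 Hz band on
a frontal channel for the BCG (≈ 19 dB). The frontal channel is used
because the artifact band overlaps occipital alpha, which is genuine
signal and must not be scored as residual artifact.

## Numerical choices and degenerate inputs

* Filters are 4th-order Butterworth applied forward-backward
  (zero-phase); decimation applies an 8th-order anti-alias low-pass at
  80 % of the target Nyquist first.
* The R-peak detector is a Pan-Tompkins-style energy detector with a
  0.3 s refractory period and sub-sample refinement by cross-correlation
  against the mean beat; a flat ECG yields an empty result with a
  warning rather than an error.
* Artifact intervals are marked where the 0.2 s moving RMS exceeds a
  robust (median/MAD) z of 4; intervals merged across < 0.5 s gaps;
  only intervals ≥ 1 s feed the nuisance regressor, but all invalidate
  power segments.
* The ICA stage is a compact symmetric fastICA (tanh contrast) with
  automated rejection (|r| > 0.3 against the ECG, or > 60 % of power
  below 2 Hz); it replaces manual component selection, is optional, and
  a failed decomposition skips the stage with a warning.
* Zero-variance voxels give NaN first-level t values (flagged and
  counted), and an infinity sentinel at the second level when the mean is
  nonzero; exactly fitted voxels are snapped to zero residual variance so
  rounding noise cannot masquerade as significance.
* Smoothing uses nearest-edge replication at the grid boundary; a
  uniform volume is exactly preserved.
* Scalar group tests use the pooled-variance two-sample t with
  `df = n_A + n_B − 2`; a summary-statistic variant computes the same
  from printed moments. Zero pooled variance returns p = 1 (equal means)
  or an infinity sentinel (unequal).

## Known limitations

OLS without prewhitening makes single-subject p values optimistic on
real (autocorrelated) fMRI noise. Channel interpolation for noisy
electrodes is not implemented (synthetic data never need it). The
gray-matter and atlas masks in the demonstration are geometric stand-ins,
not anatomy. Heteroscedastic (per-group variance) second-level inference
is not offered; the pooled form matches the classical two-sample t.
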