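# alphabold

Simultaneous resting-state EEG-fMRI analysis of **alpha-band power / BOLD
coupling**, as used to compare patients with Alzheimer's disease (AD)
against healthy controls (HC).

During relaxed, eyes-closed wakefulness the occipital EEG is dominated by
the alpha rhythm (8–12 Hz), whose amplitude waxes and wanes over seconds.
When EEG is recorded inside the MR scanner, the time course of alpha band
power can be used as a regressor for the BOLD signal: after convolution
with a hemodynamic response function (HRF), voxels whose BOLD fluctuation
tracks alpha power receive large positive (or negative) t values. In
healthy adults this coupling is positive in thalamic and default-mode
regions and negative in occipital cortex; in AD these associations are
hypothesized to weaken. `alphabold` implements the full analysis chain
needed to test this, plus a synthetic simultaneous EEG-fMRI generator so
that every stage can be validated by parameter recovery — no clinical
recordings are required or included.

## The pipeline

Per subject, for each band b ∈ {8–12, 8–10, 10–12 Hz}:

1. **EEG cleaning** — downsample 5 kHz → 250 Hz; remove the TR-locked MR
   gradient artifact and the R-peak-locked ballistocardiogram by sliding
   average-artifact subtraction (AAS); band-pass 0.5–70 Hz with a 50 Hz
   notch; optional automated ICA cleanup; common-average re-reference;
   pool O1, O2, Oz.
2. **Band power** — complex demodulation: multiply by `exp(-2πi f_c t)`,
   low-pass at half the bandwidth, scale so a sinusoid of amplitude A has
   power A²/2; average into artifact-free 1-s segments.
3. **Regressors** — mean-centered power convolved with the canonical
   double-gamma HRF and sampled at the volume onsets; an unconvolved
   artifact on/off nuisance regressor; first 6 volumes dropped.
4. **BOLD prep** — drop 6 saturation volumes, 8 mm FWHM Gaussian
   smoothing, 128-s discrete-cosine high-pass.
5. **First-level GLM** — per voxel, OLS of the BOLD time course on
   `[alpha, artifact, constant]`; positive and negative t-contrasts
   `t = c'β̂ / √(σ̂² c'(X'X)⁻¹c)`.
6. **Group level** — one-sample t maps per group and an HC > AD
   two-sample map over the per-subject alpha coefficient maps, with
   covariates (age, gender, education, optionally normalized hippocampal
   volume); gray-matter masking (probability ≥ 0.3); threshold p < 0.01
   uncorrected with cluster extent ≥ 50 voxels; ROI hit counting and
   atlas overlap (Dice).

## Worked example

```r
library(alphabold)

spec <- demo_cohort_spec(n_per_group = 8)   # HC coupled, AD uncoupled
res  <- run_demo(spec, seed = 1)

sm <- res$group$stat_maps
row <- sm[sm$band == "total_alpha" & sm$analysis == "two_sample_HC_gt_AD" &
          sm$sign == "positive" & !sm$hippo_covariate, ]
row$clusters[[1]][, c("size", "peak_t", "i", "j", "k")]
#> # A tibble: 1 × 5
#>    size peak_t     i     j     k
#>   <int>  <dbl> <int> <int> <int>
#> 1   501   24.3    10     7    12

atlas_overlap(row$clusters[[1]], spec$region_a)
#> # A tibble: 1 × 4
#>   cluster_id  size overlap_frac  dice
#>        <int> <int>        <dbl> <dbl>
#> 1          1   501        0.248 0.396
```

The two-sample HC > AD positive contrast recovers a single surviving
cluster (501 voxels, peak t ≈ 24) centered on the region where the
generator implanted a +2 %-of-baseline coupling in the HC group only; its
Dice overlap with the true region is ≈ 0.4 (the smoothing kernel spreads
the cluster beyond the implanted block, which caps attainable Dice). The
AD one-sample map yields no cluster in that region.

A thin command-line front-end is provided at `inst/cli/alphabold.R`
(`simulate` writes a BrainVision + NIfTI cohort to disk, `demo` runs the
full analysis).

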