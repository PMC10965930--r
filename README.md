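# qsmcohort

Quantitative susceptibility mapping (QSM) estimates the magnetic
susceptibility of brain tissue — raised by iron deposition, lowered by
myelin — from the phase of multi-echo gradient-echo (GRE) MRI.
Case-control psychiatric studies use it to compare subcortical structures
(red nucleus, substantia nigra, caudate, putamen, thalamus, hippocampus,
nucleus accumbens, amygdala, globus pallidus externa/interna) between
healthy controls (HC), major depressive disorder (MDD) and schizophrenia
(SCZ) groups, and to ask whether the volume–susceptibility relationship is
disease-specific.

This package implements that entire analysis as reusable, tested R code,
for researchers who want to audit, reproduce, or extend such studies
without access to raw scanner data:

1. **Phantom simulation** (`build_phantom()`, `simulate_gre()`): a digital
   susceptibility scene (ellipsoidal structures with χ in the deep-grey
   range −0.015 to +0.12 ppm, a CSF ventricle pair at χ = 0, air-like
   external sources at 9 ppm) forward-modelled through the unit dipole
   kernel `D(k) = 1/3 − k_z²/|k|²` into complex multi-echo GRE data
   (TE₁ = 3.6 ms, ΔTE = 5.91 ms, 8 echoes, 3 T), with Rician magnitude
   noise at a configurable SNR and phase wrapped to (−π, π].
2. **Reconstruction** (`reconstruct_qsm()`): Laplacian phase unwrapping,
   V-SHARP background-field removal (variable spherical-mean-value kernels),
   per-echo field conversion, R2\*-weighted echo combination with
   `w_i ∝ TE_i·exp(−TE_i·R2*)`, two-stage iterative least-squares (LSQR)
   dipole inversion with streak suppression in the ill-conditioned cone
   `{|D(k)| < 0.1}`, and zero-referencing to the lateral-ventricle mean.
3. **VOI measurement** (`extract_measurements()`): per-structure mean
   susceptibility over the VOI after 2-pixel in-plane (per-slice) erosion;
   volume as uneroded voxel count × voxel volume; unweighted bilateral
   averaging.
4. **Group statistics** (`run_group_stats()` and friends): Shapiro–Wilk and
   Levene assumption checks, per-region one-way ANOVA with
   Benjamini–Hochberg FDR across the 10 regions (per measure), Tukey HSD
   post hocs (FDR across pairs) gated on the omnibus q, a general linear
   model of standardized susceptibility on group × standardized volume
   (treatment contrasts, HC reference), ANCOVA with handedness, and Pearson
   correlation screens against clinical covariates.
   `anova_from_summary()` recomputes F statistics directly from printed
   per-group means/SDs/n, so published tables can be verified without raw
   data.
5. **Cohort simulation** (`simulate_cohort()`): per-subject tables with the
   published group sizes (50/49/24) and per-region means/SDs, plus a
   configurable within-group volume→susceptibility slope on the pooled
   standardized scale (default: 0.58 for the MDD nucleus accumbens).

## Worked example

```r
library(qsmcohort)

truth <- build_phantom(default_phantom_spec(64))
gre   <- simulate_gre(truth, acquisition_params(snr = Inf))
chi   <- reconstruct_qsm(gre, truth$brain_mask, truth$ventricle_mask,
                         recon_config(vsharp_radii_mm = seq(1, 7, 2)))
extract_measurements(chi, truth$atlas)[, 1:3]
#>     structure susceptibility_ppm volume_mm3
#>       putamen         0.09642194        552
#>   hippocampus        -0.01433111        256
```

The noiseless pipeline recovers the ground truth (0.1 and −0.015 ppm)
within 3.6 % and 4.5 %; at SNR 50 the errors grow to about 4 % and 12 %.
The volumes are the bilateral means of the uneroded voxel counts (×1 mm³).

On the statistics side, the published three-group volume ANOVA for the
thalamus is reproduced from its printed summary cells alone:

```r
anova_from_summary(means = c(5542, 5476, 5234),
                   sds   = c(471, 450, 564),
                   n     = c(50, 49, 24))
#>          F df1 df2          p
#> 1 3.380292   2 120 0.03730963
```

and a simulated cohort at the published group parameters yields the
MDD-specific accumbens interaction:

```r
cohort <- simulate_cohort(cohort_spec(seed = 7))
fit <- glm_group_volume(cohort, "nucleus accumbens")
fit[fit$term == "groupMDD:vol_z", c("B", "SE", "t", "q")]
#>           B       SE        t           q
#> 5 0.7257397 0.199178 3.643674 0.002010405
```

(a single draw; across 500 seeds the mean estimate is 0.588 with 96 %
CI coverage — see the acceptance report below).

The `analysis/` directory holds the full workflow as numbered drivers
(`01_simulate_phantom.R` … `06_reproduce_anova.R`); each writes its tables
under `results/`.  `run_pipeline()` chains phantom → reconstruction → VOI →
statistics for a configurable synthetic cohort.

## Conventions

Arrays are indexed (x, y, z), axial slices are fixed z, and B0 points along
+z by default.  Positive phase ⇔ positive field shift ⇔ paramagnetic
χ > 0; the simulator and the reconstruction share this sign convention.
All FFT-based operators treat the grid as periodic; phantom scenes keep the
brain mask ≥ 8 voxels clear of the grid edge.  Susceptibility is reported
in ppm relative to the lateral-ventricle mean, volumes in mm³.
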