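---
title: "Methods: phantom simulation, susceptibility reconstruction, and subcortical group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom simulation, susceptibility reconstruction, and subcortical group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the models, numerical choices and known limitations
behind the package, at the level of detail a maintainer or reviewer needs
to judge what the passing tests do and do not demonstrate.

## The forward model

Tissue magnetization along B0 induces a field shift that is, in k-space,
the susceptibility distribution multiplied by the unit dipole kernel

$$D(\mathbf{k}) = \frac{1}{3} - \frac{(\mathbf{k}\cdot\hat{b}_0)^2}{|\mathbf{k}|^2},$$

with the undefined value at $\mathbf{k}=0$ set to 0.  That convention makes
the forward field of any uniform susceptibility zero and leaves
reconstructed susceptibility mean-free; the absolute scale is fixed later
by zero-referencing to the lateral ventricles, which is also how the
in-vivo analysis this package models defines its reference.  The GRE phase
at echo time $TE_i$ is $\phi_i = 2\pi \gamma B_0 \cdot f_{ppm}\cdot 10^{-6}
\cdot TE_i$ ($\gamma$ = 42.577 MHz/T, $B_0$ = 3 T), magnitude decays as
$\exp(-TE_i R_2^*)$, and complex Gaussian noise gives Rician magnitudes.
SNR is defined on the first-echo magnitude within the brain mask; the
in-vivo protocol states no noise level, so the simulated SNR (default 50
in the demo pipeline, $\infty$ in the recovery studies) is an assumption,
not a measured fact.

All spectral operators treat the grid as periodic.  Phantom scenes
therefore keep the brain mask at least 8 voxels clear of every edge;
with the dipole field decaying as $r^{-3}$, wrap-around contamination is
below the tolerances of every test that uses the default scenes.

### The phantom scene

The default scene is a 64³ grid at 1 mm isotropic: a spherical "brain"
(radius 24 voxels, χ = 0, R2\* = 20 s⁻¹), bilateral paramagnetic spheres
(putamen-like, +0.1 ppm, radius 5), bilateral weakly diamagnetic spheres
(hippocampus-like, −0.015 ppm, radius 4), a ventricle pair (χ = 0, radius
4) and two air-like spheres (+9 ppm) outside the brain near the top and
bottom of the grid.  The susceptibilities span the range measured in deep
grey matter, so the scene exercises zero-referencing, background removal
and both signs of contrast.  Two geometric choices matter:

* **Structure depth.** Every labelled structure sits at least 9 voxels
  below the brain boundary.  V-SHARP (below) deconvolves with its largest
  kernel radius, and voxels whose largest *admissible* kernel is smaller
  than that radius keep a low-spatial-frequency bias that no later stage
  can undo.  Keeping structures deeper than the largest configured radius
  (7 mm in the phantom-scale configuration) makes the deconvolution exact
  over every VOI.  This is a real property of V-SHARP, not an artifact of
  this implementation: near-boundary structures in vivo carry the same
  bias.
* **Scene scaling.** `default_phantom_spec(grid)` scales centres and radii
  with the grid so the demo pipeline can run at 48³.  Below ~48 voxels the
  structures become too small to survive the 2-pixel in-plane erosion used
  for measurement, which is why the pipeline configuration refuses grids
  under 24 and the demo default is 48.

## Reconstruction chain

**Laplacian unwrapping.** The unwrapped phase is recovered from
$\nabla^{-2}[\cos\phi_w\,\nabla^2\sin\phi_w-\sin\phi_w\,\nabla^2\cos\phi_w]$
with spectral Laplacians.  On a purely periodic grid a net phase ramp
across the volume is unrepresentable — the periodicity constraint silently
removes the mean gradient, and a 6π ramp would come back with slope scaled
by the ratio of mask width to grid period.  The operators are therefore
evaluated on the mirror-extended grid (even/Neumann boundary, the DCT
convention), which represents net ramps exactly; a wrapped 6π ramp is
recovered to ~0.0014 rad.  The periodic variant is kept as an option.
Like every Laplacian unwrapper, the method determines phase only up to a
component harmonic over the volume; that component is background field by
definition and is removed by the next stage anyway.

**V-SHARP.** Fields from sources outside the brain are harmonic inside it,
so the spherical-mean-value (SMV) filter $(I-S_r)$ annihilates them where
a radius-$r$ sphere fits inside the mask.  Each voxel is filtered with the
largest radius admissible at that voxel (largest deep in the brain,
shrinking toward the boundary); the filtered field is then deconvolved by
$(1-\tilde S_{r_{max}})^{-1}$ in k-space, truncating where
$|1-\tilde S_{r_{max}}|<0.05$.  The valid mask is the input mask eroded by
the smallest radius.  The default radius schedule is 1–29 mm in 2 mm
steps, matching the in-vivo protocol the package models; radii that fit
nowhere in the mask are dropped automatically, and for the 64³ phantom the
analyses use 1–7 mm for the depth reason above.  Background removal is
applied per echo on unwrapped phase, each echo is converted to field (ppm)
by its own $TE$, and the per-echo maps are combined with weights
$w_i \propto TE_i e^{-TE_i R_2^*}$ (the phase-SNR-optimal weighting for a
monoexponential decay), with R2\* from a voxelwise log-linear fit of
magnitude versus TE — closed-form, exact on noiseless data; a nonlinear
Rician-aware fit is out of scope.

**Dipole inversion.** Stage 1 solves the support-constrained least-squares
problem
$\arg\min_\chi \lVert M(\mathcal{F}^{-1}D\mathcal{F}(M\chi))-f\rVert_2$
by LSQR (default: 50 iterations or relative residual 10⁻⁴).  The support
constraint matters: without it LSQR returns the minimum-norm solution,
which spreads susceptibility into the exterior and the ill-conditioned
cone and shrank VOI means by ~30 % in pilot phantom runs; with it the
noiseless two-sphere scene is recovered to a few percent.  Stage 2
estimates the streaking artifact: a field constrained in k-space to the
cone $\{|D(\mathbf{k})|<0.1\}$ is fitted by least squares to the
edge-weighted spatial gradients of the stage-1 map and subtracted inside
the mask.  The weights $1/(1+(|\partial f|/4\,\mathrm{med}|\partial f|)^2)$
are small across genuine tissue boundaries (flagged by large local-field
gradients) and depend only on the gradient *pattern*, keeping the whole
inversion linear under rescaling of its input — a property the tests
check.  The exact iLSQR variant used by the original MATLAB analyses is
not published in detail; the two-stage structure follows that lineage, the
constants here are this package's own, exposed in `recon_config()`.

**Zero-referencing** subtracts the mean over the ventricle mask
(intersected with the valid mask) and records the offset.

## VOI measurement

Susceptibility is averaged over the VOI after two iterations of 1-pixel
2D binary erosion applied per axial slice (4-connected cross element;
8-connectivity is available).  The in-plane reading follows the stated
measurement rule ("two pixels in each slice"); erosion is never applied
along z.  Volume is the uneroded voxel count times the voxel volume.
Both are computed per hemisphere and combined as an unweighted left/right
mean; a hemisphere whose eroded VOI is empty is dropped from the
susceptibility mean and flagged rather than failing the subject.

## Cohort simulation

`simulate_cohort()` draws, per region and group, volume
$\sim N(\mu_v^g, \sigma_v^g)$ from the published per-group cells, and
susceptibility as

$$\chi = \mu_\chi^g + b\,\frac{\sigma_\chi^{pool}}{\sigma_v^{pool}}(v-\mu_v^g) + \varepsilon,$$

with $\varepsilon$ scaled so the within-group marginal SD matches the
table.  The slope $b$ is expressed on the *pooled* standardized scale
(pooled mixture SDs computed from the group cells and simulated group
sizes) because that is the scale of the group × volume GLM that measured
the published coefficient ($B$ = 0.58 for the MDD nucleus accumbens); a
group-wise standardization would make the generator and the estimator
disagree by the ratio of group to pooled SDs (~35 % for the accumbens).
Centring the slope term on the group volume mean keeps the group means
exact in expectation.  The slope term consumes part of the group variance,
so $|b|\,\sigma_\chi^{pool}\sigma_v^g/\sigma_v^{pool} < \sigma_\chi^g$ is
required; the default configuration satisfies it with margin.
Demographics (sex, handedness, IQ with missingness, illness duration,
severity, medication dose) follow the published marginals; they are
independent of the imaging variables except where stated, which is a
simplification — real handedness or IQ confounding is *not* emulated, so
the ANCOVA and correlation tests check calibration, not confound recovery.

## Statistics

* One-way ANOVA uses the classic between/within decomposition; the
  summary-statistics path (`anova_from_summary()`) is the identity
  $SSW=\sum(n_i-1)s_i^2$, $SSB=\sum n_i(m_i-\bar m)^2$ and is tested to
  agree with the raw-data path to 10⁻⁹ relative.  Degenerate inputs with
  $SSB=0$ define $F=0$.
* BH-FDR is the literal step-up $q_{(i)} = \min_{j\ge i} p_{(j)} m/j$.
  FDR families follow the published tables: across the 10 regions within
  each measure for the omnibus tests, across the 3 pairs within a region
  for post hocs, across the 5 non-intercept terms within a region for the
  GLM.  The "Tukey HSD with FDR" reading is ambiguous in the source
  analysis; the default applies BH *on top of* Tukey-adjusted p-values,
  with `fdr_across_pairs = FALSE` to disable the second layer.
* Post hocs run only where the omnibus FDR-corrected q passes the gate
  (default 0.05); the Tukey statistic is reported as a t value
  ($q=\lvert t\rvert\sqrt2$ against the studentized range, df $N-k$),
  cross-checked against `TukeyHSD()`.
* The GLM standardizes susceptibility and volume over the pooled sample
  (the natural reading of "standardized variables" absent other
  qualification) and codes group with treatment contrasts, HC reference.
* ANCOVA fits group + categorical handedness and reports the type II
  partial F for group; absent handedness levels are dropped with a
  message.
* Correlations use pairwise deletion, mirroring the substantial IQ
  missingness in the modelled study design.
* Assumption checks (per-group Shapiro–Wilk, Levene centred on the mean)
  are reported only and never gate anything downstream.

## Problem sizes and tolerances

The recovery studies use the 64³ scene: noiseless end-to-end VOI-mean
errors are ~3.6 % (putamen) and ~4.5 % (hippocampus) against a 10 %
acceptance band, data fidelity ~3.8 % RMS against 5 %, V-SHARP leakage of
a purely external field ~0.8 % RMS against 5 %.  At SNR 50 the
hippocampus error grows to ~12 % (15 % band).  Slope recovery runs 500
cohorts at the published group sizes (mean estimate 0.588, CI coverage
96 %); calibration runs 10⁴ null replicates (ANOVA 5.3 %, GLM interaction
5.6 % at the 5 % nominal level, both inside the ±1 point band and
consistent with binomial fluctuation — a 4×10⁴-replicate pilot of the same
estimator gave 5.03 %).  These sizes keep the full suite under ~3 minutes
and the acceptance script around one minute on one CPU while leaving
every tolerance comfortably non-binding.

## Known limitations

* The phantom is geometric (spheres in a spherical brain), with none of
  the fine-scale heterogeneity, vasculature, motion or flow of real data;
  passing recovery tests demonstrates correctness of the operators, not
  in-vivo accuracy.
* Hard-edged rasterized sources violate *pointwise* discrete harmonicity
  through Gibbs ringing of the band-limited forward model (at the percent
  level next to a source).  The harmonicity property test therefore uses a
  band-limited Gaussian source; V-SHARP itself, acting through spherical
  means, is insensitive to the ringing, as its suppression numbers show.
* Printed summary cells limit the exactness of published-table
  reproduction: the four volume regions whose F recomputes to the printed
  2 decimals are thalamus, caudate, putamen and globus pallidus externa;
  susceptibility cells are printed to ~2 significant figures and drift by
  up to ~0.5 in F.
* Tissue segmentation, template registration, smoothing-based voxelwise
  analyses and surface-based validation of the modelled study are out of
  scope, as are alternative inversion methods (MEDI, TKD).
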