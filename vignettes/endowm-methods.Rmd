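---
title: "Methods: linking endothelial function to white-matter health on synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking endothelial function to white-matter health on synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`endowm` implements, as one tested pipeline, the bespoke computations of a
study design that relates a peripheral marker of endothelial function (the
reactive hyperemia index, RHI) to two neuroimaging markers of white-matter
(WM) health — fractional anisotropy (FA) and white-matter hyperintensity
(WMH) volume — and to executive function (Trail Making Test, Trail B −
Trail A). Real cohorts of this kind are small, private, and produced by long
chains of scanner-side tooling; everything upstream of the statistics
(acquisition, registration, skull-stripping, tensor fitting, streamline
sampling) is out of scope here. Instead, seeded generators produce inputs
with the statistical structure those chains deliver, with known ground
truth, so every downstream stage is testable end to end.

## WMH volumetrics: the two-Gaussian histogram model

The intensity histogram of FLAIR WM voxels is modelled as a two-component
Gaussian mixture

$$f(x) = w\,\mathcal{N}(x;\mu_1,\sigma_1) + (1-w)\,\mathcal{N}(x;\mu_2,\sigma_2),$$

whose dominant component (the larger mixing weight) represents
normal-appearing WM. Hyperintense voxels are those whose intensity strictly
exceeds

$$T = \mu_{\mathrm{dom}} + k\,\sigma_{\mathrm{dom}}, \qquad k = 2.33,$$

and WMH volume is the above-threshold voxel count times the voxel volume,
reported in mm³ and as a percentage of intracranial volume (ICV). A frontal
variant restricts the count to a frontal submask. With $k = 2.33$ a fraction
$1-\Phi(2.33) \approx 0.99\%$ of genuinely normal WM always exceeds $T$;
this tail is intrinsic to the method and is what the pipeline measures on a
lesion-free phantom. Consequently, the *total* above-threshold volume
overstates a small planted lesion load by roughly that tail, while the
planted lesions themselves (placed $6\sigma$ above the mode) are recovered
essentially completely; the package reports both quantities.

Because no fitting procedure is canonical for this model, the package uses
weighted nonlinear least squares on the binned density (256 bins by
default), Levenberg–Marquardt, initialized from a count-weighted two-means
split of the histogram mass with five deterministically jittered restarts.
Two numerical guards matter in practice:

* **Collapse guard.** A component with weight below 0.01 or SD below one bin
  width is meaningless at histogram resolution.
* **Overlap guard.** If the two fitted means lie within two fitted SDs of
  each other the mixture density is unimodal and the split between the
  components is not identifiable — on unimodal data the optimizer otherwise
  happily returns an arbitrary two-way split of the single mode, which
  biases $\sigma_{\mathrm{dom}}$ and hence $T$. Hyperintense lesion
  populations sit far above the normal-appearing mode, so real bimodal
  histograms are unaffected.

In either case the histogram is refitted with a single Gaussian via
count-weighted moments with Sheppard's grouping correction (the classical,
near-efficient estimator for grouped Gaussian data) and flagged
`degenerate`. Exact weight ties between components are broken toward the
lower mean, since normal-appearing WM is hypointense relative to lesions on
FLAIR. Membership is strict (`> T`), no minimum-lesion-size or
connected-component filter is applied, and all thresholds (2.33 here, 0.2,
0.05 and 2.5 below) are arguments with these defaults.

## Reactive hyperemia index

The RHI is the ratio of the post-occlusion to the pre-occlusion average
pulse amplitude. "Signal size" is measured per beat as peak minus the
following trough, which is the conventional plethysmographic pulse
amplitude; an RMS-envelope alternative is provided. Beats are local maxima
in the upper half of the interval's range, separated by at least half the
beat period estimated from the interval's dominant spectral component (the
spectral estimate is what makes detection robust to additive noise). The
pre average uses the whole baseline phase; the post average uses the whole
post phase unless a window is supplied — the exact averaging window of the
commercial device is unpublished, so the package implements the stated
ratio and nothing more. A residual pulse above 10% of baseline during
occlusion sets an advisory `occlusion_ok = FALSE` flag rather than failing,
since real protocols exclude on participant comfort, not signal grounds.

The generator produces an amplitude-modulated sinusoid with per-phase
envelope `baseline_amplitude * (1, occlusion_residual, hyperemia_ratio)`.
Defaults are desk-scale (60/30/30 s at 100 Hz, beat rate 1.25 Hz,
1% additive noise, hyperemic ratio 1.73, the scale of published older-adult
cohorts); the clinical 600/300/300 s protocol is one argument away, and the
noise-free index is invariant to proportional phase shortening. The default
beat rate divides the sample rate exactly, so sampling hits every peak and
trough and the noise-free index is exact to machine precision — a useful
property for regression testing.

## Connectivity hard segmentation

Each seed voxel is assigned to the target with the strictly largest
streamline count, provided it reaches `min_count` (default 1); ties and
all-zero voxels are left `UNASSIGNED` by default (a `first-in-table` switch
exists) — determinism without fabricating connectivity. Per-target assigned
counts are normalized as

$$100 \times \frac{\#\{\text{seed voxels assigned to target}\}}{\#\{\text{voxels in target mask}\}}$$

to control for cortical target size. Targets are compared by ANOVA with
Bonferroni-corrected pairwise comparisons gated on the omnibus test. The
default error model treats subjects as blocks (repeated measures,
df $=(k-1,(k-1)(n-1))$, which reproduces the conventional df structure of
published seven-target analyses at small n); a between-subjects layout is
selectable, and the df are always reported explicitly because the intended
layout in the motivating literature is ambiguous.

## Voxelwise FA inference

Subjects' FA maps live on a common skeleton (voxels with mean FA strictly
above 0.2). At each skeleton voxel, ordinary least squares of FA on
intercept, RHI, age and sex yields the t statistic of the RHI coefficient.
Family-wise error is controlled by the permutation maximum-statistic method
under the Freedman–Lane scheme: FA and the predictor are residualized
against the nuisance design, residuals are permuted (and re-residualized),
and the corrected p at a voxel is the proportion of permutations whose
maximum |t| over the skeleton reaches that voxel's observed |t| (add-one
convention for sampled permutations; exact enumeration of all $n!$
orderings, with a warning, when `n_perm` allows). Threshold-free cluster
enhancement is a published method and deliberately out of scope; its
replacement by max-statistic correction means cluster definitions differ
from TFCE-based analyses — the corrected p-values control the same
family-wise error rate, but voxel-level correction is less sensitive to
spatially extended weak effects. The significant cluster at corrected
p < 0.05 yields each subject's cluster-mean FA, the value the cohort
statistics consume. Two-sided inference is the default, with a directional
option. Structural ties in the permutation distribution are counted as ties
under a scale-aware tolerance so that p-values do not depend on the
floating-point route that produced the statistic.

## Cohort statistics

Executive function is scored as Trail B − Trail A seconds. Outliers are
excluded by a single-pass, upper-tail-only rule — score strictly greater
than mean + 2.5 SD, both computed once over all non-missing scores. The
rule is deliberately not iterated; a test asserts that secondary outliers
survive. (A quirk worth knowing: with fewer than nine scores the rule can
never fire, because the largest attainable z-score in a sample of size $n$
is $(n-1)/\sqrt{n}$.) Associations "controlling for age and sex" are
residual-based partial correlations — Pearson correlation of OLS residuals
of each variable on the covariates, df $=n-2-q$, two-sided p from the t
transform; the regression-coefficient formulation is equivalent in
standardized form. Sex differences are one-way two-group ANOVAs, F(1, n−2),
identical to the squared pooled t. The summary table reports mean (SD)
overall and by sex in the conventional ordering (age, RHI, Trail
difference, cluster FA).

## What the generators emulate — and what they do not

* **Phantom.** Nested ellipsoids (brain ⊃ WM) with mixture-distributed WM
  intensities, planted spherical lesions, ICV defined as brain-ellipsoid
  volume, and a coronal cut plane standing in for a frontal atlas mask. Only
  the intensity statistics and the regional-restriction logic matter
  downstream, and those are faithful; geometry, bias fields, motion and
  registration error are absent, so passing tests say nothing about
  segmentation robustness to such artifacts.
* **PAT.** Piecewise-constant envelopes and a single sinusoidal harmonic;
  real finger plethysmograms drift, vary beat-to-beat and contain harmonics.
  The ratio logic is exercised; device-specific normalization is not.
* **Connectivity.** Poisson or negative-binomial counts concentrated on an
  intended winner per voxel; no spatial structure or distance-dependent
  fall-off.
* **Cohort.** A latent Gaussian copula over (RHI, cluster FA, Trail
  difference) mapped to Gaussian marginals for RHI and the Trail difference
  and a moment-matched Beta for FA (guaranteeing FA ∈ (0,1)); Trail B is
  Trail A plus the difference, and rare non-positive draws are rejected and
  redrawn. Default moments sit at the scale of a 36-subject older-adult
  cohort (age 63.7 (2.9), RHI 1.73 (0.5), Trail difference 35.4 (15.5) s,
  23/36 female); default latent correlations (0.45 between RHI and FA,
  −0.36 and −0.445 against the Trail difference) take the sign structure
  and magnitude reported in that literature. The copula is the simplest
  structure matching correlation-based analyses; it cannot represent
  nonlinear dependence.
* **Skeleton FA.** Voxelwise Gaussian noise around a common profile with an
  optional linear RHI effect in a designated block, clamped to (0.01,
  0.99); no spatial autocorrelation, so cluster sizes are not comparable to
  smoothed real data.

The lesion intensity distribution is not fixed by the motivating
literature; it is a per-lesion parameter, and examples here place lesions
at $\mu + 6\sigma$ with SD 5 so that recovery is essentially
deterministic.

## Problem sizes and reproducibility

Every generator takes an explicit integer seed and restores the caller's
RNG state; identical spec plus seed gives bit-identical output. The shipped
demo configuration (`inst/extdata/demo_config.yaml`) runs the whole chain —
phantom/WMH, PAT/RHI, connectivity/ANOVA, skeleton/permutation, cohort
statistics — in well under a minute on one core, using a 72×84×54 phantom,
a 36-subject cohort, 300 skeleton voxels and 500 permutations; stage
reports carry the exact configuration and its hash, contain no timestamps,
and rerun bit-identically. The validation suite sizes its simulations to
the same desk scale: 2×10⁵-voxel WM masks for mixture recovery and null
calibration, 200 noisy PAT recordings, 1000 null cohorts of n = 32 for the
partial-correlation level, and 200 null skeleton datasets (n = 30, 500
voxels, 500 permutations) for the family-wise error calibration, with
exhaustive enumeration cross-checked at n = 6. These sizes were chosen so
Monte-Carlo bands (three binomial SEs) are tight enough to be informative
while the whole suite stays interactive.

## Known limitations

* Cluster geometry under max-statistic correction is not comparable to
  TFCE output; only the error-rate guarantee carries over.
* The RHI here is the plain post/pre amplitude ratio, not the commercial
  index (which applies unpublished baseline and contralateral corrections).
* The ANOVA error model for the target comparison is configurable rather
  than fixed, because the intended layout in the motivating literature
  cannot be recovered from its reported degrees of freedom.
* Real-data concerns — registration error, bias fields, beat arrhythmia,
  non-Gaussian FA distributions — are outside the generators' scope by
  design; conclusions about robustness to them require real data.
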