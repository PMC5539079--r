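# endowm

Simulation and analysis pipeline for studies that relate **peripheral
endothelial function** to **white-matter health** and **executive function**
in older adults. The pipeline covers four bespoke computations that such
studies chain together, plus seeded synthetic-data generators so that every
stage can be exercised and validated end to end without access to a private
MRI/EndoPAT cohort:

1. **WMH volumetrics** — the white-matter voxel intensity histogram of a
   FLAIR-like volume is fitted with a two-Gaussian mixture
   `w·N(μ₁,σ₁) + (1−w)·N(μ₂,σ₂)`; voxels exceeding
   `T = μ_dom + 2.33·σ_dom` (the dominant, normal-appearing-WM component)
   are hyperintense, and volumes are reported in mm³ and as % of
   intracranial volume, globally and for a frontal submask.
2. **Reactive hyperemia index (RHI)** — from a fingertip pulse-amplitude
   recording with baseline / cuff-occlusion / post-occlusion phases,
   `RHI = post-occlusion mean beat amplitude / baseline mean beat
   amplitude`, with beats detected as spectral-period-constrained local
   maxima and measured peak-to-trough.
3. **Connectivity hard segmentation** — each seed-cluster voxel is assigned
   to the cortical target with the strictly largest streamline count;
   per-target counts are normalized as
   `100 × assigned voxels / target mask voxels` and compared across targets
   by ANOVA with Bonferroni post-hoc tests.
4. **Voxelwise FA inference** — per-voxel OLS of fractional anisotropy on
   RHI with age and sex as nuisance covariates over a mean-FA > 0.2
   skeleton, with family-wise error controlled by Freedman–Lane
   max-statistic permutation (exact enumeration at tiny n), and extraction
   of the significant cluster's per-subject mean FA.
5. **Cohort statistics** — Trail Making scoring (Trail B − Trail A), the
   single-pass upper 2.5-SD outlier rule, Table-style summaries by sex,
   residual-based partial correlations controlling for age and sex, and
   two-group sex-difference F tests.

## Worked example

```r
library(endowm)

# a 2x10^5-voxel WM phantom: 90% N(100,10) normal-appearing WM,
# 10% N(140,15) partial-volume component
ph <- generate_phantom(phantom_spec(seed = 5))
q <- quantify_wmh(ph$intensity, ph$wm_mask, ph$icv_mm3, ph$voxel_size,
                  frontal_mask = ph$frontal_mask)
q$fit
#> <two_gaussian_fit>
#>   comp1: w=0.901 mu=100.00 sigma=10.07  [dominant]
#>   comp2: w=0.099 mu=140.35 sigma=14.75
q$threshold          # 123.47  = mu_dom + 2.33 * sigma_dom
q$global$volume_pct_icv   # 6.100 (% of ICV above threshold)

# RHI from a simulated recording with true hyperemic ratio 1.73, 1% noise
compute_rhi(generate_pat(pat_spec(hyperemia_ratio = 1.73, noise_sd = 0.01,
                                  seed = 1)))
#> <rhi_result> RHI = 1.7230 (pre 2.0141, post 3.4702; beats 74/36; occlusion ok)

# partial correlation between RHI and cluster FA, controlling age and sex
coh <- generate_cohort(cohort_spec(seed = 42))
partial_correlation(coh$rhi, coh$cluster_fa, coh[, c("age", "sex")])
#> <stat_result> partial r = 0.4384 (df = 32, p = 0.00949, n = 36) | age, sex
```

The fitted mixture recovers the generating parameters; the threshold sits
2.33 dominant SDs above the normal-appearing-WM mode (by construction about
1% of clean WM exceeds it — the method's intrinsic tail); the measured RHI
lands within 0.01 of the simulated truth; and the cohort's partial
correlation reflects the generator's latent correlation structure (0.45
between RHI and cluster FA at n = 36).

## Analysis workflow

Numbered drivers under `analysis/` run the study chain step by step from the
repository root, writing tables to `results/` and bulky intermediate volumes
to `scratch/`:

```sh
Rscript analysis/01_simulate.R       # phantoms, PAT, connectivity, cohort
Rscript analysis/02_wmh.R            # histogram fit, threshold, volumes
Rscript analysis/03_rhi.R            # RHI + recovery sweep across ratios
Rscript analysis/04_connectivity.R   # hard segmentation + target ANOVA
Rscript analysis/05_voxelwise.R      # permutation FWE + cluster mean FA
Rscript analysis/06_cohort_stats.R   # outlier rule, summary, correlations
Rscript analysis/07_pipeline.R       # the same chain via run_pipeline()
```

`run_pipeline()` drives everything from a single YAML configuration (demo:
`inst/extdata/demo_config.yaml`); stage reports embed the exact
configuration and hash, contain no timestamps, and rerun bit-identically.

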