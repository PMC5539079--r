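#!/usr/bin/env Rscript
# Generate the full set of synthetic study inputs: a FLAIR-like phantom with
# planted hyperintense lesions, a lesion-free control phantom, a PAT
# recording around an occlusion challenge, seed-to-target connectivity
# counts, and a 36-subject cohort table. Bulky volumes/series go to
# scratch/sim/, the cohort table to results/.

suppressPackageStartupMessages(library(endowm))
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)
seed <- 20170802L

les <- list(list(center = c(48, 40, 36), radius = 7, mu = 160, sigma = 5),
            list(center = c(48, 75, 36), radius = 7, mu = 160, sigma = 5),
            list(center = c(68, 56, 36), radius = 7, mu = 160, sigma = 5))
ph <- generate_phantom(phantom_spec(lesions = les, seed = seed))
print(ph)
write_volume(ph$intensity, "scratch/sim/flair.nii.gz", ph$voxel_size)
write_volume(ph$wm_mask, "scratch/sim/wm_mask.nii.gz", ph$voxel_size)
write_volume(ph$frontal_mask, "scratch/sim/frontal_mask.nii.gz", ph$voxel_size)
write_volume(ph$truth$lesion_mask, "scratch/sim/lesion_truth.nii.gz", ph$voxel_size)
saveRDS(list(icv_mm3 = ph$icv_mm3, truth_mm3 = ph$truth$lesion_volume_mm3),
        "scratch/sim/phantom_meta.rds")
cat(sprintf("lesion phantom: %d WM voxels, %.0f mm^3 planted lesion (%.2f%% of WM)\n",
            sum(ph$wm_mask), ph$truth$lesion_volume_mm3,
            100 * ph$truth$lesion_voxels / sum(ph$wm_mask)))

ph0 <- generate_phantom(phantom_spec(secondary = list(weight = 0, mu = 0, sigma = 1),
                                     seed = seed + 1L))
write_volume(ph0$intensity, "scratch/sim/flair_null.nii.gz", ph0$voxel_size)
write_volume(ph0$wm_mask, "scratch/sim/wm_mask_null.nii.gz", ph0$voxel_size)
saveRDS(list(icv_mm3 = ph0$icv_mm3), "scratch/sim/phantom_null_meta.rds")
cat("control phantom (single-Gaussian WM) written\n")

sig <- generate_pat(pat_spec(hyperemia_ratio = 1.73, noise_sd = 0.01, seed = seed))
write_pat_csv(sig, "scratch/sim/pat.csv")
cat(sprintf("PAT recording: %d samples @ %g Hz, true post/pre ratio 1.73\n",
            length(sig$samples), sig$sample_rate))

conn <- generate_connectivity(connectivity_spec(seed = seed))
write_connectivity_csv(conn, "scratch/sim/connectivity_counts.csv",
                       "scratch/sim/connectivity_targets.csv")
cat(sprintf("connectivity: %d seed voxels x %d targets\n",
            length(conn$voxel_ids), nrow(conn$targets)))

coh <- generate_cohort(cohort_spec(seed = seed))
write_cohort_csv(coh, "results/cohort.csv")
cat(sprintf("cohort: n = %d (%d F / %d M), mean RHI %.2f, mean Trail B - A %.1f s\n",
            nrow(coh), sum(coh$sex == "F"), sum(coh$sex == "M"),
            mean(coh$rhi), mean(coh$tmt_b_s - coh$tmt_a_s)))
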