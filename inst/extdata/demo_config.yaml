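# Demo configuration: end-to-end synthetic run at desk scale.
# All thresholds are the analysis defaults (2.33 SD hyperintensity cutoff,
# 0.2 FA skeleton threshold, alpha 0.05, 2.5 SD outlier rule).
seed: 20170802
phantom:
  grid_dims: [72, 84, 54]
  brain_semiaxes: [33, 39, 25]
  wm_semiaxes: [28, 34, 21]
  frontal_plane: 57
wmh:
  k: 2.33
  n_bins: 256
pat:
  hyperemia_ratio: 1.73
  noise_sd: 0.01
connectivity:
  n_seed_voxels: 400
  n_subjects: 8
connseg:
  min_count: 1
cohort:
  "n": 36   # quoted: bare n is a YAML 1.1 boolean
voxelwise:
  n_voxels: 300
  n_perm: 500
  alpha: 0.05
  effect_voxels: 40
  effect_per_rhi: 0.06
stats:
  outlier_k: 2.5
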