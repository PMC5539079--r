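#' Load a run configuration
#'
#' A run configuration is a named list (or a YAML file holding one) with a
#' top-level `seed` and optional per-stage blocks `phantom`, `wmh`, `pat`,
#' `rhi`, `connectivity`, `connseg`, `cohort`, `skeleton`, `voxelwise`,
#' `stats`. Stage blocks override the generator/analysis defaults; every
#' stochastic stage derives its seed deterministically from the top-level
#' seed unless the block sets its own. An optional `inputs` block may name
#' external files; their existence is checked before any computation.
#'
#' @param config named list or path to a YAML file.
#' @return the configuration list, validated.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must set a top-level `seed`", call. = FALSE)
  config$seed <- as.integer(config$seed)
  known <- c("seed", "inputs", "phantom", "wmh", "pat", "rhi", "connectivity",
             "connseg", "cohort", "skeleton", "voxelwise", "stats")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  config
}

# stage seeds derived from the master seed, stable across runs
stage_seed <- function(master, offset) (master + offset) %% .Machine$integer.max

merge_block <- function(config, name, defaults = list()) {
  utils::modifyList(defaults, if (is.null(config[[name]])) list() else config[[name]])
}

write_report <- function(x, dir, name) {
  jsonlite::write_json(x, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the study's computational chain end to end on synthetic data:
#' phantom simulation and WMH quantification, PAT simulation and RHI
#' computation, connectivity simulation with hard segmentation and the
#' target ANOVA, skeleton-space voxelwise permutation analysis with cluster
#' extraction, and the cohort-level statistics battery. Each stage writes a
#' JSON report into `out_dir`; a combined `summary.json` embeds the exact
#' configuration and a content hash of it, so a rerun with the same
#' configuration is bit-reproducible (no timestamps are written into the
#' reports). A stage failure aborts the downstream stages but leaves the
#' completed reports in place.
#'
#' @param config configuration list or YAML path (see [load_config()]).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the in-memory stage results and the
#'   summary.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- load_config(config)
  if (!is.null(config$inputs)) {
    paths <- unlist(config$inputs, use.names = TRUE)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input path(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  ms <- config$seed
  results <- list()
  stages_done <- character(0)
  run_stage <- function(name, fn) {
    message("[", name, "] running")
    res <- fn()
    results[[name]] <<- res
    stages_done <<- c(stages_done, name)
    res
  }

  status <- "complete"
  failed_stage <- NULL
  err <- tryCatch({
    # --- WMH branch -------------------------------------------------------
    run_stage("wmh", function() {
      blk <- merge_block(config, "phantom", list(seed = stage_seed(ms, 1L)))
      ph <- generate_phantom(do.call(phantom_spec, blk))
      wblk <- merge_block(config, "wmh", list(k = 2.33, n_bins = 256L))
      q <- quantify_wmh(ph$intensity, ph$wm_mask, icv_mm3 = ph$icv_mm3,
                        voxel_size = ph$voxel_size, k = wblk$k,
                        n_bins = wblk$n_bins, frontal_mask = ph$frontal_mask)
      rep <- list(
        fit = q$fit[c("w1", "w2", "mu1", "mu2", "sigma1", "sigma2",
                      "dominant", "sse", "degenerate")],
        threshold = q$threshold,
        global = q$global[c("voxel_count", "volume_mm3", "volume_pct_icv")],
        frontal = q$frontal[c("voxel_count", "volume_mm3", "volume_pct_icv")],
        truth_lesion_mm3 = ph$truth$lesion_volume_mm3,
        icv_mm3 = ph$icv_mm3)
      write_report(rep, out_dir, "wmh")
      list(report = rep, quant = q)
    })

    # --- RHI branch -------------------------------------------------------
    run_stage("rhi", function() {
      blk <- merge_block(config, "pat", list(seed = stage_seed(ms, 2L)))
      sig <- generate_pat(do.call(pat_spec, blk))
      rblk <- merge_block(config, "rhi", list())
      r <- if (is.null(rblk$post_window)) compute_rhi(sig)
           else compute_rhi(sig, post_window = rblk$post_window)
      rep <- c(r[c("pre_avg", "post_avg", "rhi", "beats_pre", "beats_post",
                   "occlusion_ok")],
               list(true_ratio = do.call(pat_spec, blk)$hyperemia_ratio))
      write_report(rep, out_dir, "rhi")
      list(report = rep, result = r)
    })

    # --- connectivity branch ---------------------------------------------
    run_stage("connseg", function() {
      blk <- merge_block(config, "connectivity", list(seed = stage_seed(ms, 3L)))
      n_subj <- blk$n_subjects %||% 8L
      blk$n_subjects <- NULL
      sblk <- merge_block(config, "connseg", list(min_count = 1L))
      per_subject <- t(vapply(seq_len(n_subj), function(i) {
        b <- blk; b$seed <- stage_seed(ms, 100L + i)
        conn <- generate_connectivity(do.call(connectivity_spec, b))
        normalize_counts(hard_segment(conn, min_count = sblk$min_count))
      }, numeric(nrow(do.call(connectivity_spec, blk)$targets))))
      an <- compare_targets(per_subject)
      rep <- list(normalized_pct_mean = as.list(an$means),
                  anova = list(F = an$F, df = an$df, p = an$p,
                               error_model = an$error_model),
                  n_subjects = an$n_subjects,
                  pairwise = an$pairwise)
      write_report(rep, out_dir, "connseg")
      list(report = rep, anova = an, per_subject = per_subject)
    })

    # --- cohort + voxelwise + stats --------------------------------------
    run_stage("voxelwise", function() {
      cblk <- merge_block(config, "cohort", list(seed = stage_seed(ms, 4L)))
      cohort <- generate_cohort(do.call(cohort_spec, cblk))
      vblk <- merge_block(config, "voxelwise",
                          list(n_voxels = 300L, n_perm = 500L, alpha = 0.05,
                               effect_voxels = 40L, effect_per_rhi = 0.06,
                               seed = stage_seed(ms, 5L)))
      ds <- generate_skeleton_data(
        n_subjects = nrow(cohort), n_voxels = vblk$n_voxels, cohort = cohort,
        effect_voxels = seq_len(vblk$effect_voxels),
        effect_per_rhi = vblk$effect_per_rhi, seed = vblk$seed)
      fw <- permutation_fwe(ds, n_perm = vblk$n_perm, seed = vblk$seed)
      cl <- extract_cluster(fw, ds, alpha = vblk$alpha)
      cohort$cluster_fa <- if (cl$n_voxels > 0) cl$subject_mean_fa else cohort$cluster_fa
      rep <- list(n_skeleton_voxels = length(fw$voxels),
                  n_significant = sum(fw$p_corrected < vblk$alpha),
                  cluster_voxels = cl$n_voxels,
                  min_p_corrected = min(fw$p_corrected),
                  n_perm = fw$n_perm, df = fw$df)
      write_report(rep, out_dir, "voxelwise")
      list(report = rep, cohort = cohort, cluster = cl, fwe = fw)
    })

    run_stage("stats", function() {
      cohort <- results$voxelwise$cohort
      sblk <- merge_block(config, "stats", list(outlier_k = 2.5))
      cohort$tmt_diff_s <- suppressWarnings(tmt_score(cohort$tmt_a_s, cohort$tmt_b_s))
      keep <- exclude_outliers(cohort$tmt_diff_s, k = sblk$outlier_k)
      used <- cohort[keep, ]
      cov <- used[, c("age", "sex")]
      pc <- function(x, y) {
        s <- partial_correlation(x, y, cov)
        list(r = s$estimate, df = s$df, p = s$p, n = s$n)
      }
      sx <- sex_difference(used$rhi, used$sex)
      rep <- list(
        n_total = nrow(cohort), n_excluded_outlier = sum(!keep),
        partial = list(
          rhi_fa = pc(used$rhi, used$cluster_fa),
          fa_tmt = pc(used$cluster_fa, used$tmt_diff_s),
          rhi_tmt = pc(used$rhi, used$tmt_diff_s)),
        sex_rhi = list(F = sx$estimate, df = sx$df, p = sx$p),
        summary = summarize_cohort(used))
      write_report(rep, out_dir, "stats")
      list(report = rep, cohort = used)
    })
    NULL
  }, error = function(e) conditionMessage(e))

  if (!is.null(err)) {
    status <- "failed"
    failed_stage <- setdiff(c("wmh", "rhi", "connseg", "voxelwise", "stats"),
                            stages_done)[1]
  }
  summary <- list(status = status, stages_completed = stages_done,
                  failed_stage = failed_stage, error = err,
                  config = config, config_md5 = cfg_hash,
                  package_version = as.character(utils::packageVersion("endowm")))
  write_report(summary, out_dir, "summary")
  if (!is.null(err))
    stop("pipeline failed at stage `", failed_stage, "`: ", err, call. = FALSE)
  invisible(list(results = results, summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
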