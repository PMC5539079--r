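#' Write a volume to NIfTI
#'
#' Values are written as-is (logical masks as integers); voxel sizes go into
#' the header pixdims. Coordinates are array-indexed with no reorientation.
#'
#' @param volume numeric or logical 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size numeric(3) voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(volume)) == 3L, length(voxel_size) == 3L)
  if (is.logical(volume)) volume <- array(as.integer(volume), dim(volume))
  img <- RNifti::asNifti(volume,
                         reference = list(pixdim = c(-1, voxel_size, 0, 0, 0, 0)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file path.
#' @return list with `data` (array) and `voxel_size` (numeric(3), mm, from
#'   the header zooms).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vs) | vs <= 0))
    stop("malformed NIfTI header: non-positive pixdim in ", path, call. = FALSE)
  list(data = array(as.numeric(img), dim(img)[1:3]), voxel_size = vs)
}

#' Write a PAT signal to CSV
#'
#' Columns: `time_s`, `amplitude`, `phase` (baseline/occlusion/post).
#' @param signal a [pat_signal()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pat_csv <- function(signal, path) {
  stopifnot(inherits(signal, "pat_signal"))
  n <- length(signal$samples)
  phase <- character(n)
  for (nm in c("baseline", "occlusion", "post")) {
    iv <- signal$phases[[nm]]
    phase[iv[1]:(iv[2] - 1)] <- nm
  }
  utils::write.csv(data.frame(time_s = (seq_len(n) - 1) / signal$sample_rate,
                              amplitude = signal$samples, phase = phase),
                   path, row.names = FALSE)
  invisible(path)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Read a PAT signal from CSV
#'
#' Expects the schema written by [write_pat_csv()]; the sample rate is
#' inferred from the time column, and the phase labels must form three
#' contiguous blocks in order baseline, occlusion, post.
#'
#' @param path CSV path.
#' @return a [pat_signal()].
#' @export
read_pat_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("time_s", "amplitude", "phase"), basename(path))
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing", call. = FALSE)
  phases <- lapply(c("baseline", "occlusion", "post"), function(nm) {
    idx <- which(df$phase == nm)
    if (length(idx) == 0) stop("phase block missing: ", nm, call. = FALSE)
    if (any(diff(idx) != 1)) stop("phase block not contiguous: ", nm, call. = FALSE)
    c(idx[1], idx[length(idx)] + 1L)
  })
  names(phases) <- c("baseline", "occlusion", "post")
  pat_signal(df$amplitude, sample_rate = 1 / stats::median(dt), phases = phases)
}

#' Write connectivity counts and target table to CSV
#'
#' Long-format counts CSV (`voxel_id`, `target_name`, `streamline_count`)
#' plus a companion targets CSV (`target_name`, `mask_voxel_count`).
#'
#' @param conn a [generate_connectivity()] result.
#' @param counts_path,targets_path output CSV paths.
#' @return counts_path, invisibly.
#' @export
write_connectivity_csv <- function(conn, counts_path, targets_path) {
  long <- data.frame(
    voxel_id = rep(conn$voxel_ids, times = ncol(conn$counts)),
    target_name = rep(colnames(conn$counts), each = nrow(conn$counts)),
    streamline_count = as.vector(conn$counts))
  utils::write.csv(long, counts_path, row.names = FALSE)
  utils::write.csv(data.frame(target_name = conn$targets$name,
                              mask_voxel_count = conn$targets$mask_voxel_count),
                   targets_path, row.names = FALSE)
  invisible(counts_path)
}

#' Read connectivity counts and target table from CSV
#'
#' @param counts_path,targets_path CSV paths with the schema written by
#'   [write_connectivity_csv()].
#' @return a `seed_connectivity` object (without ground-truth assignment).
#' @export
read_connectivity_csv <- function(counts_path, targets_path) {
  long <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
  check_columns(long, c("voxel_id", "target_name", "streamline_count"),
                basename(counts_path))
  tg <- utils::read.csv(targets_path, stringsAsFactors = FALSE)
  check_columns(tg, c("target_name", "mask_voxel_count"), basename(targets_path))
  vox <- sort(unique(long$voxel_id))
  counts <- matrix(NA_real_, length(vox), nrow(tg),
                   dimnames = list(NULL, tg$target_name))
  counts[cbind(match(long$voxel_id, vox), match(long$target_name, tg$target_name))] <-
    long$streamline_count
  targets <- data.frame(name = tg$target_name,
                        mask_voxel_count = tg$mask_voxel_count)
  structure(list(voxel_ids = vox, targets = targets, counts = counts,
                 truth = NULL), class = "seed_connectivity")
}

#' Write / read a cohort table
#'
#' Schema: `id, age, sex (F/M), rhi, cluster_fa, tmt_a_s, tmt_b_s`.
#' @param cohort cohort data.frame.
#' @param path CSV path.
#' @return `path` / the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  check_columns(cohort, c("id", "age", "sex", "rhi", "tmt_a_s", "tmt_b_s"),
                "cohort table")
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("id", "age", "sex", "rhi", "tmt_a_s", "tmt_b_s"),
                basename(path))
  df$sex <- factor(df$sex, levels = c("F", "M"))
  df
}
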