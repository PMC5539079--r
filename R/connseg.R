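#' Hard segmentation of a seed cluster by strongest target connectivity
#'
#' Assigns each seed voxel to the target with the strictly largest streamline
#' count, provided that count reaches `min_count`. Voxels whose largest count
#' is tied across targets, or below `min_count`, are left `UNASSIGNED`
#' (deterministic; set `ties = "first"` to assign ties to the first tied
#' target in table order instead).
#'
#' @param conn a [generate_connectivity()] result, or any list with a
#'   `counts` matrix (voxels x targets, named columns) and a `targets`
#'   data.frame with `name` and `mask_voxel_count`.
#' @param min_count minimum winning count required for assignment.
#' @param ties `"unassigned"` (default) or `"first"`.
#' @return An object of class `segmentation_result`: `assignment` (character
#'   per voxel, `"UNASSIGNED"` allowed), `per_target_voxels` (named count
#'   vector over all targets), `unassigned`, `targets`, `n_voxels`.
#' @export
hard_segment <- function(conn, min_count = 1L, ties = c("unassigned", "first")) {
  ties <- match.arg(ties)
  counts <- conn$counts
  targets <- conn$targets
  stopifnot(is.matrix(counts), nrow(counts) >= 1L, ncol(counts) >= 2L,
            identical(colnames(counts), targets$name))
  if (anyNA(counts)) {
    bad <- which(rowSums(is.na(counts)) > 0)[1]
    stop(sprintf("voxel %d has missing counts", bad), call. = FALSE)
  }
  top <- apply(counts, 1L, max)
  assignment <- rep("UNASSIGNED", nrow(counts))
  for (v in seq_len(nrow(counts))) {
    if (top[v] < min_count) next
    winners <- which(counts[v, ] == top[v])
    if (length(winners) == 1L || ties == "first")
      assignment[v] <- targets$name[winners[1L]]
  }
  per_target <- vapply(targets$name, function(nm) sum(assignment == nm), 0L)
  structure(list(assignment = assignment, per_target_voxels = per_target,
                 unassigned = sum(assignment == "UNASSIGNED"),
                 targets = targets, n_voxels = nrow(counts),
                 min_count = min_count),
            class = "segmentation_result")
}

#' Normalize per-target assigned voxel counts by target mask size
#'
#' Each target's assigned seed-voxel count is expressed as a percentage of
#' its target mask size: `100 * assigned_voxels / mask_voxel_count`. This
#' controls for differences in cortical target size.
#'
#' @param seg a [hard_segment()] result.
#' @return named numeric vector of normalized percentages, one per target.
#' @examples
#' # 17 assigned voxels against a 1000-voxel target mask -> 1.7
#' @export
normalize_counts <- function(seg) {
  stopifnot(inherits(seg, "segmentation_result"))
  msk <- seg$targets$mask_voxel_count
  if (any(msk <= 0))
    stop("target mask sizes must be positive: ",
         paste(seg$targets$name[msk <= 0], collapse = ", "), call. = FALSE)
  stats::setNames(100 * seg$per_target_voxels / msk, seg$targets$name)
}

#' Compare normalized connectivity percentages across targets
#'
#' Omnibus ANOVA for a target effect over subjects' normalized-percentage
#' vectors, followed (when the omnibus test is significant at `alpha`) by
#' pairwise comparisons with Bonferroni correction (raw p times the number of
#' pairs, capped at 1). The default error model is the repeated-measures
#' layout with subjects as blocks, giving df `(k - 1, (k - 1)(n - 1))` for k
#' targets and n subjects; `error = "between"` treats rows as independent
#' groups instead. Degrees of freedom are always reported explicitly.
#'
#' @param per_subject numeric matrix (subjects x targets, named columns) or a
#'   list of equal-length named vectors.
#' @param error `"rm"` (repeated measures, default) or `"between"`.
#' @param alpha significance level gating the pairwise table.
#' @return An object of class `target_anova`: `F`, `df` (length 2), `p`,
#'   `means` (per-target), `error_model`, `n_subjects`, `n_targets`,
#'   `pairwise` (data.frame or NULL), `note`.
#' @export
compare_targets <- function(per_subject, error = c("rm", "between"), alpha = 0.05) {
  error <- match.arg(error)
  if (is.list(per_subject) && !is.data.frame(per_subject)) {
    lens <- lengths(per_subject)
    if (length(unique(lens)) != 1L)
      stop("per-subject vectors have unequal lengths", call. = FALSE)
    per_subject <- do.call(rbind, per_subject)
  }
  per_subject <- as.matrix(per_subject)
  n <- nrow(per_subject); k <- ncol(per_subject)
  stopifnot(n >= 2L, k >= 2L, !anyNA(per_subject))
  tnames <- colnames(per_subject)
  if (is.null(tnames)) tnames <- paste0("T", seq_len(k))

  long <- data.frame(
    value = as.vector(per_subject),
    subject = factor(rep(seq_len(n), times = k)),
    target = factor(rep(tnames, each = n), levels = tnames))

  if (error == "rm") {
    ss_target <- n * sum((colMeans(per_subject) - mean(per_subject))^2)
    ss_subject <- k * sum((rowMeans(per_subject) - mean(per_subject))^2)
    ss_total <- sum((per_subject - mean(per_subject))^2)
    ss_err <- ss_total - ss_target - ss_subject
    df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  } else {
    ss_target <- n * sum((colMeans(per_subject) - mean(per_subject))^2)
    ss_err <- sum(sweep(per_subject, 2L, colMeans(per_subject))^2)
    df1 <- k - 1L; df2 <- k * (n - 1L)
  }
  ms_target <- ss_target / df1
  ms_err <- ss_err / df2

  note <- NULL
  if (ms_err <= .Machine$double.eps * max(1, ms_target)) {
    if (ms_target <= .Machine$double.eps) {
      Fv <- NA_real_; p <- NA_real_
      note <- "no variance in either effect or error; no difference detectable"
    } else {
      Fv <- Inf; p <- 0
      note <- "zero error variance with a nonzero target effect"
    }
  } else {
    Fv <- ms_target / ms_err
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }

  pairwise <- NULL
  if (isTRUE(p < alpha)) {
    pairs <- utils::combn(tnames, 2L)
    n_pairs <- ncol(pairs)
    pairwise <- data.frame(a = pairs[1, ], b = pairs[2, ],
                           mean_diff = NA_real_, p_raw = NA_real_,
                           p_bonferroni = NA_real_)
    for (i in seq_len(n_pairs)) {
      xa <- per_subject[, pairs[1, i]]; xb <- per_subject[, pairs[2, i]]
      tt <- if (error == "rm") {
        d <- xa - xb
        if (stats::sd(d) == 0) list(p.value = if (mean(d) == 0) 1 else 0)
        else stats::t.test(d)
      } else stats::t.test(xa, xb, var.equal = TRUE)
      pairwise$mean_diff[i] <- mean(xa) - mean(xb)
      pairwise$p_raw[i] <- tt$p.value
      pairwise$p_bonferroni[i] <- min(1, tt$p.value * n_pairs)
    }
  }

  structure(list(F = Fv, df = c(df1, df2), p = p,
                 means = stats::setNames(colMeans(per_subject), tnames),
                 error_model = error, n_subjects = n, n_targets = k,
                 pairwise = pairwise, note = note),
            class = "target_anova")
}

#' @export
print.target_anova <- function(x, ...) {
  cat(sprintf("<target_anova> F(%d,%d) = %s, p = %s [%s]\n",
              x$df[1], x$df[2], format(x$F, digits = 4),
              format.pval(x$p, digits = 3), x$error_model))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  if (!is.null(x$pairwise))
    cat("  ", sum(x$pairwise$p_bonferroni < 0.05),
        "of", nrow(x$pairwise), "Bonferroni pairwise comparisons < 0.05\n")
  invisible(x)
}
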