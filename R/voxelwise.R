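#' Skeleton mask from mean FA
#'
#' The analysis skeleton keeps voxels whose across-subject mean fractional
#' anisotropy strictly exceeds `threshold` (default 0.2, the conventional
#' white-matter skeleton cutoff).
#'
#' @param mean_fa numeric vector/array of per-voxel mean FA in `[0, 1]`.
#' @param threshold FA cutoff (strict `>`).
#' @return logical mask, same shape as `mean_fa`.
#' @export
build_skeleton <- function(mean_fa, threshold = 0.2) {
  if (any(mean_fa < 0 | mean_fa > 1, na.rm = TRUE))
    stop("mean FA must lie in [0, 1]", call. = FALSE)
  mean_fa > threshold
}

#' Assemble a skeleton-space FA dataset
#'
#' Bundles the subjects-by-voxels FA matrix with the per-subject predictor
#' (RHI) and nuisance covariates (age, sex), and derives the skeleton mask
#' from the mean-FA map.
#'
#' @param fa numeric matrix, subjects x voxels, values in `[0, 1]`.
#' @param rhi numeric per-subject predictor.
#' @param age numeric per-subject age (years).
#' @param sex per-subject sex, coded 0/1 or a factor with two levels (first
#'   level coded 0).
#' @param fa_threshold skeleton threshold passed to [build_skeleton()].
#' @return An object of class `skeleton_dataset`.
#' @export
skeleton_dataset <- function(fa, rhi, age, sex, fa_threshold = 0.2) {
  fa <- as.matrix(fa)
  n <- nrow(fa)
  if (is.factor(sex) || is.character(sex)) sex <- as.integer(factor(sex)) - 1L
  stopifnot(length(rhi) == n, length(age) == n, length(sex) == n,
            !anyNA(fa), !anyNA(rhi), !anyNA(age), !anyNA(sex))
  if (any(fa < 0 | fa > 1)) stop("FA values must lie in [0, 1]", call. = FALSE)
  mean_fa <- colMeans(fa)
  structure(list(fa = fa, mean_fa = mean_fa,
                 skeleton_mask = build_skeleton(mean_fa, fa_threshold),
                 rhi = as.numeric(rhi), age = as.numeric(age),
                 sex = as.numeric(sex), fa_threshold = fa_threshold),
            class = "skeleton_dataset")
}

#' Generate a synthetic skeleton-space FA dataset
#'
#' Simulates per-subject FA over skeleton voxels around a common mean-FA
#' profile, with an optional planted linear RHI effect in a designated voxel
#' block. Values are clamped to (0.01, 0.99) to respect the FA range.
#'
#' @param n_subjects,n_voxels dataset size.
#' @param cohort optional data.frame with columns `rhi`, `age`, `sex`
#'   (defaults to a fresh [generate_cohort()] draw of size `n_subjects`).
#' @param base_fa,noise_sd mean FA level and per-voxel residual SD.
#' @param effect_voxels integer indices of voxels carrying the planted
#'   effect (empty = global null).
#' @param effect_per_rhi FA change per unit RHI in the effect voxels.
#' @param seed integer RNG seed.
#' @return A `skeleton_dataset` with attribute `effect_voxels`.
#' @export
generate_skeleton_data <- function(n_subjects = 36L, n_voxels = 500L,
                                   cohort = NULL, base_fa = 0.5,
                                   noise_sd = 0.04, effect_voxels = integer(0),
                                   effect_per_rhi = 0, seed = 1L) {
  with_seed(seed, {
    if (is.null(cohort)) {
      sp <- cohort_spec(n = n_subjects, seed = sample.int(2^30, 1))
      cohort <- generate_cohort(sp)
    }
    stopifnot(nrow(cohort) == n_subjects)
    profile <- base_fa + stats::rnorm(n_voxels, 0, 0.02)
    fa <- matrix(stats::rnorm(n_subjects * n_voxels, 0, noise_sd),
                 n_subjects, n_voxels)
    fa <- sweep(fa, 2L, profile, `+`)
    if (length(effect_voxels) > 0 && effect_per_rhi != 0) {
      shift <- outer(cohort$rhi - mean(cohort$rhi), rep(effect_per_rhi, length(effect_voxels)))
      fa[, effect_voxels] <- fa[, effect_voxels] + shift
    }
    fa <- pmin(pmax(fa, 0.01), 0.99)
  })
  ds <- skeleton_dataset(fa, rhi = cohort$rhi, age = cohort$age, sex = cohort$sex)
  attr(ds, "effect_voxels") <- effect_voxels
  ds
}

# design matrices: full [1, rhi, age, sex] and nuisance-only [1, age, sex]
design_matrices <- function(data) {
  X <- cbind(intercept = 1, rhi = data$rhi, age = data$age, sex = data$sex)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  list(X = X, Z = X[, c("intercept", "age", "sex"), drop = FALSE])
}

# t statistics for the RHI coefficient, all voxels at once (OLS)
ols_rhi_t <- function(Y, X) {
  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- colSums(resid^2) / df
  xtxinv <- chol2inv(qr.R(qrX))
  v <- xtxinv[2, 2]
  b <- beta[2, ]
  # numerically-zero residual variance: either a constant voxel (t = 0) or a
  # perfect noise-free fit (flagged as infinite t)
  scale_ref <- pmax(colSums(Y^2) / nrow(Y), .Machine$double.eps)
  zero_var <- s2 < scale_ref * .Machine$double.eps^0.75
  se <- sqrt(s2 * v)
  t <- ifelse(zero_var,
              ifelse(abs(b) < sqrt(scale_ref) * 1e-7, 0, Inf * sign(b)),
              b / se)
  list(t = unname(t), df = df)
}

#' Voxelwise covariate-adjusted regression of FA on RHI
#'
#' At every skeleton voxel, ordinary least squares of FA on an intercept,
#' RHI, age and sex; returns the t statistic of the RHI coefficient. A voxel
#' with no FA variance across subjects gets t = 0; a perfect noise-free fit
#' is flagged with an infinite t.
#'
#' @param data a [skeleton_dataset()].
#' @return list with `t` (per skeleton voxel), `df`, `voxels` (column
#'   indices of the skeleton voxels).
#' @export
voxelwise_regression <- function(data) {
  stopifnot(inherits(data, "skeleton_dataset"))
  dm <- design_matrices(data)
  if (nrow(dm$X) <= ncol(dm$X) + 1L)
    stop("need more subjects than regressors + 1", call. = FALSE)
  vox <- which(data$skeleton_mask)
  Y <- data$fa[, vox, drop = FALSE]
  res <- ols_rhi_t(Y, dm$X)
  list(t = res$t, df = res$df, voxels = vox)
}

# all permutations of 1..n as a matrix (rows = permutations)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' Permutation-based family-wise-error-corrected p-values
#'
#' Freedman-Lane permutation of the nuisance-residualized data with
#' max-statistic FWE control: FA and the RHI predictor are residualized
#' against the nuisance design (intercept, age, sex); permuted datasets
#' permute the FA residuals (re-residualizing after permutation) and the
#' maximum |t| over skeleton voxels is recorded; the corrected p at voxel v
#' is the proportion of permutations whose maximum |t| reaches the observed
#' |t(v)|, with the add-one convention for sampled permutations. When
#' `n_perm` is at least the number of distinct subject orderings (n!), all
#' orderings are enumerated exactly instead (with a warning).
#'
#' @param data a [skeleton_dataset()].
#' @param n_perm number of permutations (>= 100 for sampled permutations).
#' @param seed integer seed for the permutation stream.
#' @param alternative `"two.sided"` (default) uses max |t|; `"greater"` uses
#'   max t for a directional positive-association test.
#' @return An object of class `voxelwise_result`: `t`, `df`, `p_corrected`
#'   and `p_uncorrected` (per skeleton voxel; the uncorrected value compares
#'   each voxel's statistic with its own permutation distribution, and is
#'   never above the corrected one), `voxels`, `max_null` (the null
#'   max-statistic sample), `n_perm`, `exhaustive`, `alternative`.
#' @export
permutation_fwe <- function(data, n_perm = 5000L, seed = 1L,
                            alternative = c("two.sided", "greater")) {
  stopifnot(inherits(data, "skeleton_dataset"))
  alternative <- match.arg(alternative)
  n <- nrow(data$fa)
  n_distinct <- factorial(n)
  exhaustive <- is.finite(n_distinct) && n_perm >= n_distinct
  if (!exhaustive && n_perm < 100L)
    stop("`n_perm` must be >= 100 for sampled permutations", call. = FALSE)

  dm <- design_matrices(data)
  vox <- which(data$skeleton_mask)
  Y <- data$fa[, vox, drop = FALSE]
  obs <- ols_rhi_t(Y, dm$X)
  df <- obs$df

  Z <- dm$Z
  Hz <- Z %*% chol2inv(chol(crossprod(Z))) %*% t(Z)
  Rz <- diag(n) - Hz
  E <- Rz %*% Y                       # nuisance-residualized FA
  xres <- as.vector(Rz %*% data$rhi)  # residualized predictor
  xnorm <- sqrt(sum(xres^2))
  if (xnorm == 0) stop("predictor is collinear with the nuisance design", call. = FALSE)

  # t from partial correlation between residualized predictor and FA;
  # identical to the full-model OLS t for the RHI coefficient
  perm_t <- function(Ep) {
    num <- as.vector(crossprod(Ep, xres))
    den <- sqrt(colSums(Ep^2)) * xnorm
    r <- ifelse(den > 0, num / den, 0)
    r <- pmin(pmax(r, -1), 1)
    ifelse(abs(r) >= 1, Inf * sign(r), r * sqrt(df) / sqrt(1 - r^2))
  }

  stat <- function(t) if (alternative == "two.sided") abs(t) else t

  obs_stat <- stat(obs$t)
  # scale-aware tolerance so structural ties are counted as ties regardless of
  # the floating-point route that produced the statistic
  tie_eps <- function(tv) 1e-8 * (1 + abs(tv))
  vox_count <- integer(length(obs_stat))  # per-voxel exceedance counter
  if (exhaustive) {
    warning(sprintf("n_perm (%d) >= distinct orderings (%d); enumerating exactly",
                    n_perm, n_distinct))
    perms <- all_permutations(n)
    max_null <- numeric(nrow(perms))
    for (i in seq_len(nrow(perms))) {
      tp <- stat(perm_t(Rz %*% E[perms[i, ], , drop = FALSE]))
      max_null[i] <- max(tp)
      vox_count <- vox_count + (tp >= obs_stat - tie_eps(obs_stat))
    }
    p_corr <- vapply(obs_stat, function(tv) mean(max_null >= tv - tie_eps(tv)), 0)
    p_unc <- vox_count / nrow(perms)
  } else {
    max_null <- numeric(n_perm)
    with_seed(seed, {
      for (i in seq_len(n_perm)) {
        pm <- sample.int(n)
        tp <- stat(perm_t(Rz %*% E[pm, , drop = FALSE]))
        max_null[i] <- max(tp)
        vox_count <- vox_count + (tp >= obs_stat - tie_eps(obs_stat))
      }
    })
    p_corr <- vapply(obs_stat,
                     function(tv) (1 + sum(max_null >= tv - tie_eps(tv))) / (n_perm + 1), 0)
    p_unc <- (1 + vox_count) / (n_perm + 1)
  }

  structure(list(t = obs$t, df = df, p_corrected = p_corr,
                 p_uncorrected = p_unc, voxels = vox,
                 max_null = max_null, n_perm = length(max_null),
                 exhaustive = exhaustive, alternative = alternative),
            class = "voxelwise_result")
}

#' Extract the significant cluster and per-subject cluster mean FA
#'
#' The cluster is the set of skeleton voxels with corrected p below `alpha`;
#' each subject's FA is averaged over that cluster (the value that feeds the
#' cohort-level correlation analyses). An empty cluster yields an empty
#' result object, not an error.
#'
#' @param result a [permutation_fwe()] result.
#' @param data the matching [skeleton_dataset()].
#' @param alpha corrected-p threshold (default 0.05).
#' @return list with `cluster_voxels` (column indices), `n_voxels`,
#'   `subject_mean_fa` (length n, NA when the cluster is empty).
#' @export
extract_cluster <- function(result, data, alpha = 0.05) {
  stopifnot(inherits(result, "voxelwise_result"),
            inherits(data, "skeleton_dataset"))
  sel <- result$p_corrected < alpha
  vox <- result$voxels[sel]
  if (length(vox) == 0L)
    return(list(cluster_voxels = integer(0), n_voxels = 0L,
                subject_mean_fa = rep(NA_real_, nrow(data$fa))))
  list(cluster_voxels = vox, n_voxels = length(vox),
       subject_mean_fa = rowMeans(data$fa[, vox, drop = FALSE]))
}
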