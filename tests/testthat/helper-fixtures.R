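# Small fixtures shared across test files. Everything is generated in code;
# no data files are read.

# a phantom small enough for per-test fitting (~20k WM voxels)
small_phantom_spec <- function(..., seed = 1L) {
  phantom_spec(grid_dims = c(48L, 56L, 36L),
               brain_semiaxes = c(21, 25, 16),
               wm_semiaxes = c(18, 21, 13),
               frontal_plane = 38L,
               seed = seed, ...)
}

# lesion-free phantom drawing WM from a single Gaussian
null_phantom_spec <- function(..., seed = 1L) {
  phantom_spec(secondary = list(weight = 0, mu = 0, sigma = 1), seed = seed, ...)
}

# hand-rolled cohort covariates for regression toys
toy_covariates <- function(n, seed = 7L) {
  set.seed(seed)
  list(age = round(rnorm(n, 64, 3), 1),
       sex = rep_len(c(0, 1), n),
       rhi = round(runif(n, 0.8, 2.6), 2))
}

# independent Freedman-Lane + max-statistic oracle via per-voxel lm();
# enumerates every subject ordering with pracma::perms
exhaustive_fwe_oracle <- function(fa, rhi, age, sex) {
  n <- nrow(fa)
  Z <- cbind(1, age, sex)
  Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  E <- fa - Hz %*% fa
  fitted_z <- Hz %*% fa
  t_of <- function(Y) {
    apply(Y, 2, function(y) {
      fit <- stats::lm(y ~ rhi + age + sex)
      stats::coef(summary(fit))["rhi", "t value"]
    })
  }
  t_obs <- abs(t_of(fa))
  perms <- pracma::perms(seq_len(n))
  max_null <- apply(perms, 1, function(pm) {
    max(abs(t_of(E[pm, , drop = FALSE] + fitted_z)))
  })
  vapply(t_obs, function(tv) mean(max_null >= tv - 1e-8 * (1 + abs(tv))), 0)
}
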