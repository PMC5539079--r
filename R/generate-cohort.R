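#' Specification for a synthetic study cohort
#'
#' Generates subject tables with the structure of an older-adult
#' endothelial-function study: age, sex, reactive hyperemia index (RHI),
#' mean fractional anisotropy in a white-matter cluster, and Trail Making
#' Test times. The three analysis variables (RHI, cluster FA, Trail B - Trail
#' A difference) are coupled through a latent Gaussian copula whose
#' covariance is configurable, then mapped to their marginals: Gaussian for
#' RHI and the Trail difference, a moment-matched Beta for FA so that FA is
#' guaranteed to fall in (0, 1). Trail B is Trail A plus the difference.
#' Default moments follow the cohort scale of a 36-subject aging study
#' (age 63.7 (2.9) years, RHI 1.73 (0.5), Trail B - Trail A 35.4 (15.5) s,
#' 23 of 36 female).
#'
#' @param n number of subjects.
#' @param age c(mean, sd) in years.
#' @param sex_ratio fraction female.
#' @param latent_covariance 3x3 symmetric positive-definite covariance of the
#'   latent (RHI, clusterFA, TMTdiff) triple; the diagonal carries the
#'   marginal variances, the off-diagonal the dependence.
#' @param rhi_mean,fa_mean,tmt_a,tmt_diff_mean marginal location parameters:
#'   `tmt_a` is c(mean, sd) in seconds for Trail A (independent of the latent
#'   triple), the others are scalar means whose SDs come from
#'   `latent_covariance`.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 36L,
                        age = c(63.7, 2.9),
                        sex_ratio = 23 / 36,
                        latent_covariance = default_latent_covariance(),
                        rhi_mean = 1.73,
                        fa_mean = 0.5,
                        tmt_a = c(30, 10),
                        tmt_diff_mean = 35.4,
                        seed = 1L) {
  stopifnot(n >= 1L, length(age) == 2L, age[2] >= 0,
            sex_ratio >= 0, sex_ratio <= 1,
            is.matrix(latent_covariance), all(dim(latent_covariance) == 3L),
            isTRUE(all.equal(latent_covariance, t(latent_covariance))),
            length(tmt_a) == 2L, all(tmt_a > 0),
            fa_mean > 0, fa_mean < 1)
  ev <- eigen(latent_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("latent_covariance is not positive definite (eigenvalues: ",
         paste(signif(ev, 4), collapse = ", "), ")", call. = FALSE)
  fa_var <- latent_covariance[2, 2]
  if (fa_var >= fa_mean * (1 - fa_mean))
    stop("FA variance too large for a Beta marginal with mean ", fa_mean, call. = FALSE)
  structure(list(n = as.integer(n), age = age, sex_ratio = sex_ratio,
                 latent_covariance = latent_covariance, rhi_mean = rhi_mean,
                 fa_mean = fa_mean, tmt_a = tmt_a,
                 tmt_diff_mean = tmt_diff_mean, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default latent covariance of (RHI, cluster FA, Trail B - Trail A)
#'
#' SDs 0.5 (RHI), 0.08 (FA), 15.5 s (Trail difference) with correlations
#' r(RHI, FA) = 0.45, r(RHI, TMTdiff) = -0.36, r(FA, TMTdiff) = -0.445,
#' i.e. better endothelial function goes with higher FA and both go with
#' smaller executive switching cost.
#'
#' @return 3x3 covariance matrix.
#' @export
default_latent_covariance <- function() {
  sds <- c(rhi = 0.5, fa = 0.08, tmtdiff = 15.5)
  R <- matrix(c(1, 0.45, -0.36,
                0.45, 1, -0.445,
                -0.36, -0.445, 1), 3, 3,
              dimnames = list(names(sds), names(sds)))
  diag(sds) %*% R %*% diag(sds)
}

# one latent draw mapped to observed marginals; n x 3 matrix (rhi, fa, tmtdiff)
draw_latent <- function(n, spec) {
  S <- spec$latent_covariance
  L <- chol(S)
  z <- matrix(stats::rnorm(n * 3), n, 3) %*% L  # covariance S, mean 0
  rhi <- spec$rhi_mean + z[, 1]
  # FA: Gaussian -> uniform -> Beta(mean fa_mean, var S[2,2])
  u <- stats::pnorm(z[, 2] / sqrt(S[2, 2]))
  m <- spec$fa_mean; v <- S[2, 2]
  nu <- m * (1 - m) / v - 1
  fa <- stats::qbeta(u, m * nu, (1 - m) * nu)
  tmtdiff <- spec$tmt_diff_mean + z[, 3]
  cbind(rhi = rhi, fa = fa, tmtdiff = tmtdiff)
}

#' Generate a synthetic cohort table
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `id`, `age`, `sex` (factor F/M), `rhi`,
#'   `cluster_fa`, `tmt_a_s`, `tmt_b_s`. Rows violating positivity (negative
#'   times or non-positive RHI, vanishingly rare at the default moments) are
#'   redrawn. Sample correlations converge to the latent targets as n grows.
#' @examples
#' head(generate_cohort(cohort_spec(seed = 42)))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    lat <- draw_latent(n, spec)
    tmt_a <- stats::rnorm(n, spec$tmt_a[1], spec$tmt_a[2])
    bad <- which(lat[, 1] <= 0 | tmt_a <= 0 | tmt_a + lat[, 3] <= 0)
    tries <- 0L
    while (length(bad) > 0 && tries < 100L) {
      lat[bad, ] <- draw_latent(length(bad), spec)
      tmt_a[bad] <- stats::rnorm(length(bad), spec$tmt_a[1], spec$tmt_a[2])
      bad <- which(lat[, 1] <= 0 | tmt_a <= 0 | tmt_a + lat[, 3] <= 0)
      tries <- tries + 1L
    }
    if (length(bad) > 0)
      stop("could not generate a cohort with positive times/RHI; check spec moments",
           call. = FALSE)
    sex <- factor(ifelse(stats::runif(n) < spec$sex_ratio, "F", "M"),
                  levels = c("F", "M"))
    age <- stats::rnorm(n, spec$age[1], spec$age[2])
    out <- data.frame(id = sprintf("S%03d", seq_len(n)), age = age, sex = sex,
                      rhi = lat[, 1], cluster_fa = lat[, 2],
                      tmt_a_s = tmt_a, tmt_b_s = tmt_a + lat[, 3])
  })
  attr(out, "spec") <- spec
  out
}
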