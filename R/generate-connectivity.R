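#' Specification for synthetic seed-to-target connectivity counts
#'
#' Emulates the per-voxel streamline counts produced by probabilistic
#' tractography between a white-matter seed cluster and a set of cortical
#' target masks. Each seed voxel has one intended winning target; its count
#' toward that target is centred on the target's `mean_count` while all other
#' targets receive low off-target background counts. In `"exact"` mode counts
#' are noise-free (winner gets `mean_count`, others zero) so downstream hard
#' segmentation must recover the truth exactly; in `"stochastic"` mode counts
#' are drawn from Poisson (or negative-binomial when a finite `dispersion`
#' column is present) distributions.
#'
#' The default seven targets mirror a frontal/sensorimotor target set
#' (superior frontal gyrus, frontal pole, premotor, middle and inferior
#' frontal gyri, pre- and postcentral gyri) with seed-share pattern dominated
#' by the superior frontal gyrus and frontal pole.
#'
#' @param n_seed_voxels number of seed-cluster voxels.
#' @param targets data.frame with columns `name`, `mask_voxel_count`,
#'   `mean_count`, optional `dispersion` (negative-binomial size; `Inf` =
#'   Poisson) and optional `share` (intended fraction of seed voxels assigned
#'   to the target; defaults to equal shares).
#' @param assignment_truth optional character vector (length
#'   `n_seed_voxels`) of intended winners; overrides `share`-based sampling.
#' @param mode `"stochastic"` or `"exact"`.
#' @param offtarget_mean mean background count a voxel sends to each
#'   non-winning target in stochastic mode.
#' @param seed integer RNG seed.
#' @return An object of class `connectivity_spec`.
#' @export
connectivity_spec <- function(n_seed_voxels = 800L,
                              targets = default_targets(),
                              assignment_truth = NULL,
                              mode = c("stochastic", "exact"),
                              offtarget_mean = 1,
                              seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(targets),
            all(c("name", "mask_voxel_count", "mean_count") %in% names(targets)),
            nrow(targets) >= 2L, !anyDuplicated(targets$name),
            all(targets$mask_voxel_count > 0), all(targets$mean_count >= 0),
            n_seed_voxels >= 1L, offtarget_mean >= 0)
  if (!is.null(assignment_truth)) {
    stopifnot(length(assignment_truth) == n_seed_voxels,
              all(assignment_truth %in% targets$name))
  }
  structure(list(n_seed_voxels = as.integer(n_seed_voxels), targets = targets,
                 assignment_truth = assignment_truth, mode = mode,
                 offtarget_mean = offtarget_mean, seed = as.integer(seed)),
            class = "connectivity_spec")
}

#' Default cortical target table for connectivity simulation
#'
#' Seven frontal/sensorimotor targets with mask sizes on the scale of 1-mm
#' cortical ROI masks and seed shares concentrated on the superior frontal
#' gyrus and frontal pole.
#'
#' @return data.frame with columns name, mask_voxel_count, mean_count, share.
#' @export
default_targets <- function() {
  d <- data.frame(
    name = c("SFG", "FP", "PrM", "MFG", "IFG", "PrCG", "PoCG"),
    mask_voxel_count = c(25000L, 25000L, 15000L, 20000L, 12000L, 18000L, 16000L),
    mean_count = 100,
    share = c(427, 248, 70, 54, 16, 7, 2))
  d$share <- d$share / sum(d$share)
  d
}

#' Generate synthetic seed-to-target streamline counts
#'
#' @param spec a [connectivity_spec()].
#' @return An object of class `seed_connectivity`: list with `voxel_ids`,
#'   `targets` (the target table), `counts` (voxels x targets integer
#'   matrix) and `truth` (intended winner per voxel).
#' @export
generate_connectivity <- function(spec) {
  stopifnot(inherits(spec, "connectivity_spec"))
  tg <- spec$targets
  k <- nrow(tg)
  n <- spec$n_seed_voxels
  disp <- if ("dispersion" %in% names(tg)) tg$dispersion else rep(Inf, k)

  with_seed(spec$seed, {
    truth <- spec$assignment_truth
    if (is.null(truth)) {
      share <- if ("share" %in% names(tg)) tg$share else rep(1 / k, k)
      truth <- sample(tg$name, n, replace = TRUE, prob = share)
    }
    counts <- matrix(0L, nrow = n, ncol = k, dimnames = list(NULL, tg$name))
    for (j in seq_len(k)) {
      is_winner <- truth == tg$name[j]
      if (spec$mode == "exact") {
        counts[is_winner, j] <- max(1L, as.integer(round(tg$mean_count[j])))
      } else {
        draw <- function(nn, mu) {
          if (nn == 0L) return(integer(0))
          if (is.finite(disp[j])) stats::rnbinom(nn, mu = mu, size = disp[j])
          else stats::rpois(nn, mu)
        }
        counts[is_winner, j] <- draw(sum(is_winner), tg$mean_count[j])
        counts[!is_winner, j] <- draw(sum(!is_winner), spec$offtarget_mean)
      }
    }
  })
  structure(list(voxel_ids = seq_len(n), targets = tg,
                 counts = counts, truth = truth),
            class = "seed_connectivity")
}
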