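#' Intensity histogram of masked voxels
#'
#' Bins the intensities of the voxels selected by `mask` into `n_bins` equal
#' bins spanning the masked intensity range. This is the object the
#' two-Gaussian model is fitted to.
#'
#' @param volume numeric 3D array (or vector) of intensities.
#' @param mask logical/0-1 array of the same dimensions.
#' @param n_bins number of bins (default 256, standard for MR intensity
#'   histograms).
#' @return An object of class `intensity_histogram`: `bin_edges` (length
#'   `n_bins + 1`), `mids`, `counts`, `n_voxels`.
#' @export
build_histogram <- function(volume, mask, n_bins = 256L) {
  if (!all(dim(volume) == dim(mask)) || length(volume) != length(mask))
    stop("`volume` and `mask` must have identical dimensions", call. = FALSE)
  mask <- as.logical(mask)
  if (!any(mask)) stop("`mask` selects no voxels", call. = FALSE)
  stopifnot(n_bins >= 2)
  x <- as.numeric(volume)[mask]
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)  # constant input: one central bin
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins),
                     nbins = n_bins)
  structure(list(bin_edges = edges, mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, n_voxels = length(x)),
            class = "intensity_histogram")
}

# density heights of the histogram (integrates to 1)
hist_density <- function(hist) {
  bw <- diff(hist$bin_edges)
  hist$counts / (hist$n_voxels * bw)
}

# single-Gaussian fit from count-weighted histogram moments with Sheppard's
# correction for grouping (the classical, near-efficient grouped-data
# estimator); sse reported against the histogram density for comparability
fit_single_gaussian_moments <- function(mids, counts, dens, bw, w) {
  mu <- stats::weighted.mean(mids, counts)
  v <- stats::weighted.mean((mids - mu)^2, counts) - bw^2 / 12
  sigma <- sqrt(max(v, (bw / 10)^2))
  list(mu = mu, sigma = sigma,
       sse = sum(w * (dens - stats::dnorm(mids, mu, sigma))^2))
}

# 1D two-means split of histogram mass (Lloyd iterations, count-weighted)
split_histogram_mass <- function(mids, counts) {
  c1 <- stats::weighted.mean(mids, counts)
  spread <- sqrt(stats::weighted.mean((mids - c1)^2, counts))
  ctr <- c(c1 - spread, c1 + spread)
  for (i in 1:50) {
    assign2 <- abs(mids - ctr[2]) < abs(mids - ctr[1])
    new <- c(
      if (any(!assign2 & counts > 0)) stats::weighted.mean(mids[!assign2], counts[!assign2]) else ctr[1],
      if (any(assign2 & counts > 0)) stats::weighted.mean(mids[assign2], counts[assign2]) else ctr[2])
    if (max(abs(new - ctr)) < 1e-10) break
    ctr <- new
  }
  assign2 <- abs(mids - ctr[2]) < abs(mids - ctr[1])
  g1 <- list(w = sum(counts[!assign2]) / sum(counts),
             mu = ctr[1],
             sigma = sqrt(max(stats::weighted.mean((mids[!assign2] - ctr[1])^2,
                                                   counts[!assign2]), 1e-12)))
  g2 <- list(mu = ctr[2],
             sigma = sqrt(max(stats::weighted.mean((mids[assign2] - ctr[2])^2,
                                                   counts[assign2]), 1e-12)))
  list(g1 = g1, g2 = g2)
}

#' Fit a two-component Gaussian mixture to an intensity histogram
#'
#' Least-squares fit of `w * N(mu1, sigma1) + (1 - w) * N(mu2, sigma2)` to
#' the normalized histogram density via Levenberg-Marquardt, initialized from
#' a count-weighted two-means split of the histogram mass with five jittered
#' restarts (deterministic). The dominant component is the one with the
#' larger mixing weight; an exact tie is broken toward the lower mean, since
#' normal-appearing white matter is hypointense relative to lesions on FLAIR.
#'
#' Degenerate-fit guard: if either component collapses (weight below 0.01 or
#' SD below one bin width), or the two fitted means lie within two SDs of
#' each other — the separation below which a two-Gaussian mixture is
#' unimodal, so the component split is not identifiable from the histogram
#' shape — the histogram is refitted with a single Gaussian (count-weighted
#' moments with Sheppard's grouping correction) which is then the dominant
#' component, flagged via `degenerate = TRUE`. Hyperintense lesion
#' populations sit far above the normal-appearing-WM mode, so genuinely
#' bimodal histograms are unaffected by the overlap rule.
#'
#' @param hist an [build_histogram()] result with at least two nonzero bins.
#' @param weights `"equal"` for ordinary least squares on the density
#'   (default) or `"count"` to weight each bin by its count.
#' @return An object of class `two_gaussian_fit` with fields `w1, w2, mu1,
#'   mu2, sigma1, sigma2`, `dominant` (1 or 2), `sse`, `converged`,
#'   `degenerate`, `bin_width`.
#' @export
fit_two_gaussian <- function(hist, weights = c("equal", "count")) {
  stopifnot(inherits(hist, "intensity_histogram"))
  weights <- match.arg(weights)
  if (sum(hist$counts > 0) < 2)
    stop("need at least two nonzero histogram bins to fit a mixture", call. = FALSE)
  mids <- hist$mids
  dens <- hist_density(hist)
  bw <- mean(diff(hist$bin_edges))
  wls <- if (weights == "count") hist$counts / sum(hist$counts) else rep(1, length(mids))

  init <- split_histogram_mass(mids, hist$counts)
  rng <- range(mids)
  span <- diff(rng)
  starts <- list(list(w = max(min(init$g1$w, 0.99), 0.01),
                      m1 = init$g1$mu, s1 = init$g1$sigma,
                      m2 = init$g2$mu, s2 = init$g2$sigma))
  # deterministic jittered restarts
  jit <- with_seed(1203L, replicate(5, stats::runif(5, -1, 1), simplify = FALSE))
  for (j in jit) {
    s <- starts[[1]]
    starts[[length(starts) + 1]] <-
      list(w = min(max(s$w + 0.2 * j[1], 0.05), 0.95),
           m1 = s$m1 + 0.1 * span * j[2], s1 = s$s1 * 2^j[3],
           m2 = s$m2 + 0.1 * span * j[4], s2 = s$s2 * 2^j[5])
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        dens ~ w * stats::dnorm(mids, m1, s1) + (1 - w) * stats::dnorm(mids, m2, s2),
        start = s, weights = wls,
        lower = c(0, rng[1] - span, bw / 10, rng[1] - span, bw / 10),
        upper = c(1, rng[2] + span, 2 * span, rng[2] + span, 2 * span),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(wls * stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("two-Gaussian fit failed to converge from all restarts", call. = FALSE)

  p <- stats::coef(best$fit)
  w1 <- unname(p["w"]); w2 <- 1 - w1
  out <- list(w1 = w1, w2 = w2,
              mu1 = unname(p["m1"]), mu2 = unname(p["m2"]),
              sigma1 = unname(p["s1"]), sigma2 = unname(p["s2"]),
              sse = best$sse, converged = TRUE, degenerate = FALSE,
              bin_width = bw)

  collapsed <- min(out$w1, out$w2) < 0.01 || min(out$sigma1, out$sigma2) < bw
  overlapping <- abs(out$mu1 - out$mu2) < 2 * max(out$sigma1, out$sigma2)
  if (collapsed || overlapping) {
    sg <- fit_single_gaussian_moments(mids, hist$counts, dens, bw, wls)
    out$w1 <- 1; out$w2 <- 0
    out$mu1 <- sg$mu; out$sigma1 <- sg$sigma
    out$mu2 <- NA_real_; out$sigma2 <- NA_real_
    out$sse <- sg$sse
    out$degenerate <- TRUE
    out$dominant <- 1L
  } else {
    out$dominant <- if (out$w1 > out$w2) 1L
      else if (out$w2 > out$w1) 2L
      else if (out$mu1 <= out$mu2) 1L else 2L
  }
  structure(out, class = "two_gaussian_fit")
}

#' @export
print.two_gaussian_fit <- function(x, ...) {
  cat("<two_gaussian_fit>\n")
  cat(sprintf("  comp1: w=%.3f mu=%.2f sigma=%.2f%s\n", x$w1, x$mu1, x$sigma1,
              if (x$dominant == 1L) "  [dominant]" else ""))
  if (!x$degenerate)
    cat(sprintf("  comp2: w=%.3f mu=%.2f sigma=%.2f%s\n", x$w2, x$mu2, x$sigma2,
                if (x$dominant == 2L) "  [dominant]" else ""))
  if (x$degenerate) cat("  (degenerate: refitted as single Gaussian)\n")
  invisible(x)
}

#' Dominant-component moments of a fit
#' @param fit a `two_gaussian_fit`.
#' @return list(mu, sigma) of the dominant (normal-appearing WM) component.
#' @export
dominant_component <- function(fit) {
  stopifnot(inherits(fit, "two_gaussian_fit"))
  if (fit$dominant == 1L) list(mu = fit$mu1, sigma = fit$sigma1)
  else list(mu = fit$mu2, sigma = fit$sigma2)
}

#' Hyperintensity threshold from a mixture fit
#'
#' The lesion threshold is `k` standard deviations above the mean of the
#' dominant (normal-appearing WM) Gaussian; `k = 2.33` by default.
#'
#' @param fit a [fit_two_gaussian()] result.
#' @param k number of dominant-component SDs above the dominant mean.
#' @return threshold intensity (a.u.).
#' @export
wmh_threshold <- function(fit, k = 2.33) {
  dom <- dominant_component(fit)
  dom$mu + k * dom$sigma
}

#' Segment hyperintense voxels and report volumes
#'
#' Voxels inside `mask` whose intensity strictly exceeds `threshold` are
#' labelled hyperintense; when `region_mask` is given the result is further
#' restricted to that region (e.g. a frontal submask). Volumes are reported
#' in mm^3 and as a percentage of the intracranial volume.
#'
#' @param volume intensity array.
#' @param mask logical WM mask, same dimensions.
#' @param threshold intensity threshold (strict `>`).
#' @param icv_mm3 intracranial volume in mm^3 (> 0).
#' @param voxel_size numeric(3) voxel edge lengths in mm.
#' @param region_mask optional logical array restricting the result.
#' @param region_label label stored in the result (`"global"` default,
#'   `"frontal"` typical for the restricted variant).
#' @return An object of class `wmh_result`: `threshold`, `lesion_mask`,
#'   `voxel_count`, `volume_mm3`, `volume_pct_icv`, `region_label`.
#' @export
segment_wmh <- function(volume, mask, threshold, icv_mm3,
                        voxel_size = c(1, 1, 1), region_mask = NULL,
                        region_label = if (is.null(region_mask)) "global" else "regional") {
  if (!is.finite(threshold)) stop("`threshold` must be finite", call. = FALSE)
  if (!is.numeric(icv_mm3) || icv_mm3 <= 0) stop("`icv_mm3` must be > 0", call. = FALSE)
  stopifnot(all(dim(volume) == dim(mask)))
  lesion <- as.logical(mask) & (volume > threshold)
  if (!is.null(region_mask)) {
    stopifnot(all(dim(region_mask) == dim(mask)))
    lesion <- lesion & as.logical(region_mask)
  }
  vv <- voxel_volume(voxel_size)
  vc <- sum(lesion)
  structure(list(threshold = threshold, lesion_mask = lesion, voxel_count = vc,
                 volume_mm3 = vc * vv, volume_pct_icv = 100 * vc * vv / icv_mm3,
                 region_label = region_label),
            class = "wmh_result")
}

#' Full WMH quantification on a masked volume
#'
#' Convenience wrapper: histogram, two-Gaussian fit, threshold at `k` SDs of
#' the dominant component, and global plus optional regional segmentation.
#'
#' @inheritParams build_histogram
#' @inheritParams segment_wmh
#' @param k threshold in dominant-component SDs (default 2.33).
#' @param frontal_mask optional logical array for a frontal-restricted
#'   measurement.
#' @return list with `fit`, `threshold`, `global` (`wmh_result`), and
#'   `frontal` (`wmh_result` or NULL).
#' @export
quantify_wmh <- function(volume, mask, icv_mm3, voxel_size = c(1, 1, 1),
                         k = 2.33, n_bins = 256L, frontal_mask = NULL) {
  hist <- build_histogram(volume, mask, n_bins = n_bins)
  fit <- fit_two_gaussian(hist)
  thr <- wmh_threshold(fit, k = k)
  glob <- segment_wmh(volume, mask, thr, icv_mm3, voxel_size,
                      region_label = "global")
  fron <- if (!is.null(frontal_mask))
    segment_wmh(volume, mask, thr, icv_mm3, voxel_size,
                region_mask = frontal_mask, region_label = "frontal")
  list(fit = fit, threshold = thr, global = glob, frontal = fron)
}
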