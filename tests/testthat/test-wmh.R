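# WMH quantification: histogram building, mixture fitting, thresholding,
# segmentation, and the scale/monotonicity invariants.

test_that("histogram of a constant volume concentrates in a single bin", {
  vol <- array(100, c(5, 5, 4))
  mask <- array(TRUE, c(5, 5, 4))
  h <- build_histogram(vol, mask, n_bins = 32)
  expect_identical(sum(h$counts > 0), 1L)
  expect_identical(sum(h$counts), 100L)
})

test_that("histogram counts are conserved and inputs validated", {
  ph <- generate_phantom(small_phantom_spec())
  h <- build_histogram(ph$intensity, ph$wm_mask)
  expect_identical(sum(h$counts), sum(ph$wm_mask))
  expect_identical(h$n_voxels, sum(ph$wm_mask))
  expect_true(all(diff(h$bin_edges) > 0))
  expect_error(build_histogram(ph$intensity, array(FALSE, dim(ph$intensity))),
               "no voxels")
  expect_error(build_histogram(ph$intensity, array(TRUE, c(2, 2, 2))),
               "dimensions")
})

test_that("histogram mode of a phantom sits near the dominant mean", {
  ph <- generate_phantom(phantom_spec(seed = 21))
  h <- build_histogram(ph$intensity, ph$wm_mask)
  mode_mid <- h$mids[which.max(h$counts)]
  expect_lt(abs(mode_mid - 100), 3 * mean(diff(h$bin_edges)))
})

test_that("two-Gaussian fit recovers the generating mixture parameters", {
  ph <- generate_phantom(phantom_spec(seed = 501))
  fit <- fit_two_gaussian(build_histogram(ph$intensity, ph$wm_mask))
  expect_false(fit$degenerate)
  expect_equal(fit$w1 + fit$w2, 1, tolerance = 1e-9)
  dom <- dominant_component(fit)
  expect_lt(abs(dom$mu - 100), 1)
  expect_lt(abs(dom$sigma - 10), 0.5)
  sec <- if (fit$dominant == 1L) list(mu = fit$mu2, sigma = fit$sigma2)
         else list(mu = fit$mu1, sigma = fit$sigma1)
  expect_lt(abs(sec$mu - 140), 3)
})

test_that("dominant component follows the weight-then-lower-mean rule", {
  for (s in c(502, 503)) {
    ph <- generate_phantom(phantom_spec(seed = s))
    fit <- fit_two_gaussian(build_histogram(ph$intensity, ph$wm_mask))
    w <- c(fit$w1, fit$w2); mu <- c(fit$mu1, fit$mu2)
    if (abs(w[1] - w[2]) > 1e-9) {
      expect_identical(fit$dominant, which.max(w))
    } else {
      expect_identical(fit$dominant, which.min(mu))
    }
  }
})

test_that("two-Gaussian sse never exceeds the best single-Gaussian sse", {
  ph <- generate_phantom(phantom_spec(seed = 504))
  h <- build_histogram(ph$intensity, ph$wm_mask)
  fit <- fit_two_gaussian(h)

  # independent single-Gaussian oracle: direct BFGS on the density residual
  dens <- h$counts / (h$n_voxels * diff(h$bin_edges))
  obj <- function(p) sum((dens - dnorm(h$mids, p[1], exp(p[2])))^2)
  mu0 <- weighted.mean(h$mids, h$counts)
  s0 <- sqrt(weighted.mean((h$mids - mu0)^2, h$counts))
  best1 <- optim(c(mu0, log(s0)), obj, method = "BFGS")$value
  expect_lte(fit$sse, best1 + 1e-12)
})

test_that("fit refuses a histogram with fewer than two occupied bins", {
  vol <- array(7, c(4, 4, 2)); mask <- array(TRUE, c(4, 4, 2))
  h <- build_histogram(vol, mask)
  expect_error(fit_two_gaussian(h), "two nonzero")
})

test_that("threshold arithmetic and monotonicity", {
  fit <- structure(list(w1 = 0.9, w2 = 0.1, mu1 = 100, mu2 = 140,
                        sigma1 = 10, sigma2 = 15, dominant = 1L,
                        sse = 0, converged = TRUE, degenerate = FALSE,
                        bin_width = 1),
                   class = "two_gaussian_fit")
  expect_equal(wmh_threshold(fit, k = 2.33), 123.3)
  expect_equal(wmh_threshold(fit, k = 0), 100)
  fit2 <- fit; fit2$sigma1 <- 12
  expect_gt(wmh_threshold(fit2, 2.33), wmh_threshold(fit, 2.33))
})

test_that("segmentation equals a hand-enumerated answer on a 6-voxel volume", {
  vol <- array(c(1, 2, 3, 4, 5, 6), c(6, 1, 1))
  mask <- array(TRUE, c(6, 1, 1))
  res <- segment_wmh(vol, mask, threshold = 3.5, icv_mm3 = 600)
  expect_identical(as.vector(res$lesion_mask), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(res$voxel_count, 3L)
  expect_equal(res$volume_mm3, 3)
  expect_equal(res$volume_pct_icv, 100 * 3 / 600)

  # strict inequality: a voxel exactly at the threshold is not a lesion
  res_eq <- segment_wmh(vol, mask, threshold = 4, icv_mm3 = 600)
  expect_identical(res_eq$voxel_count, 2L)

  expect_error(segment_wmh(vol, mask, 3.5, icv_mm3 = 0), "icv")
  expect_error(segment_wmh(vol, mask, Inf, icv_mm3 = 600), "finite")
})

test_that("region mask equal to the whole mask reproduces the global result", {
  ph <- generate_phantom(small_phantom_spec(seed = 6))
  q <- quantify_wmh(ph$intensity, ph$wm_mask, ph$icv_mm3, ph$voxel_size,
                    frontal_mask = ph$wm_mask)
  expect_identical(q$frontal$voxel_count, q$global$voxel_count)
  expect_equal(q$frontal$volume_pct_icv, q$global$volume_pct_icv)
})

test_that("intensity rescaling scales the fit and threshold, not the mask", {
  ph <- generate_phantom(small_phantom_spec(seed = 14))
  q1 <- quantify_wmh(ph$intensity, ph$wm_mask, ph$icv_mm3, ph$voxel_size)
  q2 <- quantify_wmh(3 * ph$intensity, ph$wm_mask, ph$icv_mm3, ph$voxel_size)
  d1 <- dominant_component(q1$fit); d2 <- dominant_component(q2$fit)
  expect_equal(d2$mu, 3 * d1$mu, tolerance = 1e-4)
  expect_equal(d2$sigma, 3 * d1$sigma, tolerance = 1e-4)
  expect_equal(q2$threshold, 3 * q1$threshold, tolerance = 1e-4)
  expect_identical(q2$global$lesion_mask, q1$global$lesion_mask)
})

test_that("raising k never increases the lesion voxel count", {
  ph <- generate_phantom(small_phantom_spec(seed = 15))
  h <- build_histogram(ph$intensity, ph$wm_mask)
  fit <- fit_two_gaussian(h)
  counts <- vapply(c(0, 1, 2, 2.33, 3, 4), function(k) {
    segment_wmh(ph$intensity, ph$wm_mask, wmh_threshold(fit, k),
                ph$icv_mm3, ph$voxel_size)$voxel_count
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("null phantom lesion fraction matches the Gaussian tail probability", {
  ph <- generate_phantom(null_phantom_spec(seed = 2))
  q <- quantify_wmh(ph$intensity, ph$wm_mask, ph$icv_mm3, ph$voxel_size)
  n_wm <- sum(ph$wm_mask)
  frac <- q$global$voxel_count / n_wm
  p_tail <- 1 - pnorm(2.33)
  expect_lt(abs(frac - p_tail), 3 * sqrt(p_tail * (1 - p_tail) / n_wm))
  expect_true(q$fit$degenerate)  # unimodal histogram collapses to one Gaussian
})

test_that("planted hyperintense lesions are recovered and frontal <= global", {
  les <- list(list(center = c(48, 40, 36), radius = 7, mu = 160, sigma = 5),
              list(center = c(48, 75, 36), radius = 7, mu = 160, sigma = 5))
  ph <- generate_phantom(phantom_spec(lesions = les,
                                      secondary = list(weight = 0, mu = 0, sigma = 1),
                                      seed = 4))
  q <- quantify_wmh(ph$intensity, ph$wm_mask, ph$icv_mm3, ph$voxel_size,
                    frontal_mask = ph$frontal_mask)
  recovered <- sum(q$global$lesion_mask & ph$truth$lesion_mask)
  expect_lt(abs(recovered - ph$truth$lesion_voxels) / ph$truth$lesion_voxels, 0.1)
  expect_lte(q$frontal$voxel_count, q$global$voxel_count)
  expect_true(all(which(q$frontal$lesion_mask) %in% which(q$global$lesion_mask)))
})
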