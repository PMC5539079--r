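# Synthetic-data generators: determinism, planted truth, statistical contracts.

test_that("phantom with no lesions reports zero truth lesion volume", {
  ph <- generate_phantom(small_phantom_spec())
  expect_identical(ph$truth$lesion_voxels, 0L)
  expect_identical(ph$truth$lesion_volume_mm3, 0)
})

test_that("planted sphere voxel count matches brute-force enumeration", {
  ctr <- c(24, 28, 18); r <- 5
  sp <- small_phantom_spec(lesions = list(list(center = ctr, radius = r,
                                               mu = 160, sigma = 5)))
  ph <- generate_phantom(sp)

  # independent oracle: walk every voxel of the grid
  brute <- 0L
  for (x in 1:48) for (y in 1:56) for (z in 1:36) {
    if ((x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2 <= r^2) brute <- brute + 1L
  }
  expect_identical(ph$truth$lesion_voxels, brute)

  # planted-truth conservation holds exactly, including anisotropic voxels
  sp4 <- small_phantom_spec(voxel_size = c(1, 1, 4),
                            lesions = list(list(center = ctr, radius = r,
                                                mu = 160, sigma = 5)))
  ph4 <- generate_phantom(sp4)
  expect_identical(ph4$truth$lesion_volume_mm3, brute * 4)
})

test_that("phantom generation is bit-identical under a fixed seed", {
  a <- generate_phantom(small_phantom_spec(seed = 42))
  b <- generate_phantom(small_phantom_spec(seed = 42))
  c <- generate_phantom(small_phantom_spec(seed = 43))
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("a lesion escaping the WM ellipsoid is rejected with a geometry error", {
  sp <- small_phantom_spec(lesions = list(list(center = c(4, 4, 4), radius = 3,
                                               mu = 160, sigma = 5)))
  expect_error(generate_phantom(sp), "outside the WM")
})

test_that("non-lesion WM intensities match the mixture moments within 3 SE", {
  for (s in c(3, 11)) {
    ph <- generate_phantom(phantom_spec(seed = s))
    x <- ph$intensity[ph$wm_mask & !ph$truth$lesion_mask]
    n <- length(x)
    m_th <- 0.9 * 100 + 0.1 * 140
    ex2 <- 0.9 * (10^2 + 100^2) + 0.1 * (15^2 + 140^2)
    sd_th <- sqrt(ex2 - m_th^2)
    expect_lt(abs(mean(x) - m_th), 3 * sd_th / sqrt(n))
    # SE of the sample SD must use the mixture kurtosis, not the Gaussian one
    mu4 <- sum(c(0.9, 0.1) * vapply(1:2, function(i) {
      s <- c(10, 15)[i]; d <- c(100, 140)[i] - m_th
      3 * s^4 + 6 * s^2 * d^2 + d^4
    }, 0))
    se_sd <- sqrt((mu4 - sd_th^4) / (4 * sd_th^2 * n))
    expect_lt(abs(sd(x) - sd_th), 3 * se_sd)
  }
})

test_that("PAT envelope construction gives the configured post/pre ratio", {
  eq <- generate_pat(pat_spec(hyperemia_ratio = 1, noise_sd = 0))
  b <- eq$phases$baseline; p <- eq$phases$post
  expect_equal(max(eq$samples[b[1]:(b[2] - 1)]), max(eq$samples[p[1]:(p[2] - 1)]))

  dbl <- generate_pat(pat_spec(hyperemia_ratio = 2, noise_sd = 0))
  b <- dbl$phases$baseline; p <- dbl$phases$post
  expect_equal(max(dbl$samples[p[1]:(p[2] - 1)]) /
                 max(dbl$samples[b[1]:(b[2] - 1)]), 2.0)
})

test_that("PAT phase boundaries match the configured durations", {
  sp <- pat_spec(sample_rate = 50, durations = c(20, 10, 15))
  sig <- generate_pat(sp)
  expect_identical(sig$phases$baseline, c(1L, 1001L))
  expect_identical(sig$phases$occlusion, c(1001L, 1501L))
  expect_identical(sig$phases$post, c(1501L, 2251L))
  expect_length(sig$samples, 2250)
})

test_that("PAT generation is reproducible under a fixed seed and validates inputs", {
  a <- generate_pat(pat_spec(noise_sd = 0.05, seed = 9))
  b <- generate_pat(pat_spec(noise_sd = 0.05, seed = 9))
  expect_identical(a$samples, b$samples)
  expect_error(pat_spec(sample_rate = 0), "sample_rate")
  expect_error(pat_spec(occlusion_residual = 0.2), "occlusion_residual")
})

test_that("exact-mode connectivity counts are recovered perfectly downstream", {
  conn <- generate_connectivity(connectivity_spec(mode = "exact", seed = 2))
  seg <- hard_segment(conn)
  expect_identical(seg$assignment, conn$truth)
  expect_identical(seg$unassigned, 0L)
})

test_that("stochastic connectivity with large mean separation is recovered >= 99%", {
  sp <- connectivity_spec(n_seed_voxels = 1000L, mode = "stochastic",
                          offtarget_mean = 1, seed = 5)
  conn <- generate_connectivity(sp)
  seg <- hard_segment(conn)
  rate <- mean(seg$assignment == conn$truth)
  expect_gte(rate, 0.99)
})

test_that("connectivity generation is deterministic under a fixed seed", {
  a <- generate_connectivity(connectivity_spec(seed = 31))
  b <- generate_connectivity(connectivity_spec(seed = 31))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
})

test_that("cohort with zero latent correlation shows near-zero sample correlation", {
  S <- diag(c(0.5, 0.08, 15.5)^2)
  coh <- generate_cohort(cohort_spec(n = 10000L, latent_covariance = S, seed = 8))
  tmtdiff <- coh$tmt_b_s - coh$tmt_a_s
  expect_lt(abs(cor(coh$rhi, tmtdiff)), 0.03)
  expect_lt(abs(cor(coh$rhi, coh$cluster_fa)), 0.03)
})

test_that("cohort table has the promised shape, ranges and determinism", {
  coh <- generate_cohort(cohort_spec(seed = 3))
  expect_identical(nrow(coh), 36L)
  expect_false(anyNA(coh))
  expect_true(all(coh$cluster_fa > 0 & coh$cluster_fa < 1))
  expect_true(all(coh$tmt_a_s > 0 & coh$tmt_b_s > 0))
  expect_setequal(levels(coh$sex), c("F", "M"))
  expect_identical(coh, generate_cohort(cohort_spec(seed = 3)))
})

test_that("cohort marginals track their configured moments at large n", {
  coh <- generate_cohort(cohort_spec(n = 20000L, seed = 12))
  expect_lt(abs(mean(coh$rhi) - 1.73), 3 * 0.5 / sqrt(20000))
  expect_lt(abs(mean(coh$tmt_b_s - coh$tmt_a_s) - 35.4), 3 * 15.5 / sqrt(20000))
  expect_lt(abs(mean(coh$cluster_fa) - 0.5), 0.01)
})

test_that("a non-positive-definite latent covariance is rejected by name", {
  S <- matrix(1, 3, 3)  # rank 1
  expect_error(cohort_spec(latent_covariance = S), "latent_covariance")
})
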