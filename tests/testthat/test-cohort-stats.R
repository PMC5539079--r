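# Subject scoring, outlier rule, partial correlations and sex comparisons.

test_that("Trail difference arithmetic and edge handling", {
  expect_identical(tmt_score(25, 60), 35)
  expect_identical(tmt_score(40, 40), 0)
  expect_warning(d <- tmt_score(50, 45), "negative")
  expect_identical(d, -5)
  expect_error(tmt_score(-1, 60), "positive")
  expect_true(is.na(tmt_score(NA, 60)))
})

test_that("the 2.5-SD upper rule, computed by the direct oracle, is honoured", {
  # oracle on the 5-point set: mean 66.4, sd 74.7 -> cutoff 253.2; the 200 is
  # retained (with n = 5 the largest possible z is (n-1)/sqrt(n) = 1.79 < 2.5)
  s5 <- c(30, 32, 34, 36, 200)
  cut5 <- mean(s5) + 2.5 * sd(s5)
  expect_true(all(s5 <= cut5))
  expect_identical(exclude_outliers(s5), rep(TRUE, 5))

  # a 10-point set where the oracle says the extreme point crosses the cutoff
  s10 <- c(30, 32, 34, 36, 38, 40, 42, 44, 46, 200)
  cut10 <- mean(s10) + 2.5 * sd(s10)
  expect_identical(exclude_outliers(s10), s10 <= cut10)
  expect_false(exclude_outliers(s10)[10])
})

test_that("all-equal scores and boundary scores are retained", {
  expect_identical(exclude_outliers(rep(12, 6)), rep(TRUE, 6))

  # locate the value x* where x equals mean + 2.5 SD of the full set;
  # just below it is retained (strict > rule), just above it is excluded
  base <- c(30, 32, 34, 36, 38, 40, 42, 44, 46)
  f <- function(x) x - (mean(c(base, x)) + 2.5 * sd(c(base, x)))
  x_star <- uniroot(f, c(50, 500), tol = 1e-12)$root
  expect_true(all(exclude_outliers(c(base, x_star - 1e-6))))
  expect_false(exclude_outliers(c(base, x_star + 1e-4))[10])
})

test_that("the rule is single-pass: secondary outliers survive", {
  # after dropping the 400, the 120 would cross the refreshed cutoff, but the
  # rule is applied once over the full set
  scores <- c(30, 31, 32, 33, 34, 35, 36, 37, 38, 120, 400)
  keep <- exclude_outliers(scores)
  expect_false(keep[11])
  expect_true(keep[10])
  refiltered <- exclude_outliers(scores[keep])
  expect_false(all(refiltered))  # re-application would indeed drop more
})

test_that("missing scores are unusable but never counted as outliers", {
  scores <- c(30, 32, 34, NA, 36)
  keep <- exclude_outliers(scores)
  expect_true(keep[4])
  expect_error(exclude_outliers(c(1, NA, NA)), "3 non-missing")
})

test_that("partial correlation with no covariates reduces to Pearson r", {
  set.seed(15)
  x <- rnorm(25); y <- 0.4 * x + rnorm(25)
  res <- partial_correlation(x, y)
  ref <- cor.test(x, y)
  expect_equal(res$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_identical(res$kind, "pearson_r")
})

test_that("partial correlation equals the residualize-then-correlate oracle", {
  set.seed(16)
  n <- 30
  cov <- data.frame(age = rnorm(n, 64, 3), sex = rep_len(c(0, 1), n))
  x <- 0.3 * cov$age + rnorm(n)
  y <- -0.2 * cov$age + 0.5 * cov$sex + rnorm(n)
  res <- partial_correlation(x, y, cov)

  rx <- resid(lm(x ~ age + sex, data = cov))
  ry <- resid(lm(y ~ age + sex, data = cov))
  r_oracle <- cor(rx, ry)
  expect_equal(res$estimate, r_oracle, tolerance = 1e-10)
  expect_identical(res$df, 26L)  # n - 2 - 2 covariates
  t_oracle <- r_oracle * sqrt(n - 4) / sqrt(1 - r_oracle^2)
  expect_equal(res$p, 2 * pt(abs(t_oracle), n - 4, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("partial correlation is invariant to affine covariate rescaling", {
  coh <- generate_cohort(cohort_spec(seed = 31))
  cov1 <- data.frame(age = coh$age, sex = as.integer(coh$sex) - 1)
  cov2 <- data.frame(age = 12 * coh$age - 300, sex = 5 * (as.integer(coh$sex) - 1) + 2)
  a <- partial_correlation(coh$rhi, coh$cluster_fa, cov1)
  b <- partial_correlation(coh$rhi, coh$cluster_fa, cov2)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("constant inputs after residualization are refused", {
  cov <- data.frame(age = 1:10)
  expect_error(partial_correlation(rep(3, 10), rnorm(10), cov), "constant")
})

test_that("null partial correlation rejects at close to the nominal 5% rate", {
  S <- diag(c(0.5, 0.08, 15.5)^2)
  n_rep <- 400
  rej <- vapply(seq_len(n_rep), function(i) {
    coh <- generate_cohort(cohort_spec(n = 32L, latent_covariance = S,
                                       seed = 5000L + i))
    res <- partial_correlation(coh$rhi, coh$tmt_b_s - coh$tmt_a_s,
                               coh[, c("age", "sex")])
    res$p < 0.05
  }, NA)
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("sex F equals the squared pooled t and uses df (1, n-2)", {
  coh <- generate_cohort(cohort_spec(seed = 18))
  res <- sex_difference(coh$rhi, coh$sex)
  tt <- t.test(rhi ~ sex, data = coh, var.equal = TRUE)
  expect_equal(res$estimate, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_identical(res$df, c(1L, 34L))  # n = 36
})

test_that("identical groups give F = 0 and lone groups are refused", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- factor(rep(c("F", "M"), each = 3))
  res <- sex_difference(v, g)
  expect_equal(res$estimate, 0, tolerance = 1e-12)
  expect_error(sex_difference(1:4, factor(rep("F", 4))), "two groups")
})

test_that("cohort summary equals hand arithmetic on a 4-row table", {
  tab <- data.frame(id = 1:4, age = c(60, 62, 64, 66),
                    sex = factor(c("F", "F", "M", "M")),
                    rhi = c(1.2, 1.8, 2.0, 1.0),
                    tmt_a_s = c(20, 30, 25, 35), tmt_b_s = c(50, 70, 60, 80))
  s <- summarize_cohort(tab)
  overall_age <- s[s$group == "overall" & s$variable == "age", ]
  expect_equal(overall_age$mean, 63)
  expect_equal(overall_age$sd, sd(c(60, 62, 64, 66)))
  f_rhi <- s[s$group == "F" & s$variable == "rhi", ]
  expect_equal(f_rhi$mean, 1.5)
  expect_identical(f_rhi$n, 2L)
  tmt <- s[s$group == "overall" & s$variable == "tmt_diff_s", ]
  expect_equal(tmt$mean, mean(c(30, 40, 35, 45)))
  # column order follows the conventional table layout
  expect_identical(unique(s$variable), c("age", "rhi", "tmt_diff_s"))
})

test_that("a single-subject summary flags SD as undefined", {
  tab <- data.frame(id = 1, age = 65, sex = factor("F", levels = c("F", "M")),
                    rhi = 1.7, tmt_a_s = 30, tmt_b_s = 60)
  s <- summarize_cohort(tab)
  expect_true(all(is.na(s$sd[s$group == "overall"])))
  expect_identical(s$n[s$group == "overall"], rep(1L, 3))
})
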