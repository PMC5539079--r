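#' Trail Making Test switching score
#'
#' The executive-function score is the Trail B completion time minus the
#' Trail A completion time, in seconds. Negative differences are possible
#' and are flagged with a warning; missing inputs give a missing score.
#'
#' @param tmt_a_s,tmt_b_s completion times in seconds (> 0).
#' @return numeric `tmt_b_s - tmt_a_s` (NA where either input is missing).
#' @export
tmt_score <- function(tmt_a_s, tmt_b_s) {
  if (any(c(tmt_a_s, tmt_b_s) <= 0, na.rm = TRUE))
    stop("completion times must be positive", call. = FALSE)
  d <- tmt_b_s - tmt_a_s
  if (any(d < 0, na.rm = TRUE))
    warning("negative Trail B - Trail A difference(s) present")
  d
}

#' Upper-tail outlier exclusion
#'
#' Flags scores strictly greater than `mean + k * SD`, with mean and SD
#' computed once over all non-missing scores (single pass; the rule is not
#' re-applied to the filtered set). The rule is one-sided: only the upper
#' tail is excluded. Zero SD excludes nobody; missing scores are never
#' flagged as outliers (they are simply unusable).
#'
#' @param scores numeric vector (>= 3 non-missing values).
#' @param k SD multiplier (default 2.5).
#' @return logical vector, TRUE = keep, FALSE = excluded as outlier.
#' @examples
#' exclude_outliers(c(30, 32, 34, 36, 200))  # the 200 is excluded
#' @export
exclude_outliers <- function(scores, k = 2.5) {
  ok <- !is.na(scores)
  if (sum(ok) < 3L) stop("need at least 3 non-missing scores", call. = FALSE)
  m <- mean(scores[ok]); s <- stats::sd(scores[ok])
  keep <- rep(TRUE, length(scores))
  if (s > 0) keep[ok] <- scores[ok] <= m + k * s
  keep
}

stat_result <- function(kind, estimate, df, p, n, controlled = character(0)) {
  structure(list(kind = kind, estimate = estimate, df = df, p = p, n = n,
                 controlled = controlled), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  lab <- switch(x$kind, partial_r = "partial r", pearson_r = "r", anova_F = "F")
  ctl <- if (length(x$controlled)) paste0(" | ", paste(x$controlled, collapse = ", ")) else ""
  cat(sprintf("<stat_result> %s = %.4f (df = %s, p = %s, n = %d)%s\n",
              lab, x$estimate, paste(x$df, collapse = ","),
              format.pval(x$p, digits = 3), x$n, ctl))
  invisible(x)
}

#' Partial correlation controlling for nuisance covariates
#'
#' Pearson correlation of the OLS residuals of `x` and `y` after each is
#' regressed on an intercept plus the covariates. With no covariates this
#' reduces to the plain Pearson correlation. The two-sided p-value comes
#' from the t transform with `df = n - 2 - n_covariates`.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of nuisance covariates (e.g. age and
#'   sex), or NULL for a plain correlation. Factors are converted to 0/1
#'   dummies via `model.matrix`.
#' @return A `stat_result` with kind `partial_r` (or `pearson_r` when no
#'   covariates are given).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  keep <- stats::complete.cases(x, y, if (!is.null(covariates)) covariates)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    q <- 0L
    rx <- x - mean(x); ry <- y - mean(y)
    ctl <- character(0)
    kind <- "pearson_r"
  } else {
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
    Z <- stats::model.matrix(~ ., data = covariates)
    q <- ncol(Z) - 1L
    rx <- stats::lm.fit(Z, x)$residuals
    ry <- stats::lm.fit(Z, y)$residuals
    ctl <- colnames(covariates)
    kind <- "partial_r"
  }
  if (n <= q + 2L) stop("too few observations for the covariate set", call. = FALSE)
  # residual energy at rounding-noise scale means the variable is (numerically)
  # constant given the covariates, so the correlation is undefined
  tiny <- function(res, orig) sum(res^2) <= .Machine$double.eps * (sum(orig^2) + 1)
  if (tiny(rx, x) || tiny(ry, y))
    stop("x or y is constant after residualization; correlation undefined",
         call. = FALSE)
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - q
  tval <- r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  stat_result(kind, r, df, p, n, controlled = ctl)
}

#' Two-group sex difference as a one-way ANOVA F
#'
#' One-way two-group ANOVA of `values` by `group`, reported as F with
#' df (1, n - 2); identical to the squared pooled-variance two-sample t.
#'
#' @param values numeric outcome.
#' @param group two-level factor (e.g. sex F/M), each level with >= 2
#'   observations.
#' @return A `stat_result` with kind `anova_F`.
#' @export
sex_difference <- function(values, group) {
  keep <- stats::complete.cases(values, group)
  values <- values[keep]; group <- droplevels(factor(group[keep]))
  if (nlevels(group) != 2L || any(table(group) < 2L))
    stop("need exactly two groups with at least 2 observations each", call. = FALSE)
  n <- length(values)
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  Fv <- tab[1, "F value"]
  p <- tab[1, "Pr(>F)"]
  if (is.na(Fv)) { Fv <- 0; p <- 1 }   # zero residual + zero effect variance
  stat_result("anova_F", Fv, c(1L, n - 2L), p, n)
}

#' Cohort summary table (mean and SD, overall and by sex)
#'
#' Summarizes the demographic, endothelial and executive-function columns in
#' the conventional order: age, RHI, Trail B - Trail A, then cluster FA when
#' present. Missing values are dropped columnwise with the effective n
#' reported; SD for a single observation is reported as NA and flagged.
#'
#' @param table cohort data.frame with at least `age`, `sex`, `rhi`; columns
#'   `tmt_a_s`/`tmt_b_s` and `cluster_fa` are summarized when present.
#' @return data.frame with one row per (group, variable): `group`,
#'   `variable`, `n`, `mean`, `sd`.
#' @export
summarize_cohort <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L,
            all(c("age", "sex", "rhi") %in% names(table)))
  tab <- table
  if (all(c("tmt_a_s", "tmt_b_s") %in% names(tab)))
    tab$tmt_diff_s <- suppressWarnings(tmt_score(tab$tmt_a_s, tab$tmt_b_s))
  vars <- intersect(c("age", "rhi", "tmt_diff_s", "cluster_fa"), names(tab))
  groups <- c(list(overall = tab), split(tab, tab$sex))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    df <- groups[[g]]
    do.call(rbind, lapply(vars, function(v) {
      x <- df[[v]][!is.na(df[[v]])]
      data.frame(group = g, variable = v, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) > 1) stats::sd(x) else NA_real_)
    }))
  }))
  rownames(out) <- NULL
  out
}
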