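#!/usr/bin/env Rscript
# Cohort-level statistics battery: Trail Making scoring with the one-sided
# 2.5-SD outlier rule, the Table-1 style summary, partial correlations among
# RHI, cluster FA and executive function controlling for age and sex, and
# the sex-difference F tests. Run analysis/05_voxelwise.R first.

suppressPackageStartupMessages(library(endowm))
dir.create("results", showWarnings = FALSE)

coh <- read_cohort_csv("results/cohort_with_cluster_fa.csv")
coh$tmt_diff_s <- tmt_score(coh$tmt_a_s, coh$tmt_b_s)
keep <- exclude_outliers(coh$tmt_diff_s)
cat(sprintf("%d of %d subjects retained after the >2.5 SD Trail rule\n",
            sum(keep), nrow(coh)))
used <- coh[keep, ]

summary_tab <- summarize_cohort(used)
write.csv(summary_tab, "results/cohort_summary.csv", row.names = FALSE)
cat("\ncohort summary (mean/SD overall and by sex):\n")
print(summary_tab, digits = 3)

cov <- used[, c("age", "sex")]
tests <- list(
  rhi_vs_cluster_fa = partial_correlation(used$rhi, used$cluster_fa, cov),
  cluster_fa_vs_tmt = partial_correlation(used$cluster_fa, used$tmt_diff_s, cov),
  rhi_vs_tmt = partial_correlation(used$rhi, used$tmt_diff_s, cov))
cat("\npartial correlations (controlling for age and sex):\n")
for (nm in names(tests)) { cat(" ", nm, ": "); print(tests[[nm]]) }

sexes <- list(rhi = sex_difference(used$rhi, used$sex),
              tmt = sex_difference(used$tmt_diff_s, used$sex))
cat("\nsex differences (one-way F, df 1 and n-2):\n")
for (nm in names(sexes)) { cat(" ", nm, ": "); print(sexes[[nm]]) }

stats_tab <- do.call(rbind, lapply(names(tests), function(nm) {
  s <- tests[[nm]]
  data.frame(analysis = nm, kind = s$kind, estimate = s$estimate,
             df = s$df, p = s$p, n = s$n)
}))
sex_tab <- do.call(rbind, lapply(names(sexes), function(nm) {
  s <- sexes[[nm]]
  data.frame(analysis = paste0("sex_", nm), kind = s$kind, estimate = s$estimate,
             df = paste(s$df, collapse = ","), p = s$p, n = s$n)
}))
stats_tab$df <- as.character(stats_tab$df)
write.csv(rbind(stats_tab, sex_tab), "results/cohort_stats.csv", row.names = FALSE)
cat("\nwrote results/cohort_stats.csv\n")
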