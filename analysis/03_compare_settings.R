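#!/usr/bin/env Rscript
# Step 3: cross-setting comparisons of the fitted migration probability m
# and biodiversity number theta — paired Wilcoxon signed-rank tests over
# the six setting pairs (pairing by couple) plus the per-setting numeric
# summaries (median, mean, IQR) that replace box plots.
# Reads the summary tables written by 02_fit_settings.R.

suppressPackageStartupMessages(library(msneutral))

out_dir <- "results"
settings <- c("CM+CNA+CNB", "CM+CNA", "CM+CNB", "CNA+CNB")
summaries <- lapply(settings, function(s) {
  fn <- file.path(out_dir, paste0("setting_", gsub("\\+", "_", s), ".tsv"))
  df <- read.delim(fn, check.names = FALSE)
  df[df$ID != "Mean", ] # comparisons pair the per-couple rows
})
names(summaries) <- settings

cmp <- compare_settings(summaries)
write.table(cmp, file.path(out_dir, "comparisons.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

num_sum <- do.call(rbind, lapply(settings, function(s) {
  df <- summaries[[s]]
  data.frame(setting = s,
             theta_median = median(df$theta), theta_mean = mean(df$theta),
             theta_iqr = IQR(df$theta),
             m_median = median(df$m), m_mean = mean(df$m),
             m_iqr = IQR(df$m))
}))
write.table(num_sum, file.path(out_dir, "setting_distributions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Pairwise Wilcoxon tests (paired by couple):\n")
print(cmp[, c("setting_a", "setting_b", "quantity", "p_value",
              "significant")], row.names = FALSE)
cat("\nOn neutral synthetic data with a common m_true across roles, no\n")
cat("contrast is expected to be significant; with role-specific m_true\n")
cat("(e.g. lower within-vaginal migration) the CNA+CNB rows flag.\n")
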