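#!/usr/bin/env Rscript
# Stage 4: group-level inference.
#
# Reads the dwell table (stage 2), BITSEA domain scores (stage 3), and the
# demographics (stage 1), then runs the full statistical layer: the linear
# mixed model of the longitudinal dwell indices with Bonferroni post hocs
# and Cohen's d, the BITSEA group t-tests (including the sleep-items-
# removed dysregulation row), the dwell x domain correlation table, and the
# demographic chi-square comparisons. Writes the tables plus a plain-text
# report, and a dwell-by-condition figure when ggplot2 is available.

library(overlapgaze)

read_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE))
}
dwell <- read_tsv("results/dwell_table.tsv")
scores <- read_tsv("results/bitsea_domain_scores.tsv")
demographics <- read_tsv("results/cohort/demographics.tsv")

analysis <- analyze_cohort(dwell, scores, demographics)
write_analysis(analysis, "results/analysis")

print(analysis$lmm)
cat("\nBITSEA group comparisons:\n")
print(as.data.frame(analysis$bitsea_tests[
  , c("domain", "t", "df", "p_value", "d", "variant")]),
  row.names = FALSE, digits = 4)
cat("\nDemographic chi-square tests:\n")
print(as.data.frame(analysis$demographics_chi2), row.names = FALSE, digits = 4)

sig <- analysis$correlations[!is.na(analysis$correlations$p_value) &
                               analysis$correlations$p_value < 0.05, ]
cat("\nDwell x BITSEA correlations with unadjusted p < .05:\n")
print(as.data.frame(sig), row.names = FALSE, digits = 3)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  inc <- dwell[dwell$included & !is.na(dwell$dwell_index), ]
  fig <- ggplot(inc, aes(x = condition, y = dwell_index, fill = group)) +
    geom_boxplot(outlier.size = 0.5) +
    facet_wrap(~age, labeller = label_both) +
    labs(y = "Normalized dwell-time index", x = "Face condition") +
    theme_minimal()
  ggsave("results/analysis/dwell_by_condition.pdf", fig,
         width = 8, height = 4)
  cat("\nFigure written to results/analysis/dwell_by_condition.pdf\n")
}
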