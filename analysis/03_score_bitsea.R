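#!/usr/bin/env Rscript
# Stage 3: score the BITSEA questionnaire.
#
# Reads the item-level response table written by stage 1, scores the four
# analysis domains plus the sleep-items-removed dysregulation variant, and
# reports internal-consistency reliability per domain.

library(overlapgaze)

responses <- tibble::as_tibble(
  utils::read.delim("results/cohort/bitsea_responses.tsv", sep = "\t",
                    check.names = FALSE))
instrument <- load_instrument()

scores <- score_domains(responses, instrument)
overlapgaze:::write_tsv_file(scores, "results/bitsea_domain_scores.tsv")

alphas <- domain_alphas(responses, instrument)
overlapgaze:::write_tsv_file(alphas, "results/bitsea_alphas.tsv")

cat("Domain score summaries (n =", nrow(scores), "respondents):\n")
print(summary(scores[, -1]))
cat("\nInternal consistency (Cronbach's alpha):\n")
print(as.data.frame(alphas), row.names = FALSE, digits = 3)
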