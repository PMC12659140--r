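#!/usr/bin/env Rscript
# Stage 4: tree-based scan statistics.
#
# Unconditional Bernoulli scans over every cut of the ICD-10 tree (full
# cohort) and the ATC tree (drug-register sub-cohort), each with its own
# Monte-Carlo max-LLR null (R = 999 here; the study design uses 9,999) and
# the 10 most likely cuts reported with risks, risk ratios, risk
# differences, and multiplicity-adjusted p-values.

library(utilscan)

seed <- 20260930L
read_cohort <- function(path) {
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("birth_date", "death_date", "emigration_date"))
    x[[col]] <- as.Date(x[[col]])
  x
}
cohort <- read_cohort("results/cohort.tsv")
drug <- read_cohort("results/cohort_drug.tsv")

tree_icd <- toy_tree("ICD10")
tree_atc <- toy_tree("ATC")
hz <- hazard_config()

ev_icd <- exclude_chapters(simulate_events(cohort, tree_icd, hz,
                                           seed = seed + 2L))
ev_icd$code <- as.character(apply_mask(ev_icd$code, "ICD10",
                                       tree = tree_icd))
scan_icd <- tbss_scan(ev_icd, cohort, tree_icd, R = 999L, k = 10L,
                      seed = seed + 4L)
cat("ICD-10 tree scan (full cohort):\n")
print(scan_icd)

ev_atc <- simulate_events(cohort, tree_atc, hz, seed = seed + 3L)
ev_atc$code <- as.character(apply_mask(ev_atc$code, "ATC",
                                       tree = tree_atc))
ev_atc <- ev_atc[ev_atc$child_id %in% drug$child_id, ]
scan_atc <- tbss_scan(ev_atc, drug, tree_atc, R = 999L, k = 10L,
                      seed = seed + 5L)
cat("\nATC tree scan (drug-register sub-cohort):\n")
print(scan_atc)

if (min(scan_icd$table$p_adj) > 0.05 && min(scan_atc$table$p_adj) > 0.05) {
  cat("\nno cut reaches adjusted p <= 0.05: the uniform utilisation excess\n")
  cat("spreads over the whole tree rather than clustering, as expected\n")
  cat("under the generator's health-seeking (no-cluster) defaults\n")
}
write.table(scan_icd$table, "results/table3_icd.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(scan_atc$table, "results/table3_atc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/table3_icd.tsv and results/table3_atc.tsv\n")
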