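#!/usr/bin/env Rscript
# Stage 2: build the matched analysis cohort.
#
# Weighted 1:5 matching on maternal age (exact integer age, caliper
# widening to +/-1 year where exhausted), follow-up to the earliest of
# death, emigration, and age five, and the drug-register sub-cohort
# (matched sets whose exposed child was born on/after 2005-07-01).

library(utilscan)

seed <- 20260930L
read_registry <- function(path)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             colClasses = NA)

exposed <- read_registry("results/registry/children_exposed.tsv")
pool <- read_registry("results/registry/children_pool.tsv")
for (df in c("exposed", "pool")) {
  d <- get(df)
  for (col in c("birth_date", "death_date", "emigration_date"))
    d[[col]] <- as.Date(d[[col]])
  assign(df, d)
}

cohort <- match_children(exposed, pool, ratio = 5L, seed = seed + 1L)
cohort <- define_followup(cohort)
cat(sprintf("matched cohort: %d exposed + %d comparators (%d sets needed the wider caliper)\n",
            sum(cohort$role == "exposed"),
            sum(cohort$role == "comparator"),
            attr(cohort, "n_widened")))
cat(sprintf("person-time: %.0f person-years total, mean %.2f per child\n",
            sum(cohort$person_years), mean(cohort$person_years)))

drug <- build_drug_subcohort(cohort)
cat(sprintf("drug-register sub-cohort: %d children (%d sets)\n",
            nrow(drug), attr(drug, "n_sets")))

write_registry_table(cohort, "results/cohort.tsv", seed)
write_registry_table(drug, "results/cohort_drug.tsv", seed)
cat("wrote results/cohort.tsv and results/cohort_drug.tsv\n")
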