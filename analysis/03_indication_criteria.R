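#!/usr/bin/env Rscript
# Stage 3: national germline-testing indication criteria.
#
# Evaluates the HBOC personal/family rules and the LS rules for every
# patient and partitions the cohort into LS-only / HBOC-only / both /
# non-indicated.

library(ecgermline)

phenotypes <- read_patient_table("results/cohort/phenotypes.tsv")
relatives <- read_relatives_table("results/cohort/relatives.tsv")

groups <- assign_indication_groups(phenotypes, relatives)
readr::write_tsv(groups, "results/indication_groups.tsv")

counts <- partition_cohort(groups)
n <- sum(counts)
for (g in names(counts)) {
  cat(sprintf("%-10s %4d/%d (%.1f%%)\n", g, counts[[g]], n,
              100 * counts[[g]] / n))
}
cat("Per-patient rule traces written to results/indication_groups.tsv\n")
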