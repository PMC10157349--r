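#!/usr/bin/env Rscript
# Stage 4: case-control carrier burden.
#
# Builds per-gene and aggregate 2x2 carrier tables against the controls and
# estimates odds ratios with Woolf 95% confidence intervals (chi-square or
# Fisher p-values by the expected-count rule). Then repeats the analysis for
# candidate genes after removing every carrier of a PV in an
# EC-predisposition gene from both cohorts, including the pooled POLE/POLD1
# loss-of-function row.

library(ecgermline)

panel <- load_gene_panel()
case_triage <- triage_cohort(
  read_variant_table("results/cohort/case_variants.tsv"), n_subjects = 527)
control_triage <- triage_cohort(
  read_variant_table("results/cohort/control_variants.tsv"), n_subjects = 1662)
groups <- readr::read_tsv("results/indication_groups.tsv",
                          show_col_types = FALSE)

burden <- gene_level_burden(case_triage, control_triage, panel,
                            groups = groups)
readr::write_tsv(burden, "results/burden_panel.tsv")

candidate <- carrier_excluded_burden(case_triage, control_triage, panel)
readr::write_tsv(candidate, "results/burden_candidate.tsv")
denoms <- attr(candidate, "denominators")

show <- function(tab, gene) {
  r <- tab[tab$gene == gene, ]
  if (is.na(r$or)) {
    cat(sprintf("%-20s %3d vs %3d  OR N.A.\n", gene, r$carriers_cases,
                r$carriers_controls))
  } else {
    cat(sprintf("%-20s %3d (%.1f%%) vs %3d (%.1f%%)  OR %.2f (%.2f-%.2f)  p=%.2g [%s]\n",
                gene, r$carriers_cases, r$pct_cases, r$carriers_controls,
                r$pct_controls, r$or, r$ci_low, r$ci_high, r$p_value,
                r$test_used))
  }
}
cat("EC-predisposition panel (527 cases vs 1662 controls):\n")
for (g in c("All LS genes", "MLH1", "MSH2", "MSH6", "All HBOC genes",
            "BRCA1", "BRCA2", "CHEK2", "All carriers")) show(burden, g)
cat(sprintf("\nCandidate genes after excluding panel-PV carriers (%d cases vs %d controls):\n",
            denoms[["n_cases"]], denoms[["n_controls"]]))
for (g in c("MUTYH", "FANCA", "POLE/POLD1", "All candidate genes")) {
  show(candidate, g)
}
cat("\nTables written to results/burden_panel.tsv and results/burden_candidate.tsv\n")
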