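#!/usr/bin/env Rscript
# Stage 6: estimator validation by parameter recovery.
#
# Monte-Carlo check of the burden machinery: binomial carrier counts are
# drawn at the study's cohort sizes and aggregate carrier frequencies, the
# Woolf interval is computed for each replicate, and empirical CI coverage
# and mean log-OR bias are reported per gene group, plus a null scenario
# (generating OR = 1).

library(ecgermline)

rec <- recovery_experiment(simulation_params(), n_reps = 200, seed = 1)
null_sim <- ci_coverage_sim(27 / 527, 27 / 527, 527, 1662, n_reps = 200,
                            seed = 1)
rec <- dplyr::bind_rows(
  rec,
  tibble::tibble(group = "null (OR=1)", generating_or = null_sim$generating_or,
                 n_reps = 200L, n_defined = null_sim$n_defined,
                 mean_log_or_bias = null_sim$mean_log_or_bias,
                 coverage = null_sim$coverage))
readr::write_tsv(rec, "results/recovery_experiment.tsv")
print(as.data.frame(rec), row.names = FALSE, digits = 3)
cat("\nReport written to results/recovery_experiment.tsv\n")
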