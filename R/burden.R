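#' Case-control carrier burden estimation
#'
#' Per-gene and aggregate 2x2 carrier tables against population-matched
#' controls, with odds ratios, Woolf (log-method) confidence intervals and
#' chi-square / Fisher exact p-values. Zero-cell tables report an undefined
#' ("N.A.") odds ratio rather than a continuity-corrected one.
#'
#' @name burden_stats
NULL

#' Build a 2x2 carrier contingency table
#'
#' @param case_carriers Character vector of carrier subject ids among cases,
#'   or a single non-negative count.
#' @param n_cases Number of cases.
#' @param control_carriers Carrier ids (or count) among controls.
#' @param n_controls Number of controls.
#' @return A `contingency_table`: list with cells `a` (case carriers), `b`
#'   (case non-carriers), `c` (control carriers), `d` (control non-carriers).
#' @export
carrier_table <- function(case_carriers, n_cases, control_carriers, n_controls) {
  count_of <- function(x) {
    if (is.numeric(x) && length(x) == 1) as.integer(x)
    else length(unique(x))
  }
  a <- count_of(case_carriers)
  c_ <- count_of(control_carriers)
  if (a > n_cases) abort("more case carriers than cases")
  if (c_ > n_controls) abort("more control carriers than controls")
  structure(list(a = a, b = as.integer(n_cases) - a,
                 c = c_, d = as.integer(n_controls) - c_),
            class = "contingency_table")
}

as_matrix.contingency_table <- function(t) {
  matrix(c(t$a, t$b, t$c, t$d), nrow = 2,
         dimnames = list(c("carrier", "non_carrier"), c("case", "control")))
}

#' @export
print.contingency_table <- function(x, ...) {
  print(as_matrix.contingency_table(x))
  invisible(x)
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = (a d)/(b c); the CI is the Woolf log method,
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the
#' standard-normal quantile for the confidence level. Any zero cell makes the
#' estimate undefined (`NA`), mirroring how such rows are reported as "N.A.".
#'
#' @param t A [carrier_table()].
#' @param conf Confidence level, default 0.95.
#' @return List with `or`, `ci_low`, `ci_high`, `conf`.
#' @export
odds_ratio_ci <- function(t, conf = 0.95) {
  stopifnot(inherits(t, "contingency_table"), conf > 0, conf < 1)
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                conf = conf))
  }
  or <- (t$a * t$d) / (t$b * t$c)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  z <- qnorm(1 - (1 - conf) / 2)
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       conf = conf)
}

#' Association test for a 2x2 table
#'
#' Policy `"auto"` uses Fisher's exact test (two-sided) when any expected cell
#' count is below 5, otherwise a Pearson chi-square test without continuity
#' correction. `"chi2"` and `"fisher"` force the named test. The Fisher
#' p-value is the sum of hypergeometric probabilities no greater than that of
#' the observed table. Tables with a degenerate margin (no carriers at all, or
#' nobody) have an undefined p-value.
#'
#' @param t A [carrier_table()].
#' @param policy `"auto"` (default), `"chi2"` or `"fisher"`.
#' @return List with `p_value` and `test_used` (`"chi2"`, `"fisher"`,
#'   `"none"`).
#' @export
association_test <- function(t, policy = c("auto", "chi2", "fisher")) {
  policy <- match.arg(policy)
  stopifnot(inherits(t, "contingency_table"))
  m <- as_matrix.contingency_table(t)
  n <- sum(m)
  if (n == 0 || any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(p_value = NA_real_, test_used = "none"))
  }
  expected <- outer(rowSums(m), colSums(m)) / n
  use_fisher <- switch(policy,
    auto = any(expected < 5),
    fisher = TRUE,
    chi2 = FALSE
  )
  if (use_fisher) {
    p <- fisher.test(m)$p.value
    list(p_value = min(p, 1), test_used = "fisher")
  } else {
    p <- suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
    list(p_value = p, test_used = "chi2")
  }
}

burden_row <- function(label, group, case_ids, n_cases, control_ids,
                       n_controls, conf, policy, group_counts = NULL) {
  t <- carrier_table(case_ids, n_cases, control_ids, n_controls)
  orci <- odds_ratio_ci(t, conf)
  test <- association_test(t, policy)
  row <- tibble(
    gene = label, group = group,
    carriers_cases = t$a, pct_cases = 100 * t$a / max(n_cases, 1),
    carriers_controls = t$c, pct_controls = 100 * t$c / max(n_controls, 1),
    or = orci$or, ci_low = orci$ci_low, ci_high = orci$ci_high,
    p_value = test$p_value, test_used = test$test_used
  )
  if (!is.null(group_counts)) row <- dplyr::bind_cols(row, group_counts)
  row
}

# Carrier counts of a subject-id vector per indication group; `groups` is the
# assign_indication_groups() output for the case cohort.
indication_counts <- function(ids, groups) {
  if (is.null(groups)) return(NULL)
  g <- groups$indication_group[match(ids, groups$patient_id)]
  counts <- table(factor(g, levels = INDICATION_GROUPS))
  tibble(n_ls_only = as.integer(counts[["LS_ONLY"]]),
         n_hboc_only = as.integer(counts[["HBOC_ONLY"]]),
         n_both = as.integer(counts[["BOTH"]]),
         n_none = as.integer(counts[["NONE"]]))
}

#' Gene-level burden table for the EC-predisposition panel
#'
#' One row per LS/HBOC panel gene plus aggregate rows `All LS genes`,
#' `All HBOC genes` and `All carriers`; aggregates count unique subjects, so a
#' patient with PV in two genes of a group counts once there. When the case
#' indication-group assignment is supplied, per-group carrier counts are
#' emitted alongside (the indication-distribution surface).
#'
#' @param case_triage,control_triage `triage_summary` objects computed with
#'   identical thresholds.
#' @param panel A `gene_panel`.
#' @param groups Optional [assign_indication_groups()] output for the cases.
#' @param conf Confidence level for the Woolf CI.
#' @param policy Test policy for [association_test()].
#' @return A tibble, one row per gene/aggregate.
#' @export
gene_level_burden <- function(case_triage, control_triage, panel,
                              groups = NULL, conf = 0.95, policy = "auto") {
  n_cases <- case_triage$n_subjects
  n_controls <- control_triage$n_subjects
  rows <- list()
  for (grp in c("LS", "HBOC")) {
    for (gene in panel_genes(panel, grp)) {
      rows[[length(rows) + 1L]] <- burden_row(
        gene, grp,
        carriers_of(case_triage, gene), n_cases,
        carriers_of(control_triage, gene), n_controls,
        conf, policy, indication_counts(carriers_of(case_triage, gene), groups))
    }
    agg_ids <- carriers_of(case_triage, panel_genes(panel, grp))
    rows[[length(rows) + 1L]] <- burden_row(
      paste("All", grp, "genes"), grp,
      agg_ids, n_cases,
      carriers_of(control_triage, panel_genes(panel, grp)), n_controls,
      conf, policy, indication_counts(agg_ids, groups))
  }
  all_genes <- panel_genes(panel, c("LS", "HBOC"))
  all_ids <- carriers_of(case_triage, all_genes)
  rows[[length(rows) + 1L]] <- burden_row(
    "All carriers", "ALL",
    all_ids, n_cases,
    carriers_of(control_triage, all_genes), n_controls,
    conf, policy, indication_counts(all_ids, groups))
  bind_rows(rows)
}

#' Candidate-gene burden with EC-predisposition carriers excluded
#'
#' Removes every subject carrying at least one PV in an LS or HBOC gene from
#' both numerators and denominators, then computes candidate-gene burden. A
#' pooled `POLE/POLD1` loss-of-function row and an `All candidate genes`
#' aggregate are appended.
#'
#' @inheritParams gene_level_burden
#' @param min_case_carriers Per-gene rows are emitted only for genes with at
#'   least this many case carriers (default 1); aggregates always cover all
#'   candidate genes.
#' @return A tibble; the attribute `denominators` records the carrier-excluded
#'   cohort sizes.
#' @export
carrier_excluded_burden <- function(case_triage, control_triage, panel,
                                    conf = 0.95, policy = "auto",
                                    min_case_carriers = 1) {
  pred_genes <- panel_genes(panel, c("LS", "HBOC"))
  excl_cases <- carriers_of(case_triage, pred_genes)
  excl_controls <- carriers_of(control_triage, pred_genes)
  n_cases <- case_triage$n_subjects - length(excl_cases)
  n_controls <- control_triage$n_subjects - length(excl_controls)

  keep <- function(summary, excluded, genes) {
    ids <- summary$carriers$subject_id[summary$carriers$gene %in% genes]
    unique(setdiff(ids, excluded))
  }
  cand <- panel_genes(panel, "CANDIDATE")
  rows <- list()
  for (gene in cand) {
    case_ids <- keep(case_triage, excl_cases, gene)
    control_ids <- keep(control_triage, excl_controls, gene)
    if (length(case_ids) < min_case_carriers) next
    rows[[length(rows) + 1L]] <- burden_row(
      gene, "CANDIDATE", case_ids, n_cases, control_ids, n_controls,
      conf, policy)
  }
  pol <- intersect(c("POLE", "POLD1"), cand)
  rows[[length(rows) + 1L]] <- burden_row(
    "POLE/POLD1", "CANDIDATE",
    keep(case_triage, excl_cases, pol), n_cases,
    keep(control_triage, excl_controls, pol), n_controls, conf, policy)
  rows[[length(rows) + 1L]] <- burden_row(
    "All candidate genes", "CANDIDATE",
    keep(case_triage, excl_cases, cand), n_cases,
    keep(control_triage, excl_controls, cand), n_controls, conf, policy)
  out <- bind_rows(rows)
  attr(out, "denominators") <- c(n_cases = n_cases, n_controls = n_controls)
  out
}
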