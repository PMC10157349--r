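#' End-to-end pipeline
#'
#' Orchestrates triage, indication-criteria partition, burden estimation
#' (panel plus carrier-excluded candidate analysis) and clinicopathological
#' summaries from a single configuration, writing a reproducible report
#' bundle.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' @param paths Named list: `case_variants`, `control_variants`, `phenotypes`,
#'   `relatives`, `panel` (optional; bundled default), `out_dir`.
#' @param triage Named list of [filter_thresholds()] arguments.
#' @param criteria Named list of [criteria_options()] arguments.
#' @param stats Named list: `conf` (default 0.95), `policy` (default
#'   `"auto"`).
#' @param n_controls Control cohort size (denominator; defaults to the number
#'   of distinct subjects in the control variant table).
#' @param n_cases As above, for cases (defaults to the number of patients in
#'   the phenotype table).
#' @param seed Integer seed recorded in the run log.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(paths, triage = list(), criteria = list(),
                            stats = list(), n_controls = NULL, n_cases = NULL,
                            seed = 1L) {
  required <- c("case_variants", "control_variants", "phenotypes", "out_dir")
  missing <- setdiff(required, names(paths))
  if (length(missing) > 0) {
    abort(paste0("pipeline config is missing path key(s): ",
                 paste(missing, collapse = ", ")))
  }
  structure(list(paths = paths, triage = triage, criteria = criteria,
                 stats = stats, n_controls = n_controls, n_cases = n_cases,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys `paths`, `triage`, `criteria`, `stats`,
#'   `n_controls`, `n_cases`, `seed`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  cfg <- yaml::read_yaml(path)
  pipeline_config(
    paths = cfg$paths,
    triage = cfg$triage %||% list(),
    criteria = cfg$criteria %||% list(),
    stats = cfg$stats %||% list(),
    n_controls = cfg$n_controls, n_cases = cfg$n_cases,
    seed = cfg$seed %||% 1L
  )
}

#' Run the full pipeline
#'
#' Stages: variant triage of cases and controls, indication-criteria
#' partition, gene-level burden (panel genes plus the carrier-excluded
#' candidate-gene analysis) and clinicopathological summaries. Every output
#' file carries a header comment naming the configuration hash; the
#' configuration itself is echoed into the bundle.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @return Invisibly, a list with the in-memory stage results and the bundle
#'   directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$paths
  for (key in c("case_variants", "control_variants", "phenotypes")) {
    if (!file.exists(p[[key]])) {
      abort(paste0("config path '", key, "' does not exist: ", p[[key]]))
    }
  }
  out <- p$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  echo_path <- file.path(out, "config_echo.yaml")
  yaml::write_yaml(unclass(config), echo_path)
  cfg_hash <- unname(tools::md5sum(echo_path))
  stamp <- paste0("config_md5=", cfg_hash)
  log_lines <- c(
    paste0("ecgermline ", as.character(utils::packageVersion("ecgermline"))),
    paste0("R ", R.version.string),
    paste0("seed=", config$seed),
    stamp
  )

  thresholds <- do.call(filter_thresholds, config$triage)
  options <- do.call(criteria_options, config$criteria)
  conf <- config$stats$conf %||% 0.95
  policy <- config$stats$policy %||% "auto"

  panel <- load_gene_panel(p$panel)
  phenotypes <- read_patient_table(p$phenotypes)
  relatives <- if (!is.null(p$relatives)) read_relatives_table(p$relatives)
               else NULL
  n_cases <- config$n_cases %||% dplyr::n_distinct(phenotypes$patient_id)

  case_variants <- read_variant_table(p$case_variants)
  control_variants <- read_variant_table(p$control_variants)
  n_controls <- config$n_controls %||%
    dplyr::n_distinct(control_variants$subject_id)

  case_triage <- triage_cohort(case_variants, thresholds, n_subjects = n_cases)
  control_triage <- triage_cohort(control_variants, thresholds,
                                  n_subjects = n_controls)
  write_decision_trace(case_triage, file.path(out, "triage_cases.tsv"), stamp)
  write_decision_trace(control_triage, file.path(out, "triage_controls.tsv"),
                       stamp)

  groups <- assign_indication_groups(phenotypes, relatives, options)
  write_tsv_commented(groups, file.path(out, "indication_groups.tsv"), stamp)
  partition <- partition_cohort(groups)

  burden <- gene_level_burden(case_triage, control_triage, panel,
                              groups = groups, conf = conf, policy = policy)
  write_tsv_commented(burden, file.path(out, "burden_panel.tsv"), stamp)
  candidate <- carrier_excluded_burden(case_triage, control_triage, panel,
                                       conf = conf, policy = policy)
  write_tsv_commented(candidate, file.path(out, "burden_candidate.tsv"), stamp)

  carrier_groups <- assign_carrier_groups(unique(phenotypes$patient_id),
                                          case_triage, panel)
  ages <- ec_onset_ages(phenotypes)
  age_cmp <- age_at_onset_comparison(ages, carrier_groups)
  jsonlite::write_json(
    list(config_md5 = cfg_hash,
         group_stats = age_cmp$group_stats,
         f_statistic = age_cmp$f_statistic, p_anova = age_cmp$p_anova,
         pairwise = age_cmp$pairwise),
    file.path(out, "age_comparison.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, na = "null")
  subgroup <- list()
  for (s in c("histology", "second_primary", "family_history")) {
    tab <- suppressWarnings(
      subgroup_frequencies(phenotypes, relatives, carrier_groups, s))
    write_tsv_commented(tab, file.path(out, paste0("subgroups_", s, ".tsv")),
                        stamp)
    subgroup[[s]] <- tab
  }

  writeLines(c(log_lines, paste0("partition=",
                                 paste(names(partition), partition,
                                       sep = ":", collapse = " "))),
             file.path(out, "run_log.txt"))
  invisible(list(
    out_dir = out, config_md5 = cfg_hash,
    case_triage = case_triage, control_triage = control_triage,
    groups = groups, partition = partition,
    burden = burden, candidate_burden = candidate,
    carrier_groups = carrier_groups, age_comparison = age_cmp,
    subgroups = subgroup
  ))
}
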