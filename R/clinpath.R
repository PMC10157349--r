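#' Clinicopathological stratification of carriers
#'
#' Carrier-group assignment, age-at-onset comparison (one-way ANOVA with
#' Tukey-Kramer pairwise adjustment; medians reported alongside), and carrier
#' frequency tables by histology, second primary tumors and family cancer
#' history.
#'
#' @name clinpath_summaries
NULL

#' Assign each patient a carrier group
#'
#' Total partition with precedence LS > HBOC > CANDIDATE > NON: a patient with
#' PV in both an LS and an HBOC gene is displayed as an LS carrier (full
#' per-gene membership stays available in the triage summary).
#'
#' @param patient_ids Character vector of all case patient ids.
#' @param case_triage The case `triage_summary`.
#' @param panel A `gene_panel`.
#' @return Tibble `patient_id`, `carrier_group`.
#' @export
assign_carrier_groups <- function(patient_ids, case_triage, panel) {
  ls_ids <- carriers_of(case_triage, panel_genes(panel, "LS"))
  hboc_ids <- carriers_of(case_triage, panel_genes(panel, "HBOC"))
  cand_ids <- carriers_of(case_triage, panel_genes(panel, "CANDIDATE"))
  tibble(
    patient_id = patient_ids,
    carrier_group = dplyr::case_when(
      patient_ids %in% ls_ids ~ "LS_CARRIER",
      patient_ids %in% hboc_ids ~ "HBOC_CARRIER",
      patient_ids %in% cand_ids ~ "CANDIDATE_CARRIER",
      TRUE ~ "NON_CARRIER"
    )
  )
}

#' Age at endometrial cancer diagnosis per patient
#'
#' The age used throughout the clinicopathological comparisons is the age at
#' the endometrial (C54/C55) diagnosis specifically, not at the first cancer.
#'
#' @param phenotypes Phenotype tibble.
#' @return Tibble `patient_id`, `age_ec` (`NA` when unknown).
#' @export
ec_onset_ages <- function(phenotypes) {
  phenotypes <- validate_phenotypes(phenotypes)
  ec <- phenotypes[icd_match(phenotypes$icd10, EC_CODES), ]
  ec %>%
    group_by(.data$patient_id) %>%
    summarise(age_ec = if (all(is.na(.data$age_at_dx))) NA_real_
              else min(.data$age_at_dx, na.rm = TRUE), .groups = "drop")
}

#' Compare age at EC onset across carrier groups
#'
#' One-way ANOVA across carrier groups followed by Tukey-Kramer adjusted
#' pairwise comparisons (Tukey's HSD on unbalanced groups). Unknown ages are
#' excluded listwise. Medians and means are reported per group alongside the
#' omnibus test.
#'
#' @param ages Tibble with `patient_id`, `age_ec` (see [ec_onset_ages()]).
#' @param groups Tibble with `patient_id`, `carrier_group`
#'   ([assign_carrier_groups()]).
#' @return An `age_comparison` list: `group_stats` (n, median, mean per
#'   group), `f_statistic`, `p_anova`, `pairwise` (tibble with adjusted p per
#'   group pair). Undefined statistics (with a warning) when fewer than two
#'   groups have two or more known ages.
#' @export
age_at_onset_comparison <- function(ages, groups) {
  df <- dplyr::inner_join(ages, groups, by = "patient_id") %>%
    filter(!is.na(.data$age_ec))
  stats_tbl <- df %>%
    group_by(carrier_group = .data$carrier_group) %>%
    summarise(n = dplyr::n(), median = median(.data$age_ec),
              mean = mean(.data$age_ec), .groups = "drop")
  usable <- stats_tbl$n >= 2
  if (sum(usable) < 2) {
    warn("fewer than two carrier groups with >= 2 known ages; ANOVA undefined")
    return(structure(list(group_stats = stats_tbl, f_statistic = NA_real_,
                          p_anova = NA_real_, pairwise = tibble()),
                     class = "age_comparison"))
  }
  df <- df[df$carrier_group %in% stats_tbl$carrier_group[usable], ]
  df$carrier_group <- factor(df$carrier_group)
  fit <- aov(age_ec ~ carrier_group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$carrier_group
  pairwise <- tibble(
    comparison = rownames(tk),
    diff = tk[, "diff"],
    ci_low = tk[, "lwr"],
    ci_high = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  structure(list(
    group_stats = stats_tbl,
    f_statistic = an[["F value"]][1],
    p_anova = an[["Pr(>F)"]][1],
    pairwise = pairwise
  ), class = "age_comparison")
}

#' @export
print.age_comparison <- function(x, ...) {
  cat("<age_comparison> F =", format(x$f_statistic, digits = 4),
      ", ANOVA p =", format(x$p_anova, digits = 3), "\n")
  print(x$group_stats)
  invisible(x)
}

# Derive the stratum of one patient for a given stratifier.
patient_stratum <- function(patient, stratifier) {
  dx <- patient$diagnoses
  ec <- dx[icd_match(dx$icd10, EC_CODES), ]
  if (stratifier == "histology") {
    h <- ec$histology[!is.na(ec$histology)]
    return(if (length(h) == 0) NA_character_ else h[1])
  }
  if (stratifier == "second_primary") {
    other <- dx[!icd_match(dx$icd10, EC_CODES), ]
    has_crc <- any(icd_match(other$icd10, CRC_CODES))
    has_oc <- any(icd_match(other$icd10, "C56"))
    has_bc <- any(icd_match(other$icd10, "C50"))
    n_other <- nrow(other)
    if (n_other == 0) return("none")
    if (n_other >= 2 && (has_crc + has_oc + has_bc) >= 1) return("triple")
    if (has_crc) return("CRC")
    if (has_oc) return("OC")
    if (has_bc) return("BC")
    return("other")
  }
  if (stratifier == "family_history") {
    if (!isTRUE(patient$fh_known)) return(NA_character_)
    rel <- patient$relatives
    if (nrow(rel) == 0) return("none")
    has <- c(EC = any(icd_match(rel$icd10, EC_CODES)),
             CRC = any(icd_match(rel$icd10, CRC_CODES)),
             OC = any(icd_match(rel$icd10, "C56")),
             BC = any(icd_match(rel$icd10, "C50")))
    if (sum(has[c("EC", "CRC", "OC")]) >= 2) return("multiple")
    if (has[["CRC"]]) return("CRC")
    if (has[["OC"]]) return("OC")
    if (has[["EC"]]) return("EC")
    if (has[["BC"]]) return("BC")
    return("other")
  }
  abort(paste0("unknown stratifier: ", stratifier))
}

#' Carrier frequencies by clinicopathological stratum
#'
#' Per-stratum carrier proportions; patients with an unknown value of the
#' stratifier are excluded from that stratifier's denominators (proportions
#' are over patients with known characteristics). Second-primary strata:
#' `CRC`, `OC`, `BC`, `triple` (EC plus two or more further primaries),
#' `other`, `none`. Family-history strata: `multiple` (two or more of EC, CRC,
#' OC among relatives), `CRC`, `OC`, `EC`, `BC`, `other`, `none`.
#'
#' @param phenotypes Phenotype tibble.
#' @param relatives Relatives tibble (or `NULL`).
#' @param groups [assign_carrier_groups()] output.
#' @param stratifier `"histology"`, `"second_primary"` or `"family_history"`.
#' @return Tibble: `stratum`, `n`, carrier counts per group, and
#'   `prop_carrier` (proportion carrying PV in any EC-predisposition gene).
#' @export
subgroup_frequencies <- function(phenotypes, relatives, groups,
                                 stratifier = c("histology", "second_primary",
                                                "family_history")) {
  stratifier <- match.arg(stratifier)
  patients <- as_patient_list(phenotypes, relatives)
  strata <- vapply(patients, patient_stratum, character(1),
                   stratifier = stratifier)
  df <- tibble(patient_id = names(strata), stratum = unname(strata)) %>%
    left_join(groups, by = "patient_id")
  dropped <- sum(is.na(df$stratum))
  if (dropped > 0) {
    warn(paste0(dropped, " patient(s) with unknown ", stratifier,
                " excluded from denominators"))
  }
  df %>%
    filter(!is.na(.data$stratum)) %>%
    group_by(stratum = .data$stratum) %>%
    summarise(
      n = dplyr::n(),
      n_ls = sum(.data$carrier_group == "LS_CARRIER"),
      n_hboc = sum(.data$carrier_group == "HBOC_CARRIER"),
      n_candidate = sum(.data$carrier_group == "CANDIDATE_CARRIER"),
      n_non = sum(.data$carrier_group == "NON_CARRIER"),
      prop_carrier = (n_ls + n_hboc) / n,
      .groups = "drop"
    ) %>%
    arrange(dplyr::desc(.data$n))
}
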