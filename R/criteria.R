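#' National germline-testing indication criteria
#'
#' Encodes the national indication criteria for hereditary breast/ovarian
#' cancer (HBOC) and Lynch syndrome (LS) germline testing and partitions a
#' cohort into LS-only / HBOC-only / both / non-indicated. Unknown values use
#' three-valued logic: a comparison against an unknown age is false, so an
#' age-bounded rule never fires on missing data.
#'
#' @name criteria_engine
NULL

# Default LS-linked diagnosis code set (patient side): colorectal, stomach,
# pancreatic, ovarian, small intestine, ureter, renal pelvis, bile tract,
# glioblastoma (C71 prefix).
LS_LINKED_CODES <- c("C18", "C19", "C20", "C16", "C25", "C56", "C17",
                     "C66", "C65", "C23", "C24", "C71")
EC_CODES <- c("C54", "C55")
CRC_CODES <- c("C18", "C19", "C20")

#' Criteria engine options
#'
#' @param ls_linked_codes ICD-10 prefixes counted as LS-linked diagnoses for
#'   the patient.
#' @param ls4_age_mode How the `<50 years` condition of the first-degree
#'   relative rule (LS-4) is applied: `"either"` (default; the patient's index
#'   diagnosis or the relative's diagnosis is under 50), `"both"`, or
#'   `"relative_only"`.
#' @param relative_codes_include_ec Whether endometrial cancer itself counts
#'   as an LS-linked diagnosis on the relative side of LS-4/LS-5 (default
#'   `TRUE`).
#' @return A `criteria_options` list.
#' @export
criteria_options <- function(ls_linked_codes = LS_LINKED_CODES,
                             ls4_age_mode = c("either", "both", "relative_only"),
                             relative_codes_include_ec = TRUE) {
  ls4_age_mode <- match.arg(ls4_age_mode)
  structure(list(
    ls_linked_codes = ls_linked_codes,
    ls4_age_mode = ls4_age_mode,
    relative_codes_include_ec = relative_codes_include_ec
  ), class = "criteria_options")
}

# Comparisons that must be FALSE (never NA) on unknown values.
lt <- function(x, y) !is.na(x) & x < y
le <- function(x, y) !is.na(x) & x <= y

#' Build per-patient objects from the flat tables
#'
#' @param phenotypes Phenotype tibble ([read_patient_table()]).
#' @param relatives Relatives tibble ([read_relatives_table()]); may be
#'   `NULL`.
#' @return A named list of patient objects, each with `patient_id`, `sex`,
#'   `fh_known`, `diagnoses` and `relatives`.
#' @export
as_patient_list <- function(phenotypes, relatives = NULL) {
  phenotypes <- validate_phenotypes(phenotypes)
  if (is.null(relatives)) {
    relatives <- tibble(patient_id = character(0), degree = character(0),
                        direct_line = logical(0), icd10 = character(0),
                        age_at_dx = numeric(0), sex = character(0))
  }
  relatives <- validate_relatives(relatives)
  ids <- unique(phenotypes$patient_id)
  out <- lapply(ids, function(id) {
    dx <- phenotypes[phenotypes$patient_id == id, ]
    list(
      patient_id = id,
      sex = dx$sex[1],
      fh_known = isTRUE(dx$fh_known[1]),
      diagnoses = dx,
      relatives = relatives[relatives$patient_id == id, ]
    )
  })
  setNames(out, ids)
}

#' Evaluate the HBOC indication criteria for one patient
#'
#' Personal-history rules: HBOC-P1 (breast cancer, C50, under 45, or under 50
#' when family history is unknown), HBOC-P2 (bilateral C50, first under 50 and
#' both under 60), HBOC-P3 (triple-negative C50 at 60 or younger), HBOC-P4
#' (male with C50), HBOC-P5 (C56/C57/C48), HBOC-P6 (C50 and C25 double
#' primary, any age). Family rules: HBOC-F1 (patient plus two relatives with
#' C50), HBOC-F2 (patient plus one relative with C50, one diagnosis under 50
#' or both under 60), HBOC-F3 (patient with a qualifying diagnosis plus a
#' direct-line relative with ovarian/fallopian/peritoneal cancer, pancreatic
#' cancer, prostate cancer, or male breast cancer).
#'
#' @param patient A patient object from [as_patient_list()].
#' @return List with `met` (logical) and `fired_rules` (character).
#' @export
evaluate_hboc_criteria <- function(patient) {
  dx <- patient$diagnoses
  rel <- patient$relatives
  fired <- character(0)

  c50 <- dx[icd_match(dx$icd10, "C50"), ]
  has_c50 <- nrow(c50) > 0
  fh_known <- isTRUE(patient$fh_known)

  # P1: C50 <45, or <50 if family history unknown
  age_cut <- if (fh_known) 45 else 50
  if (has_c50 && any(lt(c50$age_at_dx, age_cut))) fired <- c(fired, "HBOC-P1")

  # P2: bilateral C50, first <50, both <60. With a single bilateral record the
  # recorded age is the first diagnosis; with two C50 records the younger must
  # be <50 and the older <60.
  if (has_c50) {
    if (nrow(c50) >= 2) {
      ages <- c50$age_at_dx
      if (all(!is.na(ages)) && min(ages) < 50 && max(ages) < 60) {
        fired <- c(fired, "HBOC-P2")
      }
    } else if (isTRUE(c50$bilateral[1]) && lt(c50$age_at_dx[1], 50)) {
      fired <- c(fired, "HBOC-P2")
    }
  }

  # P3: triple-negative C50 <=60
  if (has_c50 && any(!is.na(c50$triple_negative) & c50$triple_negative &
                     le(c50$age_at_dx, 60))) {
    fired <- c(fired, "HBOC-P3")
  }

  # P4: male with C50
  if (has_c50 && identical(patient$sex, "male")) fired <- c(fired, "HBOC-P4")

  # P5: C56/C57/C48
  if (any(icd_match(dx$icd10, c("C56", "C57", "C48")))) {
    fired <- c(fired, "HBOC-P5")
  }

  # P6: C50 + C25 double primary, any ages
  if (has_c50 && any(icd_match(dx$icd10, "C25"))) fired <- c(fired, "HBOC-P6")

  rel_c50 <- rel[icd_match(rel$icd10, "C50"), ]

  # F1: patient C50 plus >=2 relatives with C50
  if (has_c50 && nrow(rel_c50) >= 2) fired <- c(fired, "HBOC-F1")

  # F2: patient C50 plus 1 relative C50; one dx <50, or both <60
  if (has_c50 && nrow(rel_c50) >= 1) {
    pa <- c50$age_at_dx
    for (ra in rel_c50$age_at_dx) {
      if (any(lt(pa, 50)) || lt(ra, 50) ||
          (any(lt(pa, 60)) && lt(ra, 60))) {
        fired <- c(fired, "HBOC-F2")
        break
      }
    }
  }

  # F3: proband with a qualifying dx (C50 or gynecologic C56/C57/C48) plus a
  # direct-line relative with: C56/C57/C48, pancreatic (C25), prostate (C61),
  # or a male relative with C50. Relative-level receptor status and Gleason
  # grade are not representable in the relative schema, so those refinements
  # are not applied.
  proband_qualifies <- has_c50 || any(icd_match(dx$icd10, c("C56", "C57", "C48")))
  if (proband_qualifies && nrow(rel) > 0) {
    direct <- rel[!is.na(rel$direct_line) & rel$direct_line, ]
    if (nrow(direct) > 0) {
      qual <- icd_match(direct$icd10, c("C56", "C57", "C48", "C25", "C61")) |
        (icd_match(direct$icd10, "C50") &
           !is.na(direct$sex) & direct$sex == "male")
      if (any(qual)) fired <- c(fired, "HBOC-F3")
    }
  }

  list(met = length(fired) > 0, fired_rules = unique(fired))
}

#' Evaluate the LS indication criteria for one patient
#'
#' Applies to patients with a colorectal (C18-C20) or endometrial (C54/C55)
#' index diagnosis. Rules: LS-1 (index diagnosis under 50), LS-2 (proven
#' microsatellite instability under 60), LS-3 (a concurrent LS-linked
#' diagnosis), LS-4 (one first-degree relative with an LS-linked diagnosis,
#' with an under-50 age condition configurable via
#' [criteria_options()]), LS-5 (two second-degree relatives with LS-linked
#' diagnoses at any age), LS-6 (colorectal cancer with more than ten
#' adenomas/polyps).
#'
#' @param patient A patient object from [as_patient_list()].
#' @param options A [criteria_options()] object.
#' @return List with `met` and `fired_rules`.
#' @export
evaluate_ls_criteria <- function(patient, options = criteria_options()) {
  dx <- patient$diagnoses
  index <- dx[icd_match(dx$icd10, c(CRC_CODES, EC_CODES)), ]
  if (nrow(index) == 0) {
    abort(paste0("patient ", patient$patient_id,
                 " has no colorectal or endometrial index diagnosis"))
  }
  rel <- patient$relatives
  fired <- character(0)
  index_ages <- index$age_at_dx

  # LS-1: index diagnosis <50
  if (any(lt(index_ages, 50))) fired <- c(fired, "LS-1")

  # LS-2: proven MSI and <60
  if (any(mapply(function(msi, a) isTRUE(msi) && lt(a, 60),
                 index$msi_positive, index$age_at_dx))) {
    fired <- c(fired, "LS-2")
  }

  # LS-3: concurrent LS-linked diagnosis (a second primary beyond the index).
  # An endometrial index with a concurrent colorectal primary qualifies and
  # vice versa; the index record itself is not counted.
  is_index <- seq_len(nrow(dx)) %in% which(icd_match(dx$icd10, c(CRC_CODES, EC_CODES)))[1]
  concurrent <- dx[!is_index, ]
  if (any(icd_match(concurrent$icd10, options$ls_linked_codes))) {
    fired <- c(fired, "LS-3")
  }

  rel_codes <- options$ls_linked_codes
  if (isTRUE(options$relative_codes_include_ec)) rel_codes <- c(rel_codes, EC_CODES)
  rel_linked <- rel[icd_match(rel$icd10, rel_codes), ]

  # LS-4: >=1 first-degree relative with an LS-linked dx; age condition per
  # ls4_age_mode
  first_deg <- rel_linked[rel_linked$degree == "first", ]
  if (nrow(first_deg) > 0) {
    patient_young <- any(lt(index_ages, 50))
    rel_young <- lt(first_deg$age_at_dx, 50)
    ok <- switch(options$ls4_age_mode,
      either = patient_young | rel_young,
      both = patient_young & rel_young,
      relative_only = rel_young
    )
    if (any(ok)) fired <- c(fired, "LS-4")
  }

  # LS-5: >=2 second-degree relatives with LS-linked dx, any age
  if (sum(rel_linked$degree == "second") >= 2) fired <- c(fired, "LS-5")

  # LS-6: colorectal cancer with >10 adenomas/polyps
  crc <- dx[icd_match(dx$icd10, CRC_CODES), ]
  if (nrow(crc) > 0 && any(!is.na(crc$adenoma_count) & crc$adenoma_count > 10)) {
    fired <- c(fired, "LS-6")
  }

  list(met = length(fired) > 0, fired_rules = unique(fired))
}

#' Assign a patient's indication group
#'
#' Cross-product of the HBOC and LS results: `LS_ONLY`, `HBOC_ONLY`, `BOTH`
#' or `NONE`. A patient without a colorectal/endometrial index diagnosis is
#' outside the LS criteria's scope and counts as LS-not-met.
#'
#' @param patient A patient object.
#' @param options A [criteria_options()] object.
#' @return One of `"LS_ONLY"`, `"HBOC_ONLY"`, `"BOTH"`, `"NONE"`.
#' @export
assign_indication_group <- function(patient, options = criteria_options()) {
  hboc <- evaluate_hboc_criteria(patient)$met
  has_index <- any(icd_match(patient$diagnoses$icd10, c(CRC_CODES, EC_CODES)))
  ls <- if (has_index) evaluate_ls_criteria(patient, options)$met else FALSE
  if (ls && hboc) "BOTH" else if (ls) "LS_ONLY" else if (hboc) "HBOC_ONLY" else "NONE"
}

#' Evaluate both criteria for a whole cohort
#'
#' @param phenotypes Phenotype tibble.
#' @param relatives Relatives tibble (or `NULL`).
#' @param options A [criteria_options()] object.
#' @return A tibble with one row per patient: `patient_id`, `hboc_met`,
#'   `hboc_rules`, `ls_met`, `ls_rules`, `indication_group`.
#' @export
assign_indication_groups <- function(phenotypes, relatives = NULL,
                                     options = criteria_options()) {
  patients <- as_patient_list(phenotypes, relatives)
  rows <- lapply(patients, function(p) {
    hboc <- evaluate_hboc_criteria(p)
    has_index <- any(icd_match(p$diagnoses$icd10, c(CRC_CODES, EC_CODES)))
    ls <- if (has_index) evaluate_ls_criteria(p, options)
          else list(met = FALSE, fired_rules = character(0))
    tibble(
      patient_id = p$patient_id,
      hboc_met = hboc$met,
      hboc_rules = paste(hboc$fired_rules, collapse = ";"),
      ls_met = ls$met,
      ls_rules = paste(ls$fired_rules, collapse = ";"),
      indication_group = if (ls$met && hboc$met) "BOTH"
        else if (ls$met) "LS_ONLY" else if (hboc$met) "HBOC_ONLY" else "NONE"
    )
  })
  bind_rows(rows)
}

#' Partition a cohort by indication group
#'
#' @param groups Output of [assign_indication_groups()], or a character vector
#'   of group labels.
#' @return Named integer vector over `LS_ONLY`, `HBOC_ONLY`, `BOTH`, `NONE`;
#'   always sums to the cohort size.
#' @export
partition_cohort <- function(groups) {
  if (is.data.frame(groups)) {
    if (anyDuplicated(groups$patient_id)) abort("duplicate patient_id in cohort")
    groups <- groups$indication_group
  }
  counts <- table(factor(groups, levels = INDICATION_GROUPS))
  setNames(as.integer(counts), INDICATION_GROUPS)
}
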