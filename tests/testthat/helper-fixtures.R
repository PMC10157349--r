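# Shared builders and a memoised default-size cohort (simulated once per
# test run; several files inspect different surfaces of the same cohort).

make_variant <- function(subject_id = "S1", gene = "MSH6", chrom = "chr2",
                         pos = 1000L, ref = "A", alt = "G",
                         hgvs_c = "c.1A>G", consequence = "missense",
                         quality = 500, maf_gnomad = 0, maf_esp = NA_real_,
                         maf_1kg = NA_real_, control_freq = 0,
                         clinvar_assertion = NA_character_,
                         clinvar_stars = NA_integer_,
                         clinvar_submitters = NA_integer_,
                         in_last_exon = FALSE) {
  tibble::tibble(
    subject_id = subject_id, gene = gene, chrom = chrom, pos = pos,
    ref = ref, alt = alt, hgvs_c = hgvs_c, consequence = consequence,
    quality = quality, maf_gnomad = maf_gnomad, maf_esp = maf_esp,
    maf_1kg = maf_1kg, control_freq = control_freq,
    clinvar_assertion = clinvar_assertion, clinvar_stars = clinvar_stars,
    clinvar_submitters = clinvar_submitters, in_last_exon = in_last_exon
  )
}

make_patient <- function(patient_id = "P1", sex = "female", dx = list(),
                         relatives = NULL, fh_known = TRUE) {
  rows <- lapply(dx, function(d) {
    defaults <- list(icd10 = "C54", age_at_dx = NA_real_, bilateral = FALSE,
                     triple_negative = FALSE, medullar = FALSE,
                     gleason = NA_integer_, msi_positive = NA,
                     adenoma_count = NA_integer_, histology = NA_character_,
                     figo_grade = NA_character_, figo_stage = NA_character_)
    d <- utils::modifyList(defaults, d)
    tibble::tibble(patient_id = patient_id, sex = sex, icd10 = d$icd10,
                   age_at_dx = d$age_at_dx, bilateral = d$bilateral,
                   triple_negative = d$triple_negative, medullar = d$medullar,
                   gleason = d$gleason, msi_positive = d$msi_positive,
                   adenoma_count = d$adenoma_count, histology = d$histology,
                   figo_grade = d$figo_grade, figo_stage = d$figo_stage,
                   fh_known = fh_known)
  })
  phenotypes <- dplyr::bind_rows(rows)
  rel_rows <- if (is.null(relatives)) NULL else lapply(relatives, function(r) {
    defaults <- list(degree = "first", direct_line = TRUE, icd10 = "C18",
                     age_at_dx = NA_real_, sex = "female")
    r <- utils::modifyList(defaults, r)
    tibble::tibble(patient_id = patient_id, degree = r$degree,
                   direct_line = r$direct_line, icd10 = r$icd10,
                   age_at_dx = r$age_at_dx, sex = r$sex)
  })
  as_patient_list(phenotypes,
                  if (is.null(rel_rows)) NULL else dplyr::bind_rows(rel_rows))[[1]]
}

.fixture_env <- new.env(parent = emptyenv())

default_cohort <- function(seed = 20417) {
  key <- paste0("cohort_", seed)
  if (!exists(key, envir = .fixture_env)) {
    assign(key, simulate_cohort(simulation_params(seed = seed)),
           envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

default_cohort_analysis <- function(seed = 20417) {
  key <- paste0("analysis_", seed)
  if (!exists(key, envir = .fixture_env)) {
    co <- default_cohort(seed)
    panel <- load_gene_panel()
    case_triage <- triage_cohort(co$case_variants,
                                 n_subjects = co$params$n_cases)
    control_triage <- triage_cohort(co$control_variants,
                                    n_subjects = co$params$n_controls)
    groups <- assign_indication_groups(co$phenotypes, co$relatives)
    assign(key, list(cohort = co, panel = panel, case_triage = case_triage,
                     control_triage = control_triage, groups = groups),
           envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Independent Fisher oracle: exhaustive hypergeometric enumeration over all
# tables with the observed margins, using choose() arithmetic only.
fisher_enum_p <- function(a, b, c, d) {
  n_cases <- a + b
  carriers <- a + c
  N <- a + b + c + d
  support <- max(0, carriers - (c + d)):min(carriers, n_cases)
  probs <- vapply(support, function(k) {
    choose(carriers, k) * choose(N - carriers, n_cases - k) / choose(N, n_cases)
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
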