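#' Variant prioritization cascade and pathogenicity classification
#'
#' Germline calls are filtered by six exclusion rules, each recorded as a
#' reason code; a retained variant is then classified as pathogenic / likely
#' pathogenic (jointly "PV") or VUS by a deliberately simple, auditable
#' surrogate for a full ACMG evaluation (see the package vignette for what the
#' surrogate can and cannot reproduce).
#'
#' @name variant_triage
NULL

# Known low-risk alleles excluded from carrier counting regardless of any
# other annotation.
LOW_RISK_VARIANTS <- data.frame(
  gene = c("BRCA2", "CHEK2"),
  hgvs_c = c("c.9976A>T", "c.470T>C")
)

#' Filter thresholds for the prioritization cascade
#'
#' @param min_quality Minimum variant quality score; calls with `q <
#'   min_quality` are excluded. Default 150.
#' @param max_pop_maf Maximum minor allele frequency in any population
#'   database; exceeding it (strictly) excludes unless ClinVar-rescued.
#'   Default 0.001.
#' @param max_control_freq Maximum allele frequency in the in-house
#'   777-subject reference panel; exceeding 0.005 (strictly) excludes unless
#'   ClinVar-rescued.
#' @param maf_aggregation `"max"` (default): a variant fails the population
#'   frequency rule when its maximum MAF across the provided databases exceeds
#'   the threshold; `"all"`: only when every non-missing MAF exceeds it.
#' @param splice_window Consensus splice-site window in bp (donor/acceptor
#'   dinucleotide, so 2). The upstream annotator encodes it in the consequence
#'   (`canonical_splice` vs `non_canonical_intronic`); the value is carried for
#'   provenance.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_quality = 150, max_pop_maf = 0.001,
                              max_control_freq = 0.005,
                              maf_aggregation = c("max", "all"),
                              splice_window = 2L) {
  maf_aggregation <- match.arg(maf_aggregation)
  stopifnot(min_quality > 0, max_pop_maf > 0, max_control_freq > 0,
            splice_window > 0)
  structure(list(min_quality = min_quality, max_pop_maf = max_pop_maf,
                 max_control_freq = max_control_freq,
                 maf_aggregation = maf_aggregation,
                 splice_window = as.integer(splice_window)),
            class = "filter_thresholds")
}

#' Apply the six-rule filter cascade
#'
#' Evaluates all rules for every variant and records every reason that fires
#' (not only the first), so decision traces are audit-friendly and rule order
#' is irrelevant. Rules:
#' \describe{
#'   \item{LOW_QUALITY}{quality strictly below `min_quality`.}
#'   \item{HIGH_POP_MAF}{population MAF strictly above `max_pop_maf`;
#'     rescued by a ClinVar P/LP assertion.}
#'   \item{HIGH_CONTROL_FREQ}{reference-panel allele frequency strictly above
#'     `max_control_freq`; rescued by ClinVar P/LP.}
#'   \item{NONCODING_OR_SILENT}{UTR, intronic outside consensus splice sites,
#'     synonymous, or in-frame indel; rescued by ClinVar P/LP.}
#'   \item{CLINVAR_BENIGN_2STAR}{ClinVar benign/likely benign with review
#'     status of at least two stars.}
#'   \item{LOW_RISK_EXCLUDED}{the enumerated low-risk alleles BRCA2
#'     c.9976A>T and CHEK2 c.470T>C, regardless of other fields.}
#' }
#'
#' @param variants A validated variant tibble (see [read_variant_table()]).
#' @param thresholds A [filter_thresholds()] object.
#' @return The input tibble plus `status` (`"retained"`/`"excluded"`) and
#'   `reasons` (semicolon-joined reason codes, `""` when retained).
#' @export
apply_filter_cascade <- function(variants, thresholds = filter_thresholds()) {
  variants <- validate_variants(variants)
  t <- thresholds

  rescued <- !is.na(variants$clinvar_assertion) &
    variants$clinvar_assertion %in% c("pathogenic", "likely_pathogenic")

  mafs <- as.matrix(variants[, MAF_COLUMNS])
  if (t$maf_aggregation == "max") {
    maf_stat <- suppressWarnings(apply(mafs, 1, max, na.rm = TRUE))
    maf_stat[!is.finite(maf_stat)] <- NA_real_
    maf_high <- !is.na(maf_stat) & maf_stat > t$max_pop_maf
  } else {
    maf_high <- apply(mafs, 1, function(m) {
      m <- m[!is.na(m)]
      length(m) > 0 && all(m > t$max_pop_maf)
    })
  }

  fired <- cbind(
    LOW_QUALITY = !is.na(variants$quality) & variants$quality < t$min_quality,
    HIGH_POP_MAF = maf_high & !rescued,
    HIGH_CONTROL_FREQ = !is.na(variants$control_freq) &
      variants$control_freq > t$max_control_freq & !rescued,
    NONCODING_OR_SILENT = variants$consequence %in%
      c("utr", "non_canonical_intronic", "synonymous", "inframe_indel") &
      !rescued,
    CLINVAR_BENIGN_2STAR = !is.na(variants$clinvar_assertion) &
      variants$clinvar_assertion %in% c("benign", "likely_benign") &
      !is.na(variants$clinvar_stars) & variants$clinvar_stars >= 2,
    LOW_RISK_EXCLUDED = paste(variants$gene, variants$hgvs_c) %in%
      paste(LOW_RISK_VARIANTS$gene, LOW_RISK_VARIANTS$hgvs_c)
  )

  reasons <- apply(fired, 1, function(f) paste(FILTER_REASONS[f], collapse = ";"))
  variants$status <- if_else(reasons == "", "retained", "excluded")
  variants$reasons <- reasons
  variants
}

#' Classify retained variants
#'
#' A documented surrogate for full ACMG scoring, applied only to variants that
#' pass the cascade:
#' \enumerate{
#'   \item ClinVar pathogenic / likely pathogenic with at least two submitters
#'     (and not a conflicting record) takes the ClinVar class.
#'   \item A ClinVar record from a single submitter, or with conflicting
#'     interpretations, is VUS.
#'   \item Any other ClinVar record (e.g. benign below two stars) is VUS.
#'   \item Without usable ClinVar evidence, a loss-of-function consequence
#'     (nonsense, frameshift, canonical splice, whole-gene deletion) outside
#'     the last exon is pathogenic.
#'   \item Whole-gene duplications and last-exon truncations are VUS, as is
#'     everything else (notably ClinVar-absent missense).
#' }
#'
#' @param triaged Output of [apply_filter_cascade()].
#' @return The tibble with a `pclass` column (`"pathogenic"`,
#'   `"likely_pathogenic"`, `"vus"`; `NA` for excluded variants) and a logical
#'   `is_pv` column.
#' @export
classify_variants <- function(triaged) {
  if (!all(c("status", "reasons") %in% names(triaged))) {
    abort("classify_variants() expects the output of apply_filter_cascade()")
  }
  has_clinvar <- !is.na(triaged$clinvar_assertion)
  strong_plp <- has_clinvar &
    triaged$clinvar_assertion %in% c("pathogenic", "likely_pathogenic") &
    !is.na(triaged$clinvar_submitters) & triaged$clinvar_submitters >= 2
  weak_clinvar <- has_clinvar & !strong_plp
  lof <- triaged$consequence %in%
    c("nonsense", "frameshift", "canonical_splice", "whole_gene_del")
  last_exon <- !is.na(triaged$in_last_exon) & triaged$in_last_exon

  pclass <- dplyr::case_when(
    strong_plp ~ triaged$clinvar_assertion,
    weak_clinvar ~ "vus",
    lof & !last_exon ~ "pathogenic",
    TRUE ~ "vus"
  )
  triaged$pclass <- if_else(triaged$status == "retained", pclass, NA_character_)
  triaged$is_pv <- !is.na(triaged$pclass) &
    triaged$pclass %in% c("pathogenic", "likely_pathogenic")
  triaged
}

#' Classify a single retained variant
#'
#' Single-record convenience wrapper around [classify_variants()];
#' calling it on an excluded variant is a contract violation.
#'
#' @param variant A one-row triaged variant tibble.
#' @return `"pathogenic"`, `"likely_pathogenic"` or `"vus"`.
#' @export
classify_variant <- function(variant) {
  stopifnot(nrow(variant) == 1)
  if (!identical(variant$status, "retained")) {
    abort("classify_variant() called on a variant excluded by the cascade")
  }
  classify_variants(variant)$pclass
}

#' Triage a cohort's variant table
#'
#' Runs the cascade and the classifier and aggregates carriers: for each gene,
#' the set of distinct subjects carrying at least one PV. A subject with PV in
#' two genes appears in both gene's carrier sets (deduplication happens in the
#' burden aggregation, not here).
#'
#' @param variants A validated variant tibble.
#' @param thresholds A [filter_thresholds()] object.
#' @param n_subjects Cohort size. Defaults to the number of distinct subject
#'   ids in the table; pass explicitly when some subjects carry no variants
#'   (the usual case).
#' @return A `triage_summary`: list with `triaged` (full decision trace),
#'   `class_counts`, `carriers` (tibble `gene`, `subject_id`, one row per
#'   PV-carrier pair) and `n_subjects`.
#' @export
triage_cohort <- function(variants, thresholds = filter_thresholds(),
                          n_subjects = NULL) {
  triaged <- classify_variants(apply_filter_cascade(variants, thresholds))
  n_obs <- dplyr::n_distinct(triaged$subject_id)
  if (is.null(n_subjects)) n_subjects <- n_obs
  if (n_subjects < n_obs) {
    abort("n_subjects is smaller than the number of distinct subjects observed")
  }
  carriers <- triaged %>%
    filter(.data$is_pv) %>%
    distinct(.data$gene, .data$subject_id)
  structure(list(
    triaged = triaged,
    class_counts = c(
      excluded = sum(triaged$status == "excluded"),
      retained = sum(triaged$status == "retained"),
      pv = sum(triaged$is_pv),
      vus = sum(!is.na(triaged$pclass) & triaged$pclass == "vus")
    ),
    carriers = carriers,
    n_subjects = as.integer(n_subjects)
  ), class = "triage_summary")
}

#' @export
print.triage_summary <- function(x, ...) {
  cat("<triage_summary> ", nrow(x$triaged), " variants from ", x$n_subjects,
      " subjects: ", x$class_counts[["pv"]], " PV, ", x$class_counts[["vus"]],
      " VUS, ", x$class_counts[["excluded"]], " excluded\n", sep = "")
  invisible(x)
}

#' Subjects carrying a PV in any gene of a set
#'
#' @param summary A `triage_summary`.
#' @param genes Character vector of gene symbols.
#' @return Character vector of distinct subject ids.
#' @export
carriers_of <- function(summary, genes) {
  unique(summary$carriers$subject_id[summary$carriers$gene %in% genes])
}

#' Write a triage decision trace
#'
#' @param summary A `triage_summary`.
#' @param path Output TSV path.
#' @param header_comment Optional `#` comment line.
#' @return `path`, invisibly.
#' @export
write_decision_trace <- function(summary, path, header_comment = NULL) {
  trace <- summary$triaged[, c("subject_id", "gene", "hgvs_c", "status",
                               "reasons", "pclass")]
  write_tsv_commented(trace, path, header_comment)
}
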