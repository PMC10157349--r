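#' Variant, phenotype and panel input/output
#'
#' The package works on three flat inputs: an annotated germline variant table
#' (one row per variant call per subject), a phenotype table (one row per
#' diagnosis, patient-level columns repeated), and a relatives table (one row
#' per affected relative). All readers return validated tibbles; unknown values
#' stay `NA` and are never imputed.
#'
#' @name cohort_io
NULL

VARIANT_COLUMNS <- c(
  "subject_id", "gene", "chrom", "pos", "ref", "alt", "hgvs_c", "consequence",
  "quality", "maf_gnomad", "maf_esp", "maf_1kg", "control_freq",
  "clinvar_assertion", "clinvar_stars", "clinvar_submitters", "in_last_exon"
)

MAF_COLUMNS <- c("maf_gnomad", "maf_esp", "maf_1kg")

PHENOTYPE_COLUMNS <- c(
  "patient_id", "sex", "icd10", "age_at_dx", "bilateral", "triple_negative",
  "medullar", "gleason", "msi_positive", "adenoma_count", "histology",
  "figo_grade", "figo_stage", "fh_known"
)

RELATIVE_COLUMNS <- c("patient_id", "degree", "direct_line", "icd10",
                      "age_at_dx", "sex")

#' Validate a variant table
#'
#' Checks the column set, coordinate and frequency invariants, and the
#' consequence vocabulary. Unknown consequence strings are mapped to `"other"`
#' with a warning rather than rejected, so upstream annotators with richer
#' vocabularies degrade gracefully.
#'
#' @param variants A data frame with the columns listed in
#'   [read_variant_table()].
#' @return The validated tibble (invisibly modified: consequences normalised).
#' @export
validate_variants <- function(variants) {
  variants <- as_tibble(variants)
  missing <- setdiff(VARIANT_COLUMNS, names(variants))
  if (length(missing) > 0) {
    abort(paste0("variant table is missing mandatory field(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_cons <- !is.na(variants$consequence) &
    !variants$consequence %in% CONSEQUENCE_LEVELS
  if (any(bad_cons)) {
    warn(paste0("unknown consequence value(s) mapped to 'other': ",
                paste(unique(variants$consequence[bad_cons]), collapse = ", ")))
    variants$consequence[bad_cons] <- "other"
  }
  if (any(is.na(variants$consequence))) {
    abort("variant table has records with no consequence")
  }
  if (any(!is.na(variants$pos) & variants$pos < 1)) {
    abort("variant positions must be >= 1 (1-based coordinates)")
  }
  if (any(variants$quality < 0, na.rm = TRUE)) {
    abort("variant quality must be non-negative")
  }
  freqs <- unlist(variants[, c(MAF_COLUMNS, "control_freq")], use.names = FALSE)
  if (any(freqs < 0 | freqs > 1, na.rm = TRUE)) {
    abort("all allele frequencies must lie in [0, 1]")
  }
  bad_clv <- !is.na(variants$clinvar_assertion) &
    !variants$clinvar_assertion %in% CLINVAR_ASSERTIONS
  if (any(bad_clv)) {
    abort(paste0("unknown ClinVar assertion value(s): ",
                 paste(unique(variants$clinvar_assertion[bad_clv]),
                       collapse = ", ")))
  }
  conflicted <- !is.na(variants$clinvar_assertion) &
    variants$clinvar_assertion == "conflicting"
  if (any(conflicted & variants$clinvar_submitters < 2, na.rm = TRUE)) {
    abort("a conflicting ClinVar assertion requires >= 2 submitters")
  }
  variants
}

#' Read an annotated variant table
#'
#' Two dialects are supported. `"tsv"` is the primary flat format with one row
#' per variant call per subject and a mandatory header:
#' `subject_id, gene, chrom, pos, ref, alt, hgvs_c, consequence, quality,
#' maf_gnomad, maf_esp, maf_1kg, control_freq, clinvar_assertion,
#' clinvar_stars, clinvar_submitters, in_last_exon`.
#' `"vcf"` reads the same annotations from INFO keys (`GENE`, `CSQ_CLASS`,
#' `MAF_GNOMAD`, `MAF_ESP`, `MAF_1KG`, `PMC_AF`, `CLNSIG`, `CLNSTARS`,
#' `CLNSUB`, `LASTEXON`) with per-sample presence taken from non-reference
#' `GT` fields; multiallelic records are decomposed into one row per ALT.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @return A tibble of validated variant records.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (dialect == "tsv") {
    variants <- readr::read_tsv(
      path, comment = "#", show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(
        subject_id = "c", gene = "c", chrom = "c", pos = "i", ref = "c",
        alt = "c", hgvs_c = "c", consequence = "c", quality = "d",
        maf_gnomad = "d", maf_esp = "d", maf_1kg = "d", control_freq = "d",
        clinvar_assertion = "c", clinvar_stars = "i", clinvar_submitters = "i",
        in_last_exon = "l"
      )
    )
  } else {
    variants <- read_variant_vcf(path)
  }
  validate_variants(variants)
}

# Minimal reader for the package's annotated-VCF dialect (vcfR does the
# parsing; this function only maps INFO keys onto the flat schema).
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("the 'vcfR' package is required to read the VCF dialect")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_get <- function(key) {
    vcfR::extract.info(vcf, element = key)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    carriers <- colnames(gt)[!is.na(gt[i, ]) & !gt[i, ] %in% c("0/0", "0|0", ".")]
    if (length(carriers) == 0) next
    for (alt in alts[[i]]) {
      for (subj in carriers) {
        rows[[length(rows) + 1L]] <- tibble(
          subject_id = subj,
          gene = info_get("GENE")[i],
          chrom = fix$CHROM[i],
          pos = as.integer(fix$POS[i]),
          ref = fix$REF[i],
          alt = alt,
          hgvs_c = if (is.null(fix$ID) || is.na(fix$ID[i]) || fix$ID[i] == ".")
            NA_character_ else fix$ID[i],
          consequence = info_get("CSQ_CLASS")[i],
          quality = suppressWarnings(as.numeric(fix$QUAL[i])),
          maf_gnomad = suppressWarnings(as.numeric(info_get("MAF_GNOMAD")[i])),
          maf_esp = suppressWarnings(as.numeric(info_get("MAF_ESP")[i])),
          maf_1kg = suppressWarnings(as.numeric(info_get("MAF_1KG")[i])),
          control_freq = suppressWarnings(as.numeric(info_get("PMC_AF")[i])),
          clinvar_assertion = info_get("CLNSIG")[i],
          clinvar_stars = suppressWarnings(as.integer(info_get("CLNSTARS")[i])),
          clinvar_submitters = suppressWarnings(as.integer(info_get("CLNSUB")[i])),
          in_last_exon = !is.na(info_get("LASTEXON")[i]) &
            info_get("LASTEXON")[i] %in% c("1", "TRUE", "true")
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a variant table
#'
#' @param variants A validated variant tibble.
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"vcf"`. The VCF dialect writes one
#'   record per variant with annotations as INFO keys and one sample column per
#'   subject.
#' @param header_comment Optional comment line(s) written before the header,
#'   each prefixed with `#`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path, dialect = c("tsv", "vcf"),
                                header_comment = NULL) {
  dialect <- match.arg(dialect)
  variants <- validate_variants(variants)
  if (dialect == "tsv") {
    write_tsv_commented(variants[, VARIANT_COLUMNS], path, header_comment)
  } else {
    write_variant_vcf(variants, path, header_comment)
  }
  invisible(path)
}

write_variant_vcf <- function(variants, path, header_comment = NULL) {
  subjects <- sort(unique(variants$subject_id))
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               variants$gene, sep = "\r")
  meta <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(header_comment)) paste0("##comment=", header_comment),
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=MAF_GNOMAD,Number=1,Type=Float,Description="gnomAD MAF">',
    '##INFO=<ID=MAF_ESP,Number=1,Type=Float,Description="ESP MAF">',
    '##INFO=<ID=MAF_1KG,Number=1,Type=Float,Description="1000 Genomes MAF">',
    '##INFO=<ID=PMC_AF,Number=1,Type=Float,Description="In-house reference panel allele frequency">',
    '##INFO=<ID=CLNSIG,Number=1,Type=String,Description="ClinVar assertion">',
    '##INFO=<ID=CLNSTARS,Number=1,Type=Integer,Description="ClinVar review stars">',
    '##INFO=<ID=CLNSUB,Number=1,Type=Integer,Description="ClinVar submitter count">',
    '##INFO=<ID=LASTEXON,Number=0,Type=Flag,Description="Truncating event in last exon">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", subjects), collapse = "\t")
  )
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE))
  body <- character(0)
  for (k in unique(key)) {
    rows <- variants[key == k, ]
    v <- rows[1, ]
    info <- paste0(
      "GENE=", v$gene, ";CSQ_CLASS=", v$consequence,
      ";MAF_GNOMAD=", fmt_num(v$maf_gnomad),
      ";MAF_ESP=", fmt_num(v$maf_esp),
      ";MAF_1KG=", fmt_num(v$maf_1kg),
      ";PMC_AF=", fmt_num(v$control_freq),
      if (!is.na(v$clinvar_assertion)) paste0(
        ";CLNSIG=", v$clinvar_assertion,
        ";CLNSTARS=", v$clinvar_stars,
        ";CLNSUB=", v$clinvar_submitters) else "",
      if (isTRUE(v$in_last_exon)) ";LASTEXON" else ""
    )
    gts <- ifelse(subjects %in% rows$subject_id, "0/1", "0/0")
    body <- c(body, paste(c(
      v$chrom, v$pos, if (is.na(v$hgvs_c)) "." else v$hgvs_c, v$ref, v$alt,
      fmt_num(v$quality), "PASS", info, "GT", gts), collapse = "\t"))
  }
  writeLines(c(meta, body), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' One row per diagnosis; patient-level columns (`sex`, `fh_known`) must be
#' consistent within a patient. Empty age fields are kept as `NA` ("unknown"),
#' never imputed. Non-C ICD-10 codes are kept with a warning.
#'
#' @param path Path to the phenotype TSV.
#' @return A tibble of diagnosis rows.
#' @export
read_patient_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ph <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      patient_id = "c", sex = "c", icd10 = "c", age_at_dx = "d",
      bilateral = "l", triple_negative = "l", medullar = "l", gleason = "i",
      msi_positive = "l", adenoma_count = "i", histology = "c",
      figo_grade = "c", figo_stage = "c", fh_known = "l"
    )
  )
  validate_phenotypes(ph)
}

#' @rdname read_patient_table
#' @export
validate_phenotypes <- function(ph) {
  ph <- as_tibble(ph)
  missing <- setdiff(PHENOTYPE_COLUMNS, names(ph))
  if (length(missing) > 0) {
    abort(paste0("phenotype table is missing mandatory field(s): ",
                 paste(missing, collapse = ", ")))
  }
  dup <- duplicated(ph[, c("patient_id", "icd10", "age_at_dx")])
  if (any(dup)) {
    abort(paste0("duplicate (patient_id, diagnosis) row(s) for: ",
                 paste(unique(ph$patient_id[dup]), collapse = ", ")))
  }
  non_c <- !is.na(ph$icd10) & !startsWith(ph$icd10, "C") & !startsWith(ph$icd10, "D")
  if (any(non_c)) {
    warn(paste0("non-C ICD-10 code(s) kept as-is: ",
                paste(unique(ph$icd10[non_c]), collapse = ", ")))
  }
  if (any(!is.na(ph$age_at_dx) & (ph$age_at_dx < 0 | ph$age_at_dx > 120))) {
    abort("age_at_dx out of [0, 120]")
  }
  ph
}

#' Read a relatives table
#'
#' One row per affected relative: `patient_id`, `degree` (`first`/`second`,
#' numeric 1/2 accepted), `direct_line` (parent/sibling/child or a parental
#' sister), `icd10`, `age_at_dx`, `sex`.
#'
#' @param path Path to the relatives TSV.
#' @return A tibble of relative diagnosis rows.
#' @export
read_relatives_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  rel <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      patient_id = "c", degree = "c", direct_line = "l", icd10 = "c",
      age_at_dx = "d", sex = "c"
    )
  )
  validate_relatives(rel)
}

#' @rdname read_relatives_table
#' @export
validate_relatives <- function(rel) {
  rel <- as_tibble(rel)
  missing <- setdiff(RELATIVE_COLUMNS, names(rel))
  if (length(missing) > 0) {
    abort(paste0("relatives table is missing mandatory field(s): ",
                 paste(missing, collapse = ", ")))
  }
  rel$degree <- dplyr::case_when(
    rel$degree %in% c("first", "1") ~ "first",
    rel$degree %in% c("second", "2") ~ "second",
    TRUE ~ NA_character_
  )
  if (any(is.na(rel$degree))) {
    abort("relative degree must be 'first'/'second' (or 1/2)")
  }
  rel
}

#' Write phenotype / relatives tables
#'
#' @param x The tibble to write.
#' @param path Output path.
#' @param header_comment Optional `#`-prefixed comment line.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(x, path, header_comment = NULL) {
  write_tsv_commented(validate_phenotypes(x)[, PHENOTYPE_COLUMNS], path,
                      header_comment)
}

#' @rdname write_patient_table
#' @export
write_relatives_table <- function(x, path, header_comment = NULL) {
  write_tsv_commented(validate_relatives(x)[, RELATIVE_COLUMNS], path,
                      header_comment)
}

write_tsv_commented <- function(x, path, header_comment = NULL) {
  txt <- readr::format_tsv(x)
  if (!is.null(header_comment)) {
    txt <- paste0(paste0("# ", header_comment, "\n", collapse = ""), txt)
  }
  writeLines(sub("\n$", "", txt), path)
  invisible(path)
}

#' Load a gene panel configuration
#'
#' The panel is a JSON or YAML file with keys `ls_genes`, `hboc_genes`,
#' `candidate_genes`. The bundled default reproduces the study design: 5
#' Lynch-syndrome genes, 14 hereditary breast/ovarian cancer genes and 207
#' candidate genes. The bundled candidate list is synthetic (real
#' cancer-susceptibility gene symbols standing in for the capture panel's
#' unpublished candidate set; only the named candidate genes and the 5/14/207
#' split are meaningful), hence the `_synthetic` file name.
#'
#' @param path Path to a panel config; `NULL` (default) loads the bundled
#'   panel.
#' @return A `gene_panel` object: a named character vector mapping gene to
#'   group (`"LS"`, `"HBOC"`, `"CANDIDATE"`).
#' @export
load_gene_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_panel_synthetic.json",
                        package = "ecgermline")
  }
  if (!file.exists(path)) abort(paste0("no such panel config: ", path))
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  gene_panel(cfg$ls_genes, cfg$hboc_genes, cfg$candidate_genes)
}

#' @rdname load_gene_panel
#' @param ls_genes,hboc_genes,candidate_genes Character vectors of gene
#'   symbols; the three groups must be disjoint.
#' @export
gene_panel <- function(ls_genes, hboc_genes, candidate_genes = character(0)) {
  ls_genes <- as.character(ls_genes %||% character(0))
  hboc_genes <- as.character(hboc_genes %||% character(0))
  candidate_genes <- as.character(candidate_genes %||% character(0))
  all_genes <- c(ls_genes, hboc_genes, candidate_genes)
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup) > 0) {
    abort(paste0("gene(s) listed in more than one panel group: ",
                 paste(dup, collapse = ", ")))
  }
  panel <- c(
    setNames(rep("LS", length(ls_genes)), ls_genes),
    setNames(rep("HBOC", length(hboc_genes)), hboc_genes),
    setNames(rep("CANDIDATE", length(candidate_genes)), candidate_genes)
  )
  structure(panel, class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = c("LS", "HBOC", "CANDIDATE")))
  cat("<gene_panel> ", tab[["LS"]], " LS + ", tab[["HBOC"]], " HBOC + ",
      tab[["CANDIDATE"]], " candidate genes\n", sep = "")
  invisible(x)
}

#' Genes of a panel group
#'
#' @param panel A `gene_panel`.
#' @param group One or more of `"LS"`, `"HBOC"`, `"CANDIDATE"`.
#' @return Character vector of gene symbols.
#' @export
panel_genes <- function(panel, group = c("LS", "HBOC", "CANDIDATE")) {
  group <- match.arg(group, several.ok = TRUE)
  names(panel)[unclass(panel) %in% group]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Prefix match for ICD-10 category codes: "C50" matches "C50", "C50.9".
icd_match <- function(codes, prefixes) {
  if (length(codes) == 0) return(logical(0))
  out <- rep(FALSE, length(codes))
  for (p in prefixes) {
    out <- out | (!is.na(codes) & startsWith(codes, p))
  }
  out
}
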