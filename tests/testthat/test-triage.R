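# Independent truth-table oracle for the cascade: plain boolean expressions
# over the rule conditions, written separately from the implementation.
oracle_reasons <- function(quality, maf, ctrl_freq, consequence, clinvar,
                           low_risk) {
  rescued <- clinvar == "plp"
  fired <- c(
    LOW_QUALITY = quality < 150,
    HIGH_POP_MAF = maf > 0.001 && !rescued,
    HIGH_CONTROL_FREQ = ctrl_freq > 0.005 && !rescued,
    NONCODING_OR_SILENT = consequence %in%
      c("synonymous", "utr", "non_canonical_intronic", "inframe_indel") &&
      !rescued,
    CLINVAR_BENIGN_2STAR = clinvar == "benign2star",
    LOW_RISK_EXCLUDED = low_risk
  )
  paste(names(fired)[fired], collapse = ";")
}

test_that("cascade equals the truth-table oracle over all rule combinations", {
  grid <- expand.grid(
    quality = c(500, 120),
    maf = c(0, 0.01),
    ctrl_freq = c(0, 0.02),
    consequence = c("missense", "synonymous"),
    clinvar = c("none", "benign2star", "plp"),
    low_risk = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  variants <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    make_variant(
      subject_id = paste0("G", i),
      gene = if (g$low_risk) "CHEK2" else "MSH6",
      hgvs_c = if (g$low_risk) "c.470T>C" else "c.1A>G",
      consequence = g$consequence, quality = g$quality,
      maf_gnomad = g$maf, control_freq = g$ctrl_freq,
      clinvar_assertion = switch(g$clinvar, none = NA_character_,
                                 benign2star = "benign", plp = "pathogenic"),
      clinvar_stars = switch(g$clinvar, none = NA_integer_,
                             benign2star = 3L, plp = 2L),
      clinvar_submitters = switch(g$clinvar, none = NA_integer_,
                                  benign2star = 4L, plp = 3L)
    )
  }))
  triaged <- apply_filter_cascade(variants)
  expected <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    oracle_reasons(g$quality, g$maf, g$ctrl_freq, g$consequence, g$clinvar,
                   g$low_risk)
  }, character(1))
  expect_equal(triaged$reasons, expected)
  expect_equal(triaged$status,
               ifelse(expected == "", "retained", "excluded"))
})

test_that("cascade is order-independent and accumulates all reasons", {
  v1 <- make_variant("A", quality = 100, maf_gnomad = 0.01)
  v2 <- make_variant("B", consequence = "synonymous")
  v3 <- make_variant("C")
  fwd <- apply_filter_cascade(dplyr::bind_rows(v1, v2, v3))
  rev <- apply_filter_cascade(dplyr::bind_rows(v3, v2, v1))
  expect_equal(fwd$reasons[fwd$subject_id == "A"],
               rev$reasons[rev$subject_id == "A"])
  expect_equal(fwd$reasons[1], "LOW_QUALITY;HIGH_POP_MAF")
  # singleton evaluation equals batch evaluation (pure function)
  alone <- apply_filter_cascade(v1)
  expect_equal(alone$reasons, fwd$reasons[fwd$subject_id == "A"])
})

test_that("ClinVar P/LP rescues frequency and consequence rules but not quality", {
  plp <- list(clinvar_assertion = "pathogenic", clinvar_stars = 2L,
              clinvar_submitters = 3L)
  rescued <- apply_filter_cascade(make_variant(
    maf_gnomad = 0.05, control_freq = 0.05, consequence = "synonymous",
    clinvar_assertion = plp$clinvar_assertion,
    clinvar_stars = plp$clinvar_stars,
    clinvar_submitters = plp$clinvar_submitters))
  expect_equal(rescued$status, "retained")

  low_q <- apply_filter_cascade(make_variant(
    quality = 100, clinvar_assertion = "pathogenic", clinvar_stars = 2L,
    clinvar_submitters = 3L))
  expect_equal(low_q$reasons, "LOW_QUALITY")

  low_risk <- apply_filter_cascade(make_variant(
    gene = "BRCA2", hgvs_c = "c.9976A>T", consequence = "nonsense",
    clinvar_assertion = "pathogenic", clinvar_stars = 2L,
    clinvar_submitters = 3L))
  expect_equal(low_risk$reasons, "LOW_RISK_EXCLUDED")
})

test_that("boundary values use strict comparators", {
  at_bounds <- apply_filter_cascade(make_variant(
    quality = 150, maf_gnomad = 0.001, control_freq = 0.005))
  expect_equal(at_bounds$status, "retained")
  below <- apply_filter_cascade(make_variant(quality = 149.99))
  expect_equal(below$reasons, "LOW_QUALITY")
})

test_that("classifier follows the surrogate decision rules", {
  classify_one <- function(...) {
    classify_variant(apply_filter_cascade(make_variant(...)))
  }
  expect_equal(classify_one(consequence = "nonsense"), "pathogenic")
  expect_equal(classify_one(consequence = "frameshift", in_last_exon = TRUE),
               "vus")
  expect_equal(classify_one(clinvar_assertion = "likely_pathogenic",
                            clinvar_stars = 0L, clinvar_submitters = 1L),
               "vus")
  expect_equal(classify_one(consequence = "whole_gene_dup",
                            clinvar_assertion = "pathogenic",
                            clinvar_stars = 2L, clinvar_submitters = 3L),
               "pathogenic")
  expect_equal(classify_one(consequence = "whole_gene_dup"), "vus")
  expect_equal(classify_one(consequence = "whole_gene_del"), "pathogenic")
  expect_equal(classify_one(clinvar_assertion = "conflicting",
                            clinvar_stars = 1L, clinvar_submitters = 3L),
               "vus")
  expect_equal(classify_one(), "vus")  # ClinVar-absent missense

  excluded <- apply_filter_cascade(make_variant(quality = 100))
  expect_error(classify_variant(excluded), "excluded")
})

test_that("triage fixtures reproduce their truth file exactly", {
  fx <- make_triage_fixtures()
  expect_gte(nrow(fx$variants), 12L)
  triaged <- classify_variants(apply_filter_cascade(fx$variants))
  expect_equal(triaged$status, fx$truth$expected_status)
  expect_equal(triaged$reasons, fx$truth$expected_reasons)
  expect_equal(triaged$pclass, fx$truth$expected_pclass)
  expect_true(any(fx$variants$gene == "BRCA2" &
                    fx$variants$hgvs_c == "c.9976A>T"))
})

test_that("cohort triage aggregates carriers per gene without deduplication", {
  pv <- function(subject, gene) {
    make_variant(subject, gene, consequence = "frameshift",
                 clinvar_assertion = "pathogenic", clinvar_stars = 2L,
                 clinvar_submitters = 3L)
  }
  variants <- dplyr::bind_rows(
    pv("S1", "MSH6"), pv("S2", "MSH6"),         # shared variant, 2 carriers
    pv("S3", "MLH1"), pv("S3", "BRCA1"),        # double carrier
    make_variant("S4", "ATM", quality = 100)    # excluded
  )
  summary <- triage_cohort(variants, n_subjects = 10)
  expect_setequal(carriers_of(summary, "MSH6"), c("S1", "S2"))
  expect_setequal(carriers_of(summary, "MLH1"), "S3")
  expect_setequal(carriers_of(summary, "BRCA1"), "S3")
  expect_length(carriers_of(summary, c("MLH1", "BRCA1")), 1L)
  expect_length(carriers_of(summary, "ATM"), 0L)

  none <- triage_cohort(make_variant("S9", quality = 10), n_subjects = 5)
  expect_equal(nrow(none$carriers), 0L)
})
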