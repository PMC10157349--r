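#' Seeded synthetic cohort generator
#'
#' Generates case/control cohorts (phenotype, relatives and variant tables)
#' with the statistical structure of the study the package re-implements:
#' 527 cases partitioned 151/16/82/278 across testing-indication groups by
#' construction (and re-derived by the criteria engine, never assigned
#' directly), per-gene carrier counts matching the published burden table,
#' two cross-syndrome double carriers, and 1,662 controls. Carrier variants
#' are retained-class PV records (mid-gene frameshift, ClinVar pathogenic,
#' two-star); background variants exercise every cascade-failure class.
#'
#' @name synthetic_cohort
NULL

# Per-gene case PV-carrier counts by indication group and control counts
# (EC-predisposition panel).
DEFAULT_CARRIER_COUNTS <- local({
  m <- rbind(
    MLH1   = c(3, 0, 2, 1),
    MSH2   = c(6, 0, 2, 0),
    MSH6   = c(8, 0, 1, 4),
    PMS2   = c(0, 0, 0, 0),
    EPCAM  = c(0, 0, 0, 0),
    ATM    = c(1, 0, 1, 3),
    BARD1  = c(0, 0, 1, 0),
    BRCA1  = c(2, 2, 6, 1),
    BRCA2  = c(1, 1, 0, 5),
    BRIP1  = c(0, 0, 0, 1),
    CDH1   = c(0, 0, 0, 0),
    CHEK2  = c(3, 0, 1, 2),
    NF1    = c(0, 0, 0, 0),
    PALB2  = c(1, 0, 0, 0),
    PTEN   = c(1, 0, 0, 0),
    RAD51C = c(0, 0, 2, 0),
    RAD51D = c(0, 0, 0, 0),
    STK11  = c(0, 0, 0, 0),
    TP53   = c(0, 0, 0, 0)
  )
  colnames(m) <- INDICATION_GROUPS
  m
})

DEFAULT_CONTROL_CARRIER_COUNTS <- c(
  MLH1 = 1, MSH2 = 0, MSH6 = 0, PMS2 = 3, EPCAM = 0,
  ATM = 7, BARD1 = 0, BRCA1 = 9, BRCA2 = 3, BRIP1 = 3, CDH1 = 0, CHEK2 = 6,
  NF1 = 1, PALB2 = 8, PTEN = 1, RAD51C = 2, RAD51D = 0, STK11 = 0, TP53 = 2
)

# Candidate-gene carriers: named counts are placed first, the remainder is
# spread one carrier per distinct further candidate gene.
DEFAULT_CANDIDATE_CASE <- list(
  by_group = c(LS_ONLY = 14, HBOC_ONLY = 2, BOTH = 14, NONE = 28),
  named_genes = c(MUTYH = 5, FANCA = 4, POLE = 2, POLD1 = 1),
  # candidate PV co-occurring in EC-predisposition-gene PV carriers
  overlap_in_pred_carriers = 8
)
DEFAULT_CANDIDATE_CONTROL <- list(
  total = 139,
  named_genes = c(MUTYH = 18, FANCA = 10, POLE = 1, POLD1 = 0)
)

#' Simulation parameters
#'
#' The defaults are the study conditions: cohort sizes, the indication-group
#' partition, per-gene carrier counts by group, the two double carriers, and
#' age/covariate distributions matching the published clinicopathological
#' margins. `carrier_sampling = "exact"` places exactly the configured number
#' of carriers (which patients carry is random under the seed);
#' `"binomial"` draws carrier counts binomially from the implied
#' per-group frequencies and is what the parameter-recovery harness uses.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param group_sizes Named sizes of the four indication groups (must sum to
#'   `n_cases`).
#' @param carrier_counts Gene-by-group matrix of case carrier counts.
#' @param control_carrier_counts Named per-gene control carrier counts.
#' @param candidate_case,candidate_control Candidate-gene carrier settings
#'   (see defaults).
#' @param double_carriers List of `c(geneA, geneB, group)` triples merged into
#'   single two-PV carriers.
#' @param carrier_sampling `"exact"` or `"binomial"`.
#' @param background_rate Mean number of non-PV background variants per
#'   subject (Poisson).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_cases = 527, n_controls = 1662,
                              group_sizes = c(LS_ONLY = 151, HBOC_ONLY = 16,
                                              BOTH = 82, NONE = 278),
                              carrier_counts = DEFAULT_CARRIER_COUNTS,
                              control_carrier_counts = DEFAULT_CONTROL_CARRIER_COUNTS,
                              candidate_case = DEFAULT_CANDIDATE_CASE,
                              candidate_control = DEFAULT_CANDIDATE_CONTROL,
                              double_carriers = list(
                                c("MLH1", "BRCA1", "BOTH"),
                                c("MSH2", "ATM", "LS_ONLY")),
                              carrier_sampling = c("exact", "binomial"),
                              background_rate = 1.5,
                              seed = 1L) {
  carrier_sampling <- match.arg(carrier_sampling)
  stopifnot(n_cases >= 0, n_controls >= 0, background_rate >= 0)
  if (sum(group_sizes) != n_cases) {
    abort("group_sizes must sum to n_cases")
  }
  if (any(carrier_counts < 0) || any(control_carrier_counts < 0)) {
    abort("carrier counts must be non-negative")
  }
  if (any(carrier_counts / rep(pmax(group_sizes, 1), each = nrow(carrier_counts)) > 1)) {
    abort("implied carrier probabilities must lie in [0, 1]")
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    group_sizes = group_sizes, carrier_counts = carrier_counts,
    control_carrier_counts = control_carrier_counts,
    candidate_case = candidate_case, candidate_control = candidate_control,
    double_carriers = double_carriers, carrier_sampling = carrier_sampling,
    background_rate = background_rate, seed = as.integer(seed)
  ), class = "simulation_params")
}

# Truncated-normal sampler (inverse CDF), used for ages: only means, medians
# and ranges are published, so a truncated normal is the simplest generative
# model consistent with them.
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

r_age <- function(n, mean, sd, lo, hi) floor(rtnorm(n, mean, sd, lo, hi))

HISTOLOGY_DIST <- c(
  endometrioid = 284, serous = 35, clear_cell = 7, undifferentiated = 3,
  mixed = 8, EIN = 8, carcinoma_unspecified = 4, leiomyosarcoma = 32,
  ess = 3, sarcoma_undifferentiated = 2, sarcoma_unspecified = 3,
  unknown = 138
)
FIGO_GRADE_DIST <- c("1" = 123, "2" = 100, "3" = 120, unknown = 184)
FIGO_STAGE_DIST <- c("0" = 8, "I" = 176, "II" = 38, "III" = 48, "IV" = 19,
                     unknown = 238)

sample_cat <- function(n, dist) {
  v <- sample(names(dist), n, replace = TRUE, prob = dist / sum(dist))
  v[v == "unknown"] <- NA_character_
  v
}

dx_row <- function(patient_id, icd10, age, sex = "female", bilateral = FALSE,
                   triple_negative = FALSE, histology = NA_character_,
                   figo_grade = NA_character_, figo_stage = NA_character_,
                   fh_known = TRUE) {
  tibble(patient_id = patient_id, sex = sex, icd10 = icd10,
         age_at_dx = age, bilateral = bilateral,
         triple_negative = triple_negative, medullar = FALSE,
         gleason = NA_integer_, msi_positive = NA,
         adenoma_count = NA_integer_, histology = histology,
         figo_grade = figo_grade, figo_stage = figo_stage,
         fh_known = fh_known)
}

rel_row <- function(patient_id, degree, icd10, age, direct_line = TRUE,
                    sex = "female") {
  tibble(patient_id = patient_id, degree = degree, direct_line = direct_line,
         icd10 = icd10, age_at_dx = age, sex = sex)
}

# Phenotype archetypes per indication group. Classification is produced by
# the criteria engine downstream; these constructions are designed so each
# patient lands in the intended group (verified by test, not assigned).
make_case_phenotypes <- function(params) {
  gs <- params$group_sizes
  scale <- params$n_cases / 527   # archetype mix scales with cohort size
  ids_of <- function(n, offset) sprintf("EC%04d", offset + seq_len(n))
  dx <- list(); rel <- list(); group <- character(0); ids_all <- character(0)
  offset <- 0

  add <- function(id, d, r = NULL) {
    dx[[length(dx) + 1L]] <<- d
    if (!is.null(r)) rel[[length(rel) + 1L]] <<- r
  }

  ## LS_ONLY: mechanisms LS-1 (young EC), LS-3 (concurrent CRC),
  ## LS-4 (first-degree relative with early CRC), LS-5 (two second-degree).
  n <- gs[["LS_ONLY"]]
  ids <- ids_of(n, offset); offset <- offset + n
  n_young <- round(79 / 151 * n)
  n_ls3 <- min(round(31 / 151 * n), n - n_young)
  n_ls5 <- min(max(round(3 / 151 * n), if (n > n_young + n_ls3) 1 else 0),
               n - n_young - n_ls3)
  n_ls4 <- n - n_young - n_ls3 - n_ls5
  young <- ids[seq_len(n_young)]
  ls3 <- ids[n_young + seq_len(n_ls3)]
  ls4 <- ids[n_young + n_ls3 + seq_len(n_ls4)]
  ls5 <- ids[n_young + n_ls3 + n_ls4 + seq_len(n_ls5)]
  for (id in young) add(id, dx_row(id, "C54", r_age(1, 44, 7, 24, 49.9)))
  for (id in ls3) {
    a <- r_age(1, 58, 7, 50, 91)
    add(id, bind_rows(dx_row(id, "C54", a),
                      dx_row(id, "C18", max(30, a - sample(0:6, 1)))))
  }
  for (id in ls4) {
    a <- r_age(1, 58, 7, 50, 91)
    add(id, dx_row(id, "C54", a),
        rel_row(id, "first", "C18", r_age(1, 42, 5, 25, 49.9)))
  }
  for (id in ls5) {
    add(id, dx_row(id, "C54", NA_real_),
        bind_rows(rel_row(id, "second", "C18", r_age(1, 55, 10, 30, 80),
                          direct_line = FALSE),
                  rel_row(id, "second", "C54", r_age(1, 58, 10, 30, 80),
                          direct_line = FALSE)))
  }
  # second primaries that do not alter classification: late BC, other sites
  n_bc <- min(round(14 * scale), length(young))
  for (id in head(young, n_bc)) {
    dx[[length(dx) + 1L]] <- dx_row(id, "C50", r_age(1, 55, 5, 46, 70))
  }
  n_oth <- min(round(22 * scale), length(ls4))
  for (id in head(ls4, n_oth)) {
    dx[[length(dx) + 1L]] <- dx_row(id, "C34", r_age(1, 60, 6, 45, 85))
  }
  # uninformative positive family history for a subset of the young
  for (id in utils::tail(young, max(0, n_young - n_bc - 5))) {
    if (runif(1) < 0.5) {
      rel[[length(rel) + 1L]] <- rel_row(id, "first", "C18",
                                         r_age(1, 62, 8, 50, 85))
    }
  }
  group <- c(group, rep("LS_ONLY", n)); ids_all <- c(ids_all, ids)

  ## HBOC_ONLY: late EC plus breast cancer qualifying personally (P1) or via
  ## one early-onset BC relative (F2).
  n <- gs[["HBOC_ONLY"]]
  ids <- ids_of(n, offset); offset <- offset + n
  n_p1 <- round(12 / 16 * n)
  for (i in seq_len(n)) {
    id <- ids[i]
    ec_age <- r_age(1, 59, 6, 51, 73)
    if (i == 1 && n >= 16) ec_age <- NA_real_  # one unknown EC age
    if (i <= n_p1) {
      add(id, bind_rows(dx_row(id, "C54", ec_age),
                        dx_row(id, "C50", r_age(1, 40, 4, 28, 44.9))))
    } else {
      add(id, bind_rows(dx_row(id, "C54", ec_age),
                        dx_row(id, "C50", r_age(1, 52, 4, 45, 59))),
          rel_row(id, "first", "C50", r_age(1, 45, 3, 35, 49.9)))
    }
  }
  group <- c(group, rep("HBOC_ONLY", n)); ids_all <- c(ids_all, ids)

  ## BOTH: EC with ovarian cancer (LS-3 and HBOC-P5 jointly), or early EC
  ## with triple-negative BC (LS-1 and HBOC-P3), or triple primaries.
  n <- gs[["BOTH"]]
  ids <- ids_of(n, offset); offset <- offset + n
  n_oc <- round(58 / 82 * n)
  n_bc <- min(round(13 / 82 * n), n - n_oc)
  n_tri <- n - n_oc - n_bc
  for (i in seq_len(n)) {
    id <- ids[i]
    if (i <= n_oc) {
      a <- r_age(1, 51, 10, 29, 82)
      if (i <= 2 && n >= 82) a <- NA_real_
      add(id, bind_rows(dx_row(id, "C54", a),
                        dx_row(id, "C56", if (is.na(a)) NA_real_
                               else max(28, a - sample(0:5, 1)))))
      if (i > n_oc - round(20 * scale)) {
        rel[[length(rel) + 1L]] <- rel_row(id, "first", "C50",
                                           r_age(1, 65, 5, 60, 85))
      }
    } else if (i <= n_oc + n_bc) {
      a <- r_age(1, 43, 5, 29, 49.9)
      add(id, bind_rows(dx_row(id, "C54", a),
                        dx_row(id, "C50", r_age(1, 45, 6, 30, 58),
                               triple_negative = TRUE)))
    } else {
      a <- r_age(1, 50, 9, 29, 80)
      third <- if ((i - n_oc - n_bc) <= ceiling(n_tri / 2)) "C50" else "C18"
      add(id, bind_rows(dx_row(id, "C54", a),
                        dx_row(id, "C56", max(28, a - sample(0:5, 1))),
                        dx_row(id, third, max(28, a - sample(0:8, 1)))))
    }
  }
  group <- c(group, rep("BOTH", n)); ids_all <- c(ids_all, ids)

  ## NONE: late-onset EC; any second primaries or family history kept below
  ## every criterion's qualifying condition.
  n <- gs[["NONE"]]
  ids <- ids_of(n, offset); offset <- offset + n
  n_bc <- round(38 / 278 * n)
  n_oth <- min(round(9 / 278 * n), n - n_bc)
  n_fh_unknown <- min(round(8 / 278 * n), max(0, n - n_bc - n_oth))
  fh_unknown_ids <- ids[n_bc + n_oth + seq_len(n_fh_unknown)]
  # no relatives for fh-unknown patients, no C50 relatives near BC cases
  fh_rel_pool <- setdiff(ids, c(ids[seq_len(n_bc)], fh_unknown_ids))
  n_relcrc <- round(30 / 278 * n); n_relec <- round(14 / 278 * n)
  n_relbc <- round(34 / 278 * n); n_reloth <- round(84 / 278 * n)
  for (i in seq_len(n)) {
    id <- ids[i]
    fh_known <- !(i > n_bc + n_oth && i <= n_bc + n_oth + n_fh_unknown)
    a <- r_age(1, 66, 9, 50, 92)
    if (i > n - 4) a <- NA_real_  # a few unknown ages
    d <- dx_row(id, "C54", a, fh_known = fh_known)
    if (i <= n_bc) {
      d <- bind_rows(d, dx_row(id, "C50", r_age(1, 64, 5, 60, 85),
                               fh_known = fh_known))
    } else if (i <= n_bc + n_oth) {
      d <- bind_rows(d, dx_row(id, "C34", r_age(1, 62, 6, 50, 85),
                               fh_known = fh_known))
    }
    add(id, d)
  }
  # family-history strata among fh-known NONE patients, never qualifying:
  # relatives all aged >= 50 so no age-bounded rule can fire
  pool <- fh_rel_pool[seq_len(min(length(fh_rel_pool),
                                  n_relcrc + n_relec + n_relbc + n_reloth))]
  k <- 0
  for (id in head(pool, n_relcrc)) {
    rel[[length(rel) + 1L]] <- rel_row(id, "first", "C18",
                                       r_age(1, 64, 7, 52, 85))
  }
  k <- n_relcrc
  for (id in pool[k + seq_len(min(n_relec, max(0, length(pool) - k)))]) {
    rel[[length(rel) + 1L]] <- rel_row(id, "first", "C54",
                                       r_age(1, 63, 6, 55, 85))
  }
  k <- k + n_relec
  for (id in pool[k + seq_len(min(n_relbc, max(0, length(pool) - k)))]) {
    rel[[length(rel) + 1L]] <- rel_row(id, "first", "C50",
                                       r_age(1, 68, 5, 62, 88))
  }
  k <- k + n_relbc
  for (id in pool[k + seq_len(min(n_reloth, max(0, length(pool) - k)))]) {
    rel[[length(rel) + 1L]] <- rel_row(id, "first", "C34",
                                       r_age(1, 63, 8, 50, 85))
  }
  group <- c(group, rep("NONE", n)); ids_all <- c(ids_all, ids)

  phenotypes <- bind_rows(dx)
  # histology / FIGO attached to the endometrial diagnosis rows only
  is_ec <- icd_match(phenotypes$icd10, EC_CODES)
  phenotypes$histology[is_ec] <- sample_cat(sum(is_ec), HISTOLOGY_DIST)
  phenotypes$figo_grade[is_ec] <- sample_cat(sum(is_ec), FIGO_GRADE_DIST)
  phenotypes$figo_stage[is_ec] <- sample_cat(sum(is_ec), FIGO_STAGE_DIST)
  relatives <- if (length(rel) > 0) bind_rows(rel) else
    tibble(patient_id = character(0), degree = character(0),
           direct_line = logical(0), icd10 = character(0),
           age_at_dx = numeric(0), sex = character(0))
  list(phenotypes = phenotypes, relatives = relatives,
       intended = tibble(patient_id = ids_all, intended_group = group))
}

# Stable fake coordinates per gene so variant records are well-formed.
gene_locus <- function(gene) {
  h <- sum(utf8ToInt(gene) * seq_along(utf8ToInt(gene)))
  list(chrom = paste0("chr", 1 + (h %% 22)), base = 1000000 + (h %% 9000) * 100)
}

pv_variant <- function(subject_id, gene, k = 1) {
  loc <- gene_locus(gene)
  pos <- loc$base + k * 3
  tibble(
    subject_id = subject_id, gene = gene, chrom = loc$chrom, pos = pos,
    ref = "A", alt = "AT", hgvs_c = paste0("c.", 100 + k * 3, "dup"),
    consequence = "frameshift", quality = round(runif(1, 160, 990)),
    maf_gnomad = 0, maf_esp = NA_real_, maf_1kg = NA_real_,
    control_freq = 0, clinvar_assertion = "pathogenic", clinvar_stars = 2L,
    clinvar_submitters = 3L, in_last_exon = FALSE
  )
}

noise_variant <- function(subject_id, gene) {
  loc <- gene_locus(gene)
  pos <- loc$base + sample(10:5000, 1)
  base <- tibble(
    subject_id = subject_id, gene = gene, chrom = loc$chrom, pos = pos,
    ref = "G", alt = "A", hgvs_c = paste0("c.", pos %% 4000 + 1, "G>A"),
    consequence = "missense", quality = round(runif(1, 200, 900)),
    maf_gnomad = 0, maf_esp = NA_real_, maf_1kg = NA_real_,
    control_freq = 0, clinvar_assertion = NA_character_,
    clinvar_stars = NA_integer_, clinvar_submitters = NA_integer_,
    in_last_exon = FALSE
  )
  kind <- sample(c("low_quality", "high_maf", "high_control", "silent",
                   "benign", "low_risk", "vus_clean", "vus_single",
                   "vus_conflicting"), 1,
                 prob = c(.15, .2, .1, .2, .1, .05, .12, .04, .04))
  switch(kind,
    low_quality = { base$quality <- round(runif(1, 10, 149)) },
    high_maf = { base$maf_gnomad <- round(runif(1, 0.002, 0.2), 4) },
    high_control = { base$control_freq <- round(runif(1, 0.006, 0.05), 4) },
    silent = { base$consequence <- sample(c("synonymous", "utr",
                                            "non_canonical_intronic"), 1) },
    benign = { base$clinvar_assertion <- "benign"; base$clinvar_stars <- 3L
               base$clinvar_submitters <- 5L },
    low_risk = {
      i <- sample(1:2, 1)
      base$gene <- LOW_RISK_VARIANTS$gene[i]
      base$hgvs_c <- LOW_RISK_VARIANTS$hgvs_c[i]
      base$consequence <- if (i == 1) "nonsense" else "missense"
      base$in_last_exon <- i == 1
    },
    vus_clean = { },
    vus_single = { base$clinvar_assertion <- "likely_pathogenic"
                   base$clinvar_stars <- 0L; base$clinvar_submitters <- 1L },
    vus_conflicting = { base$clinvar_assertion <- "conflicting"
                        base$clinvar_stars <- 1L
                        base$clinvar_submitters <- 3L }
  )
  base
}

draw_count <- function(count, pool_size, group_size, sampling) {
  if (sampling == "exact" || group_size == 0) return(min(count, pool_size))
  min(rbinom(1, group_size, count / group_size), pool_size)
}

#' Simulate a case-control cohort
#'
#' Deterministic given `params$seed`: produces case phenotype and relatives
#' tables, a case variant table and a control variant table. Carriers receive
#' a retained-class PV (mid-gene frameshift, ClinVar pathogenic two-star) in
#' the configured gene; every subject additionally receives Poisson background
#' variants drawn from the cascade-failure classes (plus ClinVar-weak missense
#' records that are retained as VUS).
#'
#' @param params A [simulation_params()] object.
#' @return An `ec_cohort` list: `phenotypes`, `relatives`, `case_variants`,
#'   `control_variants`, `intended_groups`, `params`.
#' @export
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  panel <- load_gene_panel()
  ph <- make_case_phenotypes(params)
  intended <- ph$intended

  sampling <- params$carrier_sampling
  variants <- list()

  # --- EC-predisposition carriers in cases, by gene x indication group
  assigned <- setNames(vector("list", length(INDICATION_GROUPS)),
                       INDICATION_GROUPS)
  carrier_of_gene <- list()
  for (g in INDICATION_GROUPS) {
    pool <- intended$patient_id[intended$intended_group == g]
    for (gene in rownames(params$carrier_counts)) {
      cnt <- draw_count(params$carrier_counts[gene, g], length(pool),
                        params$group_sizes[[g]], sampling)
      if (cnt == 0) next
      picked <- sample(pool, cnt)
      pool <- setdiff(pool, picked)
      carrier_of_gene[[gene]] <- c(carrier_of_gene[[gene]],
                                   setNames(picked, rep(g, cnt)))
    }
    assigned[[g]] <- pool   # remaining non-carriers of this group
  }
  # merge configured double carriers: the geneB variant moves onto a geneA
  # carrier of the same group, freeing the geneB patient
  if (sampling == "exact") {
    for (dc in params$double_carriers) {
      ga <- dc[1]; gb <- dc[2]; g <- dc[3]
      a_ids <- carrier_of_gene[[ga]][names(carrier_of_gene[[ga]]) == g]
      b_ids <- carrier_of_gene[[gb]][names(carrier_of_gene[[gb]]) == g]
      if (length(a_ids) == 0 || length(b_ids) == 0) next
      host <- a_ids[[1]]; freed <- b_ids[[1]]
      idx <- which(carrier_of_gene[[gb]] == freed)[1]
      carrier_of_gene[[gb]][idx] <- host
      names(carrier_of_gene[[gb]])[idx] <- g
      assigned[[g]] <- c(assigned[[g]], freed)
    }
  }
  k <- 0
  for (gene in names(carrier_of_gene)) {
    for (id in carrier_of_gene[[gene]]) {
      k <- k + 1
      variants[[length(variants) + 1L]] <- pv_variant(id, gene, k)
    }
  }
  pred_carriers <- unique(unlist(carrier_of_gene, use.names = FALSE))

  # --- candidate-gene carriers in cases
  cand_genes <- panel_genes(panel, "CANDIDATE")
  cc <- params$candidate_case
  cand_hosts <- character(0)
  for (g in INDICATION_GROUPS) {
    pool <- assigned[[g]]
    cnt <- draw_count(cc$by_group[[g]], length(pool),
                      params$group_sizes[[g]], sampling)
    if (cnt == 0) next
    picked <- sample(pool, cnt)
    assigned[[g]] <- setdiff(pool, picked)
    cand_hosts <- c(cand_hosts, picked)
  }
  named <- cc$named_genes[cc$named_genes > 0]
  gene_seq <- c(rep(names(named), named),
                head(setdiff(cand_genes, names(cc$named_genes)),
                     max(0, length(cand_hosts) - sum(named))))
  gene_seq <- head(gene_seq, length(cand_hosts))
  for (i in seq_along(cand_hosts)) {
    k <- k + 1
    variants[[length(variants) + 1L]] <- pv_variant(cand_hosts[i], gene_seq[i], k)
  }
  n_overlap <- min(cc$overlap_in_pred_carriers, length(pred_carriers))
  overlap_genes <- head(setdiff(cand_genes,
                                c(names(cc$named_genes), gene_seq)), n_overlap)
  if (n_overlap > 0) {
    hosts <- sample(pred_carriers, n_overlap)
    for (i in seq_len(n_overlap)) {
      k <- k + 1
      variants[[length(variants) + 1L]] <- pv_variant(hosts[i],
                                                      overlap_genes[i], k)
    }
  }

  # --- background noise in cases
  all_genes <- names(panel)
  for (id in intended$patient_id) {
    for (j in seq_len(rpois(1, params$background_rate))) {
      variants[[length(variants) + 1L]] <-
        noise_variant(id, sample(all_genes, 1))
    }
  }
  case_variants <- bind_rows(variants)

  # --- controls: EC-predisposition carriers, candidate carriers, noise
  control_ids <- sprintf("PMC%04d", seq_len(params$n_controls))
  cvars <- list()
  pool <- control_ids
  for (gene in names(params$control_carrier_counts)) {
    cnt <- draw_count(params$control_carrier_counts[[gene]], length(pool),
                      params$n_controls, sampling)
    if (cnt == 0) next
    picked <- sample(pool, cnt)
    pool <- setdiff(pool, picked)
    for (id in picked) {
      k <- k + 1
      cvars[[length(cvars) + 1L]] <- pv_variant(id, gene, k)
    }
  }
  ctl <- params$candidate_control
  named_c <- ctl$named_genes[ctl$named_genes > 0]
  n_cand_ctl <- draw_count(ctl$total, length(pool), params$n_controls, sampling)
  hosts <- sample(pool, n_cand_ctl)
  gene_seq <- c(rep(names(named_c), named_c),
                head(setdiff(cand_genes, names(ctl$named_genes)),
                     max(0, n_cand_ctl - sum(named_c))))
  gene_seq <- head(gene_seq, n_cand_ctl)
  for (i in seq_along(hosts)) {
    k <- k + 1
    cvars[[length(cvars) + 1L]] <- pv_variant(hosts[i], gene_seq[i], k)
  }
  for (id in control_ids) {
    for (j in seq_len(rpois(1, params$background_rate))) {
      cvars[[length(cvars) + 1L]] <- noise_variant(id, sample(all_genes, 1))
    }
  }
  control_variants <- bind_rows(cvars)

  structure(list(
    phenotypes = ph$phenotypes, relatives = ph$relatives,
    case_variants = case_variants, control_variants = control_variants,
    intended_groups = intended, params = params
  ), class = "ec_cohort")
}

#' @export
print.ec_cohort <- function(x, ...) {
  cat("<ec_cohort> ", x$params$n_cases, " cases / ", x$params$n_controls,
      " controls; ", nrow(x$case_variants), " case and ",
      nrow(x$control_variants), " control variant records\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes the phenotype, relatives and variant TSVs plus a parameter-echo
#' JSON for reproducibility.
#'
#' @param cohort An `ec_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_patient_table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_relatives_table(cohort$relatives, file.path(dir, "relatives.tsv"))
  write_variant_table(cohort$case_variants, file.path(dir, "case_variants.tsv"))
  write_variant_table(cohort$control_variants,
                      file.path(dir, "control_variants.tsv"))
  echo <- unclass(cohort$params)
  echo$carrier_counts <- as.data.frame(echo$carrier_counts)
  jsonlite::write_json(echo, file.path(dir, "params.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Branch-coverage fixtures for the triage cascade
#'
#' A deterministic variant table with one record per cascade and
#' classification branch, paired with the expected outcome of each record
#' (status, reason codes, pathogenicity class).
#'
#' @return List with `variants` and `truth` tibbles (row-aligned).
#' @export
make_triage_fixtures <- function() {
  base <- function(gene = "MSH6", consequence = "missense", quality = 500,
                   maf = 0, control_freq = 0, clv = NA_character_,
                   stars = NA_integer_, subs = NA_integer_,
                   last_exon = FALSE, hgvs = "c.1A>G") {
    tibble(subject_id = "FIX", gene = gene, chrom = "chr2", pos = 1000L,
           ref = "A", alt = "G", hgvs_c = hgvs, consequence = consequence,
           quality = quality, maf_gnomad = maf, maf_esp = NA_real_,
           maf_1kg = NA_real_, control_freq = control_freq,
           clinvar_assertion = clv, clinvar_stars = stars,
           clinvar_submitters = subs, in_last_exon = last_exon)
  }
  rows <- list(
    list(base(quality = 120),
         "excluded", "LOW_QUALITY", NA),
    list(base(maf = 0.01),
         "excluded", "HIGH_POP_MAF", NA),
    list(base(maf = 0.01, clv = "pathogenic", stars = 2L, subs = 3L),
         "retained", "", "pathogenic"),
    list(base(control_freq = 0.02),
         "excluded", "HIGH_CONTROL_FREQ", NA),
    list(base(control_freq = 0.02, clv = "likely_pathogenic", stars = 2L,
              subs = 2L),
         "retained", "", "likely_pathogenic"),
    list(base(consequence = "synonymous"),
         "excluded", "NONCODING_OR_SILENT", NA),
    list(base(consequence = "synonymous", clv = "pathogenic", stars = 2L,
              subs = 2L),
         "retained", "", "pathogenic"),
    list(base(consequence = "inframe_indel"),
         "excluded", "NONCODING_OR_SILENT", NA),
    list(base(clv = "benign", stars = 2L, subs = 4L),
         "excluded", "CLINVAR_BENIGN_2STAR", NA),
    list(base(clv = "benign", stars = 1L, subs = 1L),
         "retained", "", "vus"),
    list(base(gene = "BRCA2", hgvs = "c.9976A>T", consequence = "nonsense",
              last_exon = TRUE),
         "excluded", "LOW_RISK_EXCLUDED", NA),
    list(base(gene = "CHEK2", hgvs = "c.470T>C"),
         "excluded", "LOW_RISK_EXCLUDED", NA),
    list(base(quality = 100, maf = 0.01),
         "excluded", "LOW_QUALITY;HIGH_POP_MAF", NA),
    list(base(consequence = "nonsense"),
         "retained", "", "pathogenic"),
    list(base(consequence = "frameshift", last_exon = TRUE),
         "retained", "", "vus"),
    list(base(consequence = "canonical_splice"),
         "retained", "", "pathogenic"),
    list(base(consequence = "whole_gene_del"),
         "retained", "", "pathogenic"),
    list(base(consequence = "whole_gene_dup"),
         "retained", "", "vus"),
    list(base(consequence = "whole_gene_dup", clv = "pathogenic", stars = 2L,
              subs = 3L),
         "retained", "", "pathogenic"),
    list(base(clv = "likely_pathogenic", stars = 0L, subs = 1L),
         "retained", "", "vus"),
    list(base(clv = "conflicting", stars = 1L, subs = 3L),
         "retained", "", "vus"),
    list(base(),
         "retained", "", "vus")
  )
  variants <- bind_rows(lapply(rows, `[[`, 1))
  variants$subject_id <- sprintf("FIX%02d", seq_along(rows))
  truth <- tibble(
    subject_id = variants$subject_id,
    expected_status = vapply(rows, `[[`, "", 2),
    expected_reasons = vapply(rows, `[[`, "", 3),
    expected_pclass = vapply(rows, function(r) {
      if (is.na(r[[4]])) NA_character_ else r[[4]]
    }, NA_character_)
  )
  list(variants = variants, truth = truth)
}

#' Monte-Carlo coverage and bias of the Woolf interval
#'
#' Repeatedly draws binomial carrier counts at the configured cohort sizes and
#' per-group carrier frequencies, runs the burden estimator, and reports mean
#' log-OR bias and empirical coverage of the generating odds ratio.
#'
#' @param params A [simulation_params()] object supplying cohort sizes and the
#'   generating per-group carrier frequencies (aggregate LS and HBOC by
#'   default).
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return Tibble with one row per gene group: generating OR, number of
#'   replicates with a defined estimate, mean log-OR bias and CI coverage
#'   among defined replicates.
#' @export
recovery_experiment <- function(params = simulation_params(), n_reps = 200,
                                seed = 1, conf = 0.95) {
  stopifnot(n_reps >= 1)
  groups <- list(
    LS = rownames(DEFAULT_CARRIER_COUNTS)[1:5],
    HBOC = rownames(DEFAULT_CARRIER_COUNTS)[6:19]
  )
  rows <- lapply(names(groups), function(gname) {
    genes <- intersect(groups[[gname]], rownames(params$carrier_counts))
    p_case <- sum(params$carrier_counts[genes, ]) / params$n_cases
    p_ctl <- sum(params$control_carrier_counts[
      intersect(genes, names(params$control_carrier_counts))]) /
      params$n_controls
    sim <- ci_coverage_sim(p_case, p_ctl, params$n_cases, params$n_controls,
                           n_reps, seed, conf)
    tibble(group = gname, generating_or = sim$generating_or,
           n_reps = n_reps, n_defined = sim$n_defined,
           mean_log_or_bias = sim$mean_log_or_bias, coverage = sim$coverage)
  })
  bind_rows(rows)
}

#' @rdname recovery_experiment
#' @param p_case,p_control Generating carrier probabilities.
#' @param n_cases,n_controls Cohort sizes.
#' @export
ci_coverage_sim <- function(p_case, p_control, n_cases, n_controls,
                            n_reps = 200, seed = 1, conf = 0.95) {
  stopifnot(p_case >= 0, p_case <= 1, p_control >= 0, p_control <= 1)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  gen_or <- (p_case / (1 - p_case)) / (p_control / (1 - p_control))
  log_bias <- numeric(0); covered <- logical(0)
  for (r in seq_len(n_reps)) {
    a <- rbinom(1, n_cases, p_case)
    c_ <- rbinom(1, n_controls, p_control)
    est <- odds_ratio_ci(carrier_table(a, n_cases, c_, n_controls), conf)
    if (is.na(est$or)) next
    log_bias <- c(log_bias, log(est$or) - log(gen_or))
    covered <- c(covered, est$ci_low <= gen_or && gen_or <= est$ci_high)
  }
  list(generating_or = gen_or, n_defined = length(covered),
       mean_log_or_bias = if (length(log_bias) > 0) mean(log_bias) else NA_real_,
       coverage = if (length(covered) > 0) mean(covered) else NA_real_)
}
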