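test_that("HBOC personal-history rules fire on their defining presentations", {
  # ovarian/fallopian/peritoneal cancer qualifies at any age
  p <- make_patient(dx = list(list(icd10 = "C54", age_at_dx = 63),
                              list(icd10 = "C56", age_at_dx = 52)))
  res <- evaluate_hboc_criteria(p)
  expect_true(res$met)
  expect_true("HBOC-P5" %in% res$fired_rules)

  # single breast cancer at 47 with known negative family history: not met
  p <- make_patient(dx = list(list(icd10 = "C54", age_at_dx = 60),
                              list(icd10 = "C50", age_at_dx = 47)))
  expect_false(evaluate_hboc_criteria(p)$met)
  # ... but the same age qualifies when family history is unknown
  p_unk <- make_patient(dx = list(list(icd10 = "C54", age_at_dx = 60),
                                  list(icd10 = "C50", age_at_dx = 47)),
                        fh_known = FALSE)
  expect_true("HBOC-P1" %in% evaluate_hboc_criteria(p_unk)$fired_rules)

  # male breast cancer
  p <- make_patient(sex = "male", dx = list(list(icd10 = "C50", age_at_dx = 66)))
  expect_true("HBOC-P4" %in% evaluate_hboc_criteria(p)$fired_rules)

  # triple-negative at 60 (inclusive bound)
  p <- make_patient(dx = list(list(icd10 = "C50", age_at_dx = 60,
                                   triple_negative = TRUE)))
  expect_true("HBOC-P3" %in% evaluate_hboc_criteria(p)$fired_rules)
  p61 <- make_patient(dx = list(list(icd10 = "C50", age_at_dx = 61,
                                     triple_negative = TRUE)))
  expect_false(evaluate_hboc_criteria(p61)$met)

  # breast + pancreatic double primary at any ages
  p <- make_patient(dx = list(list(icd10 = "C50", age_at_dx = 71),
                              list(icd10 = "C25", age_at_dx = 73)))
  expect_true("HBOC-P6" %in% evaluate_hboc_criteria(p)$fired_rules)

  # unindicated presentation
  p <- make_patient(dx = list(list(icd10 = "C54", age_at_dx = 63)))
  expect_false(evaluate_hboc_criteria(p)$met)
})

test_that("HBOC family-history rules require the qualifying proband and kin", {
  # patient BC + two relatives BC
  p <- make_patient(dx = list(list(icd10 = "C50", age_at_dx = 55)),
                    relatives = list(list(icd10 = "C50", age_at_dx = 60),
                                     list(icd10 = "C50", age_at_dx = 65)))
  expect_true("HBOC-F1" %in% evaluate_hboc_criteria(p)$fired_rules)

  # patient BC + one relative BC, one dx under 50
  p <- make_patient(dx = list(list(icd10 = "C50", age_at_dx = 55)),
                    relatives = list(list(icd10 = "C50", age_at_dx = 44)))
  expect_true("HBOC-F2" %in% evaluate_hboc_criteria(p)$fired_rules)
  # both at 55/56: neither under 50 nor both under 60 -> only via both<60
  p <- make_patient(dx = list(list(icd10 = "C50", age_at_dx = 55)),
                    relatives = list(list(icd10 = "C50", age_at_dx = 56)))
  expect_true("HBOC-F2" %in% evaluate_hboc_criteria(p)$fired_rules)
  p <- make_patient(dx = list(list(icd10 = "C50", age_at_dx = 62)),
                    relatives = list(list(icd10 = "C50", age_at_dx = 61)))
  expect_false(evaluate_hboc_criteria(p)$met)

  # direct relative with pancreatic cancer, proband with qualifying dx
  p <- make_patient(dx = list(list(icd10 = "C50", age_at_dx = 58)),
                    relatives = list(list(icd10 = "C25", age_at_dx = 60)))
  expect_true("HBOC-F3" %in% evaluate_hboc_criteria(p)$fired_rules)
  # same relative but non-direct line: no
  p <- make_patient(dx = list(list(icd10 = "C50", age_at_dx = 58)),
                    relatives = list(list(icd10 = "C25", age_at_dx = 60,
                                          direct_line = FALSE)))
  expect_false(evaluate_hboc_criteria(p)$met)
  # proband without a qualifying diagnosis: no F3
  p <- make_patient(dx = list(list(icd10 = "C54", age_at_dx = 58)),
                    relatives = list(list(icd10 = "C25", age_at_dx = 60)))
  expect_false(evaluate_hboc_criteria(p)$met)
})

test_that("LS rules fire on their defining presentations", {
  # early onset
  p <- make_patient(dx = list(list(icd10 = "C54", age_at_dx = 45)))
  expect_equal(evaluate_ls_criteria(p)$fired_rules, "LS-1")

  # concurrent LS-linked second primary
  p <- make_patient(dx = list(list(icd10 = "C54", age_at_dx = 60),
                              list(icd10 = "C18", age_at_dx = 58)))
  expect_true("LS-3" %in% evaluate_ls_criteria(p)$fired_rules)

  # two second-degree relatives, any age
  p <- make_patient(dx = list(list(icd10 = "C54", age_at_dx = 65)),
                    relatives = list(
                      list(icd10 = "C18", age_at_dx = 70, degree = "second",
                           direct_line = FALSE),
                      list(icd10 = "C18", age_at_dx = 72, degree = "second",
                           direct_line = FALSE)))
  expect_true("LS-5" %in% evaluate_ls_criteria(p)$fired_rules)

  # MSI-positive under 60
  p <- make_patient(dx = list(list(icd10 = "C54", age_at_dx = 55,
                                   msi_positive = TRUE)))
  expect_true("LS-2" %in% evaluate_ls_criteria(p)$fired_rules)

  # colorectal cancer with >10 adenomas
  p <- make_patient(dx = list(list(icd10 = "C18", age_at_dx = 62,
                                   adenoma_count = 14L)))
  expect_true("LS-6" %in% evaluate_ls_criteria(p)$fired_rules)

  # negative presentation
  p <- make_patient(dx = list(list(icd10 = "C54", age_at_dx = 70)))
  expect_false(evaluate_ls_criteria(p)$met)

  # no colorectal/endometrial index diagnosis violates the precondition
  p <- make_patient(dx = list(list(icd10 = "C50", age_at_dx = 40)))
  expect_error(evaluate_ls_criteria(p), "index")
})

test_that("LS-4 age condition modes behave as configured", {
  young_patient <- make_patient(
    dx = list(list(icd10 = "C54", age_at_dx = 45)),
    relatives = list(list(icd10 = "C18", age_at_dx = 70)))
  old_patient_young_rel <- make_patient(
    dx = list(list(icd10 = "C54", age_at_dx = 65)),
    relatives = list(list(icd10 = "C18", age_at_dx = 45)))
  both_old <- make_patient(
    dx = list(list(icd10 = "C54", age_at_dx = 65)),
    relatives = list(list(icd10 = "C18", age_at_dx = 70)))

  either <- criteria_options(ls4_age_mode = "either")
  expect_true("LS-4" %in% evaluate_ls_criteria(young_patient, either)$fired_rules)
  expect_true("LS-4" %in%
                evaluate_ls_criteria(old_patient_young_rel, either)$fired_rules)
  expect_false("LS-4" %in% evaluate_ls_criteria(both_old, either)$fired_rules)

  both_mode <- criteria_options(ls4_age_mode = "both")
  expect_false("LS-4" %in%
                 evaluate_ls_criteria(young_patient, both_mode)$fired_rules)

  rel_only <- criteria_options(ls4_age_mode = "relative_only")
  expect_false("LS-4" %in%
                 evaluate_ls_criteria(young_patient, rel_only)$fired_rules)
  expect_true("LS-4" %in%
                evaluate_ls_criteria(old_patient_young_rel, rel_only)$fired_rules)

  # relative-side EC counts by default, excludable by option
  p <- make_patient(dx = list(list(icd10 = "C54", age_at_dx = 45)),
                    relatives = list(list(icd10 = "C54", age_at_dx = 48)))
  expect_true("LS-4" %in% evaluate_ls_criteria(p)$fired_rules)
  no_ec <- criteria_options(relative_codes_include_ec = FALSE)
  expect_false("LS-4" %in% evaluate_ls_criteria(p, no_ec)$fired_rules)
})

test_that("unknown ages never fire age-bounded rules", {
  p <- make_patient(dx = list(list(icd10 = "C54", age_at_dx = NA_real_)))
  expect_false(evaluate_ls_criteria(p)$met)
  p <- make_patient(dx = list(list(icd10 = "C50", age_at_dx = NA_real_),
                              list(icd10 = "C54", age_at_dx = 65)))
  expect_false(evaluate_hboc_criteria(p)$met)
})

test_that("indication groups are the cross-product and partition the cohort", {
  ls_only <- make_patient("A", dx = list(list(icd10 = "C54", age_at_dx = 45)))
  hboc_only <- make_patient("B", dx = list(list(icd10 = "C54", age_at_dx = 60),
                                           list(icd10 = "C50", age_at_dx = 40)))
  both <- make_patient("C", dx = list(list(icd10 = "C54", age_at_dx = 45),
                                      list(icd10 = "C56", age_at_dx = 44)))
  none <- make_patient("D", dx = list(list(icd10 = "C54", age_at_dx = 70)))
  expect_equal(assign_indication_group(ls_only), "LS_ONLY")
  expect_equal(assign_indication_group(hboc_only), "HBOC_ONLY")
  expect_equal(assign_indication_group(both), "BOTH")
  expect_equal(assign_indication_group(none), "NONE")

  ph <- dplyr::bind_rows(ls_only$diagnoses, hboc_only$diagnoses,
                         both$diagnoses, none$diagnoses)
  groups <- assign_indication_groups(ph)
  counts <- partition_cohort(groups)
  expect_equal(sum(counts), 4L)
  expect_equal(unname(counts), rep(1L, 4))

  expect_equal(sum(partition_cohort(character(0))), 0L)
  all_young <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_patient(paste0("Y", i),
                 dx = list(list(icd10 = "C54", age_at_dx = 40 + i)))$diagnoses
  }))
  expect_equal(partition_cohort(assign_indication_groups(all_young))[["LS_ONLY"]],
               5L)
})

test_that("adding a qualifying diagnosis or relative is monotone in met", {
  base_dx <- list(list(icd10 = "C54", age_at_dx = 64))
  set.seed(42)
  for (i in 1:25) {
    extra_dx <- sample(list(list(icd10 = "C18", age_at_dx = 60),
                            list(icd10 = "C56", age_at_dx = 55),
                            list(icd10 = "C34", age_at_dx = 60)), 1)
    extra_rel <- sample(list(list(icd10 = "C18", age_at_dx = 44),
                             list(icd10 = "C50", age_at_dx = 44),
                             NULL), 1)[[1]]
    before <- make_patient(dx = base_dx)
    after <- make_patient(dx = c(base_dx, extra_dx),
                          relatives = if (is.null(extra_rel)) NULL
                                      else list(extra_rel))
    for (fn in list(function(p) evaluate_ls_criteria(p)$met,
                    function(p) evaluate_hboc_criteria(p)$met)) {
      expect_false(fn(before) && !fn(after))
    }
  }
})
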