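test_that("packaged checklist has the guideline composition", {
  cl <- load_checklist()
  expect_s3_class(cl, "sp_checklist")
  expect_equal(sum(cl$items$kind == "question"), 19)
  expect_equal(sum(cl$items$kind == "examination"), 13)
  expect_equal(cl$denominator_mode, "component_sum")
  expect_false(anyDuplicated(cl$items$item_id) > 0)
})

test_that("checklist config validation catches malformed input", {
  tiny <- load_checklist(write_mini_checklist())
  expect_equal(nrow(tiny$items), 2)

  dup <- write_mini_checklist(list(
    list(id = "q1", kind = "question"),
    list(id = "q1", kind = "examination")))
  expect_error(load_checklist(dup), "duplicate")

  badkind <- write_mini_checklist(list(
    list(id = "q1", kind = "question"),
    list(id = "x", kind = "palpation")))
  expect_error(load_checklist(badkind), "kind")

  onesided <- write_mini_checklist(list(
    list(id = "q1", kind = "question"),
    list(id = "q2", kind = "question")))
  expect_error(load_checklist(onesided), "at least one")
})

test_that("process scoring counts items by kind with the component-sum denominator", {
  cl <- load_checklist()
  qs <- cl$items$item_id[cl$items$kind == "question"]
  es <- cl$items$item_id[cl$items$kind == "examination"]

  res <- score_process(c(qs[1:3], es[1:3]), cl)
  expect_equal(res[c("n_questions", "n_examinations", "nrqe")],
               list(n_questions = 3, n_examinations = 3, nrqe = 6))
  expect_equal(res$anrqe, 6 / 32)

  expect_equal(score_process(character(0), cl)$nrqe, 0)
  expect_equal(score_process(character(0), cl)$anrqe, 0)

  full <- score_process(cl$items$item_id, cl)
  expect_equal(full$n_questions, 19)
  expect_equal(full$n_examinations, 13)
  expect_equal(full$anrqe, 1)

  expect_error(score_process("q_not_a_thing", cl), "not in checklist")
  expect_error(score_process(c(qs[1], qs[1]), cl), "duplicates")
})

test_that("fixed-total denominator mode divides by the configured total", {
  path <- tempfile(fileext = ".yaml")
  cfg <- yaml::read_yaml(system.file("extdata", "checklist.yaml", package = "spaudit"))
  cfg$denominator_mode <- "fixed_total"
  yaml::write_yaml(cfg, path)
  cl31 <- load_checklist(path)
  expect_equal(score_process(cl31$items$item_id[1:6], cl31)$anrqe, 6 / 31)
})

test_that("treatment classification follows the explicit policy", {
  rules <- load_drug_rules()
  pol <- treatment_policy()

  res <- classify_treatment("metformin", rules, pol)
  expect_true(res$correct_treatment)
  expect_true(res$correct_drugs)
  expect_false(res$harmful_drugs)

  res <- classify_treatment(c("metformin", "dexamethasone"), rules, pol)
  expect_false(res$correct_treatment)   # harmful veto
  expect_true(res$correct_drugs)        # at_least_one_correct
  expect_true(res$harmful_drugs)

  res <- classify_treatment(character(0), rules, pol)
  expect_false(res$correct_treatment)
  expect_true(is.na(res$correct_drugs)) # missing iff nothing dispensed
  expect_false(res$harmful_drugs)

  ## non-pharmacological route: both advice flags, nothing harmful
  res <- classify_treatment(character(0), rules, pol,
                            lifestyle_advice = TRUE,
                            glucose_monitoring_advice = TRUE)
  expect_true(res$correct_treatment)
  res <- classify_treatment(character(0), rules, pol, lifestyle_advice = TRUE)
  expect_false(res$correct_treatment)

  ## policy variants
  strict <- treatment_policy(drug_rule = "all_correct",
                             advice_counts_as_treatment = FALSE)
  expect_false(classify_treatment(c("metformin", "vitamin_b"), rules, strict)$correct_drugs)
  refpol <- treatment_policy(referral_counts_as_treatment = TRUE,
                             advice_counts_as_treatment = FALSE)
  expect_true(classify_treatment(character(0), rules, refpol, referred = TRUE)$correct_treatment)

  expect_error(classify_treatment("snake_oil", rules, pol), "snake_oil")
})

test_that("drug names are normalized by case and whitespace only", {
  rules <- load_drug_rules()
  res <- classify_treatment("  Metformin ", rules, treatment_policy())
  expect_true(res$correct_drugs)
  expect_error(load_drug_rules({
    p <- tempfile(fileext = ".yaml")
    yaml::write_yaml(list(correct = "metformin", harmful = "METFORMIN"), p)
    p
  }), "more than one class")
})
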