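test_that("generation is deterministic under a fixed seed and leaves the RNG alone", {
  p <- generator_params(seed = 123L)
  set.seed(1); before <- .Random.seed
  c1 <- generate_cohort(p)
  expect_identical(.Random.seed, before)
  c2 <- generate_cohort(p)
  expect_identical(c1, c2)
  c3 <- generate_cohort(generator_params(seed = 124L))
  expect_false(identical(c1$interactions$items_used, c3$interactions$items_used))
})

test_that("item probabilities of one force a complete checklist", {
  p <- generator_params(
    n_per_tier = c(VC = 20, THC = 0, CH = 0),
    item_probs = lapply(default_probs <- generator_params()$item_probs,
                        function(pr) {pr[] <- 1; pr}),
    seed = 2L)
  scored <- score_interactions(generate_cohort(p)$interactions)
  expect_true(all(scored$nrqe == 32))
  expect_true(all(scored$anrqe == 1))
})

test_that("mean NRQE per tier converges to the summed item probabilities", {
  p <- generator_params(n_per_tier = c(VC = 4000, THC = 4000, CH = 4000),
                        seed = 31L)
  scored <- score_interactions(generate_cohort(p)$interactions)
  for (t in c("VC", "THC", "CH")) {
    target <- sum(p$item_probs[[t]])
    obs <- mean(scored$nrqe[scored$tier == t])
    ## 4 sigma Monte-Carlo band; per-item Bernoulli variance bound
    band <- 4 * sqrt(sum(p$item_probs[[t]] * (1 - p$item_probs[[t]])) / 4000)
    expect_lt(abs(obs - target), band)
  }
})

test_that("a positive NRQE effect yields treatment rates non-decreasing in NRQE quartile", {
  p <- generator_params(n_per_tier = c(VC = 3400, THC = 3300, CH = 3300),
                        seed = 17L)
  stopifnot(p$treatment_coef$nrqe > 0)
  scored <- score_interactions(generate_cohort(p)$interactions)
  quart <- cut(scored$nrqe, stats::quantile(scored$nrqe, 0:4 / 4),
               include.lowest = TRUE)
  rates <- tapply(scored$correct_treatment, quart, mean)
  expect_true(all(diff(rates) >= 0))
})

test_that("re-scoring generated records recovers the drawn outcome model", {
  ## the logistic treatment model must be identifiable from the scored data:
  ## every estimate from a large single cohort sits within 4 SEs of its
  ## generating value (a tight but noise-tolerant one-seed check; the full
  ## repeated-sampling coverage study is in the acceptance suite)
  p <- generator_params(n_per_tier = c(VC = 7300, THC = 7700, CH = 5000),
                        seed = 8L)
  scored <- score_interactions(generate_cohort(p)$interactions)
  fit <- fit_logistic_ame(scored, c("nrqe", "tier"),
                          outcome = "correct_treatment")
  true <- c(p$treatment_coef$intercept[["VC"]], p$treatment_coef$nrqe,
            p$treatment_coef$intercept[["THC"]] - p$treatment_coef$intercept[["VC"]],
            p$treatment_coef$intercept[["CH"]] - p$treatment_coef$intercept[["VC"]])
  z <- (fit$coefficients$estimate - true) / fit$coefficients$se
  expect_true(all(abs(z) < 4))
})

test_that("household sorting follows the configured multinomial", {
  p <- generator_params(seed = 3L)
  hh <- generate_cohort(p)$households
  expect_equal(nrow(hh), 750)
  share <- mean(hh$first_visit_choice == "VC")
  expect_lt(abs(share - 0.39), 4 * sqrt(0.39 * 0.61 / 750))
  expect_true(all(hh$first_visit_choice %in% c("VC", "THC", "CH")))
})

test_that("invalid generator parameters are rejected", {
  expect_error(generator_params(sorting = c(VC = 0.5, THC = 0.4, CH = 0.2)),
               "sum to 1")
  bad_items <- generator_params()$item_probs
  bad_items$VC[1] <- 1.5
  expect_error(generator_params(item_probs = bad_items), "\\[0,1\\]")
  bad_ref <- generator_params()$referral_probs
  bad_ref$VC <- c(none = 0.5, THC = 0.2, CH = 0.2)
  expect_error(generator_params(referral_probs = bad_ref), "sum to 1")
})

test_that("generator parameters load from YAML with overrides", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_households = 100,
                        sorting = list(VC = 0.5, THC = 0.25, CH = 0.25),
                        seed = 9), path)
  p <- load_generator_params(path)
  expect_equal(p$n_households, 100)
  expect_equal(unname(p$sorting["VC"]), 0.5)
  hh <- generate_cohort(p)$households
  expect_equal(nrow(hh), 100)
})
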