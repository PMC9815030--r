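## Every published cell of the two tier-comparison tables, as
## (variable, tier, count, pct) and (variable, tier, mean, sd) expectations.
table1_count_cells <- list(
  list("male", c(34, 32, 15), c(73.9, 65.3, 48.4)),
  list("bachelor_or_higher", c(0, 7, 11), c(0.0, 14.3, 35.5)),
  list("practicing_certificate", c(11, 45, 30), c(23.9, 91.8, 96.8)),
  list("western_medicine_major", c(26, 39, 24), c(56.5, 79.6, 77.4)),
  list("monthly_diabetes_training", c(11, 7, 6), c(23.9, 14.3, 19.4)),
  list("online_training", c(20, 27, 25), c(43.5, 55.1, 80.6))
)
table1_mean_cells <- list(
  list("age", c(48.1, 44.7, 49.5), c(7.9, 8.4, 11.8)),
  list("income", c(2358.3, 4563.1, 7151.6), c(995.9, 1352.9, 3277.1)),
  list("diabetes_patients_2wk", c(5.2, 6.3, 26.6), c(6.5, 5.7, 41.5))
)
table2_count_cells <- list(
  list("correct_diagnosis", c(32, 44, 28), c(69.6, 93.6, 93.3)),
  list("correct_treatment", c(13, 18, 10), c(28.3, 36.7, 32.3)),
  list("correct_drugs", c(12, 11, 5), c(41.4, 78.6, 83.3)),
  list("harmful_drugs", c(11, 2, 0), c(23.9, 4.1, 0.0)),
  list("lifestyle_advice", c(24, 31, 14), c(52.2, 63.3, 45.2)),
  list("glucose_monitoring_advice", c(19, 31, 20), c(41.3, 63.3, 64.5)),
  list("referred", c(17, 7, 1), c(37.0, 14.3, 3.2))
)
table2_mean_cells <- list(
  list("n_questions", c(3.0, 3.5, 3.3), c(2.0, 1.7, 1.8)),
  list("n_examinations", c(2.5, 2.9, 2.9), c(1.0, 1.1, 1.2)),
  list("nrqe", c(5.5, 6.4, 6.3), c(2.5, 2.2, 2.3)),
  list("n_drugs", c(2.0, 1.6, 1.2), c(1.1, 1.2, 0.4))
)
fixture_tables <- function() {
  fix <- build_table_fixture()
  scored <- score_interactions(fix$interactions)
  list(t1 = build_tier_table(fix$providers, provider_table_spec()),
       t2 = build_tier_table(scored, quality_table_spec()))
}

check_cells <- function(tab, count_cells, mean_cells) {
  for (cell in count_cells) {
    rows <- tab[tab$variable == cell[[1]], ]
    expect_equal(rows$count, cell[[2]], info = cell[[1]])
    expect_equal(round_half_up(rows$pct, 1), cell[[3]], info = cell[[1]])
  }
  for (cell in mean_cells) {
    rows <- tab[tab$variable == cell[[1]], ]
    expect_equal(round_half_up(rows$mean, 1), cell[[2]], info = cell[[1]])
    expect_equal(round_half_up(rows$sd, 1), cell[[3]], info = cell[[1]])
  }
}

test_that("fixture reproduces every provider-characteristics cell", {
  tabs <- fixture_tables()
  expect_equal(unique(tabs$t1$n[tabs$t1$variable == "age"]), c(46, 49, 31))
  check_cells(tabs$t1, table1_count_cells, table1_mean_cells)
})

test_that("fixture reproduces every care-quality cell including subset denominators", {
  tabs <- fixture_tables()
  t2 <- tabs$t2
  ## correct-drugs row uses the dispensing subset as denominator
  expect_equal(t2$n[t2$variable == "correct_drugs"], c(29, 14, 6))
  ## harmful-drugs row uses the full tier denominator
  expect_equal(t2$n[t2$variable == "harmful_drugs"], c(46, 49, 31))
  ## diagnosis row excludes only missing-diagnosis records
  expect_equal(t2$n[t2$variable == "correct_diagnosis"], c(46, 47, 30))
  check_cells(t2, table2_count_cells, table2_mean_cells)
})

test_that("fixture reproduces every published significance classification", {
  tabs <- fixture_tables()
  both <- rbind(tabs$t1, tabs$t2)
  for (v in names(published_sig_classification)) {
    p <- both$p_value[both$variable == v][1]
    expect_equal(unname(p < 0.05), unname(published_sig_classification[v]), info = v)
  }
})

test_that("fixture is deterministic and round-trips through CSV unchanged", {
  fix1 <- build_table_fixture()
  fix2 <- build_table_fixture()
  expect_identical(fix1, fix2)

  ipath <- tempfile(fileext = ".csv")
  ppath <- tempfile(fileext = ".csv")
  write_interactions(fix1$interactions, ipath)
  write_providers(fix1$providers, ppath)
  expect_equal(read_interactions(ipath), fix1$interactions)
  expect_equal(read_providers(ppath), fix1$providers)
  expect_equal(score_interactions(read_interactions(ipath)),
               score_interactions(fix1$interactions))
})
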