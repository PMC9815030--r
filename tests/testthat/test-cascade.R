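fig_params <- function() load_cascade_params()

test_that("start-tier probabilities match hand enumeration of the paths", {
  p <- fig_params()
  ## CH starters succeed with the CH rate under every policy
  for (pol in c("additive_credit", "conditional_on_failure", "chain_thc_referral")) {
    expect_equal(start_tier_probability("CH", p$quality, p$referral, pol), 0.323)
  }
  ## hand enumeration of the four VC paths under additive crediting
  expect_equal(start_tier_probability("VC", p$quality, p$referral, "additive_credit"),
               0.283 + 0.217 * 0.323 + 0.152 * 0.367 + 0.022 * 0.323,
               tolerance = 1e-12)
  ## no referrals: every start tier reduces to its own quality
  r0 <- referral_rates(0, 0, 0, 0, 0)
  for (pol in c("additive_credit", "conditional_on_failure", "chain_thc_referral")) {
    for (t in c("VC", "THC", "CH")) {
      expect_equal(start_tier_probability(t, p$quality, r0, pol),
                   unname(p$quality[[t]]))
    }
  }
})

test_that("system probability is the sorting-weighted start-tier mix", {
  p <- fig_params()
  ## full hand enumeration with the published inputs
  hand <- 0.39 * (0.283 + 0.217 * 0.323 + 0.152 * 0.367 + 0.022 * 0.323) +
    0.32 * (0.367 + 0.143 * 0.323) + 0.29 * 0.323
  res <- system_probability(p$sorting, p$quality, p$referral, "additive_credit")
  expect_equal(res$system_probability, hand, tolerance = 1e-12)

  ## everyone starts at CH with no referrals
  expect_equal(system_probability(sorting_distribution(0, 0, 1), p$quality,
                                  referral_rates(0, 0), "additive_credit")$system_probability,
               0.323)
  ## conservation: equal quality everywhere and no referrals gives that quality
  qc <- tier_quality(0.4, 0.4, 0.4)
  expect_equal(system_probability(p$sorting, qc, referral_rates(0, 0),
                                  "conditional_on_failure")$system_probability, 0.4)
})

test_that("path-enumeration oracle agrees with the analytic cascade", {
  p <- fig_params()
  for (pol in c("additive_credit", "conditional_on_failure", "chain_thc_referral")) {
    a <- system_probability(p$sorting, p$quality, p$referral, pol)
    o <- enumerate_paths_oracle(p$sorting, p$quality, p$referral, pol)
    expect_equal(a$system_probability, o$system_probability, tolerance = 1e-12)
    expect_equal(a$per_tier, o$per_tier, tolerance = 1e-12)
  }
  ## degenerate corners
  expect_equal(enumerate_paths_oracle(sorting_distribution(1, 0, 0),
                                      tier_quality(1, 0, 0),
                                      referral_rates(0, 0),
                                      "additive_credit")$system_probability, 1)
  expect_equal(enumerate_paths_oracle(fig_params()$sorting, tier_quality(1, 1, 1),
                                      fig_params()$referral,
                                      "conditional_on_failure")$system_probability, 1)
})

test_that("oracle equality holds on random feasible draws of every policy", {
  set.seed(99)
  for (pol in c("additive_credit", "conditional_on_failure", "chain_thc_referral")) {
    for (i in 1:100) {
      pp <- random_cascade_params(pol)
      a <- system_probability(pp$s, pp$q, pp$r, pol)$system_probability
      o <- enumerate_paths_oracle(pp$s, pp$q, pp$r, pol)$system_probability
      expect_equal(a, o, tolerance = 1e-12)
    }
  }
})

test_that("path ledger mass is conserved", {
  set.seed(7)
  for (i in 1:25) {
    pp <- random_cascade_params("conditional_on_failure")
    res <- system_probability(pp$s, pp$q, pp$r, "conditional_on_failure")
    for (t in c("VC", "THC", "CH")) {
      expect_equal(sum(res$paths$probability[res$paths$start == t]), 1,
                   tolerance = 1e-12)
      expect_equal(sum(res$paths$probability[res$paths$start == t & res$paths$treated]),
                   unname(res$per_tier[t]), tolerance = 1e-12)
    }
    pp <- random_cascade_params("additive_credit")
    res <- system_probability(pp$s, pp$q, pp$r, "additive_credit")
    for (t in c("VC", "THC", "CH")) {
      expect_equal(sum(res$paths$probability[res$paths$start == t]), 1,
                   tolerance = 1e-12)  # treated + explicit residual
    }
  }
})

test_that("all three policies land in a plausible band on the published inputs", {
  p <- fig_params()
  for (pol in c("additive_credit", "conditional_on_failure", "chain_thc_referral")) {
    v <- system_probability(p$sorting, p$quality, p$referral, pol)$system_probability
    expect_gte(v, 0.30)
    expect_lte(v, 0.45)
  }
})

test_that("system probability is monotone in every tier quality", {
  set.seed(13)
  for (pol in c("additive_credit", "conditional_on_failure", "chain_thc_referral")) {
    for (i in 1:20) {
      pp <- random_cascade_params(pol)
      base <- system_probability(pp$s, pp$q, pp$r, pol)$system_probability
      for (t in c("VC", "THC", "CH")) {
        q2 <- pp$q
        bump <- if (pol == "conditional_on_failure") {
          min(1, q2[[t]] + 0.05)
        } else min(1 - 1e-12, q2[[t]] + {
          ## stay feasible for the additive policies
          room <- switch(t, VC = 1 - q2[["VC"]] - pp$r[["vc_thc"]] - pp$r[["vc_ch"]],
                         THC = 1 - q2[["THC"]] - pp$r[["thc_ch"]],
                         CH = 1 - q2[["CH"]] - pp$r[["ch_out"]])
          min(0.05, max(room, 0))
        })
        q2[[t]] <- bump
        expect_gte(system_probability(pp$s, q2, pp$r, pol)$system_probability,
                   base - 1e-12)
      }
    }
  }
})

test_that("feasibility violations and malformed rates raise informative errors", {
  p <- fig_params()
  expect_error(system_probability(p$sorting, tier_quality(0.9, 0.3, 0.3),
                                  p$referral, "additive_credit"),
               "infeasible.*VC")
  expect_error(referral_rates(0.1, 0.2, vc_thc_ch = 0.2), "second-hop")
  expect_error(sorting_distribution(0.5, 0.4, 0.2), "sum to 1")
  expect_error(tier_quality(1.2, 0.3, 0.3), "\\[0,1\\]")
})

test_that("sensitivity sweep is affine in a quality and flags infeasible points", {
  p <- fig_params()
  r0 <- referral_rates(0, 0)
  grid <- seq(0, 1, by = 0.1)
  sens <- sensitivity_grid(p$sorting, p$quality, r0, "q_VC", grid)
  slopes <- diff(sens$system_probability) / diff(sens$value)
  expect_equal(slopes, rep(unname(p$sorting[["VC"]]), length(slopes)),
               tolerance = 1e-12)

  ## with the published referral mass, large q_VC is infeasible under
  ## additive crediting and must be flagged, not dropped
  sens2 <- sensitivity_grid(p$sorting, p$quality, p$referral, "q_VC", grid)
  expect_equal(nrow(sens2), length(grid))
  expect_true(any(!sens2$feasible))
  ## conditional policy: more direct VC-to-CH referral helps when P(CH) > 0
  sens3 <- sensitivity_grid(p$sorting, p$quality, p$referral, "vc_ch",
                            seq(0, 0.5, by = 0.1), "conditional_on_failure")
  expect_true(all(diff(sens3$system_probability) > 0))
})

test_that("parametric bootstrap is seeded, covers the point, and tightens with data", {
  p <- fig_params()
  b1 <- bootstrap_cascade_ci(p$counts, B = 400, seed = 21)
  b2 <- bootstrap_cascade_ci(p$counts, B = 400, seed = 21)
  expect_identical(b1$replicates, b2$replicates)
  expect_lte(b1$lower, b1$point)
  expect_gte(b1$upper, b1$point)

  ## zero-variance inputs: every rate 0 or 1 with huge denominators, and a
  ## degenerate sorting distribution
  det_counts <- list(
    quality = list(VC = c(0, 10000), THC = c(0, 10000), CH = c(10000, 10000)),
    referral = list(vc_thc = c(0, 10000), vc_ch = c(0, 10000),
                    vc_thc_ch = c(0, 10000), thc_ch = c(0, 10000),
                    ch_out = c(0, 10000)),
    sorting = list(prob = c(VC = 0, THC = 0, CH = 1), n = 10000))
  b0 <- bootstrap_cascade_ci(det_counts, B = 200, seed = 3)
  expect_lt(b0$upper - b0$lower, 0.01)

  ## doubling every denominator at fixed rates shrinks the interval
  double_counts <- list(
    quality = lapply(p$counts$quality, function(kn) kn * 2),
    referral = lapply(p$counts$referral, function(kn) kn * 2),
    sorting = list(prob = p$counts$sorting$prob, n = p$counts$sorting$n * 2))
  bd <- bootstrap_cascade_ci(double_counts, B = 2000, seed = 21)
  bf <- bootstrap_cascade_ci(p$counts, B = 2000, seed = 21)
  expect_lt(bd$upper - bd$lower, bf$upper - bf$lower)

  expect_error(bootstrap_cascade_ci(p$counts, B = 10), "at least 100")
})
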