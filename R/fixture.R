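## Deterministic worked-example fixture: 126 providers (46 VC / 49 THC /
## 31 CH) whose scored interactions reproduce, cell for cell, the published
## tier-comparison tables of the rural T2D standardized-patient audit this
## package re-implements. Only the per-tier marginal cells are the contract:
## the joint structure (which provider holds which combination of
## attributes) is unidentifiable from marginal tables and is packed
## deterministically in record order.

## -- frozen per-tier vectors -------------------------------------------------
## Integer vectors searched offline so that mean/SD round (half-up, 1 dp) to
## the published cells and one-way ANOVA keeps each row's published
## significance classification.

fx <- local({
  age_vc <- c(64L, 59L, 59L, 57L, 57L, 57L, 57L, 57L, 57L, 56L, 56L, 55L, 55L,
              54L, 54L, 53L, 53L, 52L, 52L, 51L, 50L, 50L, 49L, 47L, 47L, 45L,
              45L, 45L, 44L, 44L, 44L, 43L, 43L, 42L, 42L, 42L, 42L, 41L, 39L,
              39L, 39L, 37L, 36L, 35L, 34L, 32L)
  age_thc <- c(63L, 59L, 58L, 56L, 55L, 55L, 55L, 55L, 55L, 54L, 51L, 51L, 51L,
               50L, 50L, 50L, 49L, 48L, 48L, 48L, 47L, 46L, 46L, 46L, 46L, 45L,
               44L, 43L, 42L, 42L, 42L, 41L, 40L, 40L, 40L, 38L, 37L, 36L, 36L,
               36L, 36L, 35L, 35L, 34L, 33L, 33L, 33L, 31L, 28L)
  age_ch <- c(70L, 68L, 68L, 65L, 64L, 63L, 62L, 61L, 57L, 57L, 55L, 52L, 51L,
              50L, 49L, 48L, 48L, 45L, 45L, 45L, 45L, 44L, 42L, 42L, 40L, 38L,
              34L, 33L, 31L, 31L, 30L)
  inc_vc <- c(4017L, 3943L, 3843L, 3839L, 3726L, 3673L, 3597L, 3463L, 3403L,
              3357L, 3293L, 3205L, 3148L, 3048L, 2984L, 2879L, 2847L, 2807L,
              2682L, 2581L, 2572L, 2496L, 2445L, 2305L, 2237L, 2201L, 2179L,
              1983L, 1977L, 1926L, 1790L, 1735L, 1624L, 1592L, 1501L, 1423L,
              1317L, 1310L, 1180L, 1150L, 1095L, 993L, 928L, 808L, 754L, 626L)
  inc_thc <- c(6855L, 6719L, 6698L, 6578L, 6485L, 6378L, 6208L, 6130L, 6047L,
               5963L, 5902L, 5795L, 5740L, 5623L, 5498L, 5410L, 5395L, 5223L,
               5196L, 5079L, 4900L, 4755L, 4737L, 4703L, 4494L, 4494L, 4279L,
               4256L, 4103L, 4081L, 3998L, 3953L, 3759L, 3691L, 3612L, 3513L,
               3454L, 3336L, 3249L, 3119L, 3095L, 3077L, 2849L, 2731L, 2681L,
               2615L, 2504L, 2370L, 2262L)
  inc_ch <- c(12482L, 12115L, 11817L, 11394L, 11159L, 10795L, 10421L, 10237L,
              9655L, 9350L, 8943L, 8562L, 8188L, 7888L, 7589L, 7092L, 6842L,
              6526L, 6112L, 5505L, 5293L, 4966L, 4671L, 4338L, 3915L, 3636L,
              3220L, 2732L, 2504L, 2047L, 1706L)
  pat_vc <- c(25L, 20L, 17L, 16L, 15L, 14L, 13L, 12L, 12L, 11L, 11L, 10L, 9L,
              9L, 6L, 6L, 5L, 5L, 5L, 4L, 3L, 3L, 2L, 1L, 1L, 1L, 1L, 1L, 1L,
              0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
  pat_thc <- c(18L, 18L, 16L, 15L, 14L, 14L, 13L, 13L, 13L, 12L, 12L, 11L, 10L,
               10L, 10L, 9L, 9L, 9L, 8L, 8L, 8L, 7L, 7L, 7L, 7L, 7L, 6L, 4L,
               4L, 3L, 3L, 2L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
               0L, 0L, 0L, 0L, 0L)
  pat_ch <- c(134L, 118L, 103L, 94L, 84L, 80L, 55L, 54L, 35L, 30L, 26L, 10L,
              1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
              0L, 0L, 0L)
  q_vc <- c(8L, 7L, 7L, 6L, 6L, 6L, 5L, 5L, 5L, 5L, 4L, 4L, 4L, 4L, 4L, 4L,
            4L, 4L, 4L, 3L, 3L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 1L, 1L,
            1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L)
  e_vc <- c(2L, 0L, 5L, 3L, 4L, 4L, 3L, 2L, 3L, 3L, 3L, 4L, 3L, 3L, 3L, 3L,
            2L, 3L, 1L, 2L, 5L, 2L, 2L, 2L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L,
            1L, 2L, 3L, 3L, 3L, 3L, 2L, 3L, 1L, 2L, 2L, 2L, 4L, 0L)
  q_thc <- c(8L, 8L, 6L, 6L, 6L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 4L, 4L,
             4L, 4L, 4L, 4L, 4L, 4L, 4L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L,
             3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L)
  e_thc <- c(3L, 3L, 5L, 3L, 5L, 3L, 3L, 4L, 2L, 3L, 1L, 3L, 5L, 2L, 3L, 3L,
             1L, 3L, 3L, 3L, 1L, 2L, 3L, 2L, 2L, 3L, 5L, 4L, 3L, 2L, 3L, 4L,
             5L, 2L, 3L, 3L, 2L, 4L, 4L, 3L, 2L, 2L, 1L, 3L, 2L, 3L, 4L, 4L, 0L)
  q_ch <- c(8L, 7L, 6L, 5L, 5L, 5L, 5L, 5L, 4L, 4L, 4L, 4L, 4L, 3L, 3L, 3L,
            3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 0L)
  e_ch <- c(5L, 5L, 3L, 0L, 0L, 2L, 2L, 4L, 3L, 3L, 3L, 4L, 2L, 3L, 3L, 2L,
            5L, 4L, 3L, 4L, 2L, 4L, 3L, 3L, 4L, 3L, 3L, 3L, 2L, 1L, 3L)
  nd_vc <- c(5L, 4L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L,
             1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L)
  nd_thc <- c(5L, 3L, 3L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L)
  nd_ch <- c(2L, 1L, 1L, 1L, 1L, 1L)
  list(age = list(VC = age_vc, THC = age_thc, CH = age_ch),
       income = list(VC = inc_vc, THC = inc_thc, CH = inc_ch),
       patients = list(VC = pat_vc, THC = pat_thc, CH = pat_ch),
       q = list(VC = q_vc, THC = q_thc, CH = q_ch),
       e = list(VC = e_vc, THC = e_thc, CH = e_ch),
       ndrugs = list(VC = nd_vc, THC = nd_thc, CH = nd_ch))
})

## per-tier marginal counts for the binary provider attributes
fx_provider_counts <- list(
  VC  = c(n = 46, male = 34, bachelor = 0,  cert = 11, major = 26, training = 11, online = 20),
  THC = c(n = 49, male = 32, bachelor = 7,  cert = 45, major = 39, training = 7,  online = 27),
  CH  = c(n = 31, male = 15, bachelor = 11, cert = 30, major = 24, training = 6,  online = 25)
)

prefix_flags <- function(n, k) rep(c(TRUE, FALSE), c(k, n - k))

NEUTRAL_FILLERS <- c("vitamin_b", "amoxicillin", "omeprazole", "herbal_tonic")

fixture_drugs <- function(class, count) {
  if (class == "none") return("")
  lead <- switch(class, correct = "metformin", harmful = "dexamethasone",
                 neutral = NEUTRAL_FILLERS[1])
  fillers <- setdiff(NEUTRAL_FILLERS, lead)
  join_tokens(c(lead, fillers[seq_len(count - 1)]))
}

fixture_tier_interactions <- function(tier, n, q, e, nd, checklist,
                                      drug_class, diagnosis, lifestyle,
                                      monitoring, referral_to) {
  qs <- checklist$items$item_id[checklist$items$kind == "question"]
  es <- checklist$items$item_id[checklist$items$kind == "examination"]
  items <- vapply(seq_len(n), function(i) {
    join_tokens(c(qs[seq_len(q[i])], es[seq_len(e[i])]))
  }, character(1))
  counts <- integer(n)
  counts[seq_along(nd)] <- nd
  drugs <- vapply(seq_len(n), function(i) fixture_drugs(drug_class[i], counts[i]),
                  character(1))
  data.frame(
    interaction_id = sprintf("I-%s-%02d", tier, seq_len(n)),
    provider_id = sprintf("P-%s-%02d", tier, seq_len(n)),
    tier = tier, items_used = items, diagnosis = diagnosis, drugs = drugs,
    lifestyle_advice = lifestyle, glucose_monitoring_advice = monitoring,
    referral_to = referral_to, stringsAsFactors = FALSE
  )
}

#' Build the deterministic 126-record worked-example fixture
#'
#' Returns a provider roster and one SP-interaction record per provider
#' (46 village-clinic, 49 township-health-center, 31 county-hospital)
#' constructed so that [score_interactions()] under the default
#' [treatment_policy()] followed by [build_tier_table()] reproduces every
#' count, percentage and one-decimal mean/SD cell of the audit's published
#' tier-comparison tables, as well as each row's significance
#' classification. The construction is fully deterministic (no randomness);
#' only the per-tier marginals are the contract — the joint structure is an
#' arbitrary deterministic packing.
#'
#' @param checklist checklist used to materialize `items_used` sets; the
#'   packaged default.
#' @return a list with elements `providers` (126-row provider table) and
#'   `interactions` (126-row interaction table), both in the canonical
#'   schemas of [read_providers()] / [read_interactions()].
#' @examples
#' fix <- build_table_fixture()
#' table(fix$interactions$tier)
#' @export
build_table_fixture <- function(checklist = load_checklist()) {
  ## interactions ------------------------------------------------------------
  ## VC: dispensers 1..29 (1..12 correct, 13..23 harmful, 24..29 neutral);
  ## advice-pair on 1..18 and 30; lifestyle also on 19..23;
  ## referrals from the 17 non-dispensers (7 -> THC, 10 -> CH).
  vc <- fixture_tier_interactions(
    "VC", 46, fx$q$VC, fx$e$VC, fx$ndrugs$VC, checklist,
    drug_class = rep(c("correct", "harmful", "neutral", "none"), c(12, 11, 6, 17)),
    diagnosis = rep(c("correct", "incorrect"), c(32, 14)),
    lifestyle = seq_len(46) %in% c(1:23, 30),
    monitoring = seq_len(46) %in% c(1:18, 30),
    referral_to = rep(c("none", "THC", "CH"), c(29, 7, 10))
  )
  ## THC: dispensers 1..14 (1..11 correct, 12..13 harmful, 14 neutral);
  ## advice-pair treated 15..21; lifestyle-only 22..32; monitoring-only
  ## 33..43; referrals 43..49 -> CH; diagnosis missing on 48..49.
  thc <- fixture_tier_interactions(
    "THC", 49, fx$q$THC, fx$e$THC, fx$ndrugs$THC, checklist,
    drug_class = rep(c("correct", "harmful", "neutral", "none"), c(11, 2, 1, 35)),
    diagnosis = rep(c("correct", "incorrect", "missing"), c(44, 3, 2)),
    lifestyle = seq_len(49) %in% c(1:13, 15:32),
    monitoring = seq_len(49) %in% c(1:13, 15:21, 33:43),
    referral_to = rep(c("none", "CH"), c(42, 7))
  )
  ## CH: dispensers 1..6 (1..5 correct, 6 neutral); advice-pair treated
  ## 7..11; lifestyle-only 12..15; monitoring-only 16..25; one outward
  ## referral (31); diagnosis missing on 31.
  ch <- fixture_tier_interactions(
    "CH", 31, fx$q$CH, fx$e$CH, fx$ndrugs$CH, checklist,
    drug_class = rep(c("correct", "neutral", "none"), c(5, 1, 25)),
    diagnosis = rep(c("correct", "incorrect", "missing"), c(28, 2, 1)),
    lifestyle = seq_len(31) %in% c(1:5, 7:15),
    monitoring = seq_len(31) %in% c(1:5, 7:11, 16:25),
    referral_to = rep(c("none", "other"), c(30, 1))
  )
  interactions <- rbind(vc, thc, ch)

  ## providers ---------------------------------------------------------------
  providers <- do.call(rbind, lapply(TIERS, function(t) {
    k <- fx_provider_counts[[t]]
    n <- k[["n"]]
    data.frame(
      provider_id = sprintf("P-%s-%02d", t, seq_len(n)),
      tier = t,
      age = fx$age[[t]],
      male = prefix_flags(n, k[["male"]]),
      bachelor_or_higher = prefix_flags(n, k[["bachelor"]]),
      practicing_certificate = prefix_flags(n, k[["cert"]]),
      western_medicine_major = prefix_flags(n, k[["major"]]),
      income = fx$income[[t]],
      diabetes_patients_2wk = fx$patients[[t]],
      monthly_diabetes_training = prefix_flags(n, k[["training"]]),
      online_training = prefix_flags(n, k[["online"]]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(providers) <- rownames(interactions) <- NULL
  list(providers = validate_providers(providers),
       interactions = validate_interactions(interactions))
}
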