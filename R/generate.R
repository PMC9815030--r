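## Default per-item use probabilities. Profiles encode the qualitative
## pattern reported for this kind of audit (thirst asked most; family
## history rarely; capillary glucose near-universal; OGTT and BMI rare),
## scaled per tier so the expected question/examination counts match the
## published tier means (3.0/3.5/3.3 questions, 2.5/2.9/2.9 examinations).
question_base <- c(
  q_dry_mouth_thirst = 0.55, q_polyuria = 0.30, q_polyphagia = 0.22,
  q_weight_change = 0.28, q_family_history = 0.15, q_prior_glucose_test = 0.35,
  q_diabetes_history = 0.38, q_age = 0.40, q_symptom_duration = 0.25,
  q_fatigue = 0.15, q_blurred_vision = 0.08, q_numbness = 0.05,
  q_skin_healing = 0.04, q_nocturia = 0.10, q_current_medication = 0.20,
  q_hypertension_history = 0.12, q_smoking = 0.08, q_alcohol = 0.07,
  q_diet = 0.23
)
exam_base <- c(
  e_capillary_glucose = 0.95, e_fpg = 0.40, e_hba1c = 0.38, e_ogtt = 0.05,
  e_bmi = 0.02, e_height = 0.04, e_weight = 0.04, e_blood_pressure = 0.30,
  e_urine = 0.12, e_lipids = 0.08, e_renal = 0.05, e_foot = 0.03,
  e_fundus = 0.03
)

default_item_probs <- function() {
  q_target <- c(VC = 3.0, THC = 3.5, CH = 3.3)
  e_target <- c(VC = 2.5, THC = 2.9, CH = 2.9)
  out <- lapply(TIERS, function(t) {
    q <- question_base * (q_target[[t]] / sum(question_base))
    ## capillary glucose held fixed near 1; remaining mass scaled
    e_rest <- exam_base[-1] * ((e_target[[t]] - exam_base[[1]]) / sum(exam_base[-1]))
    c(q, exam_base[1], e_rest)
  })
  names(out) <- TIERS
  for (t in TIERS) names(out[[t]]) <- c(names(question_base), names(exam_base))
  out
}

#' Parameters of the synthetic-cohort generator
#'
#' Bundles every knob of [generate_cohort()]: tier sample sizes, per-tier
#' item-use probabilities, logistic coefficients of the diagnosis and
#' treatment outcome models, per-tier referral distributions, household
#' sorting probabilities, and the seed. Defaults emulate the audit's study
#' conditions: 46/49/31 providers, 750 households sorting 39%/32%/29% to
#' VC/THC/CH, item-use rates calibrated to the published per-tier mean
#' question/examination counts, and outcome-model coefficients calibrated so
#' the marginal correct-diagnosis and correct-treatment rates sit at the
#' published tier rates (with an NRQE slope on treatment whose average
#' marginal effect is about +0.05 per item).
#'
#' @param n_per_tier named integer vector (`VC`, `THC`, `CH`).
#' @param item_probs named list per tier of per-item use probabilities.
#' @param diagnosis_coef list: `intercept` (named per tier), `nrqe`,
#'   `certificate`, `income_z`.
#' @param treatment_coef list: `intercept` (named per tier), `nrqe`.
#' @param referral_probs named list per tier of destination probabilities
#'   (destinations from `none`, `THC`, `CH`, `other`), each summing to 1.
#' @param sorting named numeric (`VC`, `THC`, `CH`), summing to 1.
#' @param n_households integer.
#' @param p_household_diabetes probability that a household has a member
#'   with diagnosed diabetes.
#' @param seed integer RNG seed.
#' @return an object of class `sp_generator_params`.
#' @export
generator_params <- function(n_per_tier = c(VC = 46, THC = 49, CH = 31),
                             item_probs = default_item_probs(),
                             diagnosis_coef = list(
                               intercept = c(VC = -0.19, THC = 0.99, CH = 0.92),
                               nrqe = 0.15, certificate = 0.8, income_z = -0.2),
                             treatment_coef = list(
                               intercept = c(VC = -2.19, THC = -2.02, CH = -2.19),
                               nrqe = 0.23),
                             referral_probs = list(
                               VC = c(none = 0.631, THC = 0.152, CH = 0.217),
                               THC = c(none = 0.857, CH = 0.143),
                               CH = c(none = 0.968, other = 0.032)),
                             sorting = c(VC = 0.39, THC = 0.32, CH = 0.29),
                             n_households = 750,
                             p_household_diabetes = 0.2,
                             seed = 1L) {
  p <- structure(list(n_per_tier = n_per_tier, item_probs = item_probs,
                      diagnosis_coef = diagnosis_coef,
                      treatment_coef = treatment_coef,
                      referral_probs = referral_probs, sorting = sorting,
                      n_households = n_households,
                      p_household_diabetes = p_household_diabetes,
                      seed = as.integer(seed)),
                 class = "sp_generator_params")
  validate_generator_params(p)
  p
}

validate_generator_params <- function(p) {
  stopifnot(all(TIERS %in% names(p$n_per_tier)), all(p$n_per_tier >= 0))
  for (t in TIERS) {
    pr <- p$item_probs[[t]]
    if (any(pr < 0 | pr > 1)) stop_sp("item probability outside [0,1] for tier %s", t)
    rp <- p$referral_probs[[t]]
    if (any(rp < 0 | rp > 1)) stop_sp("referral probability outside [0,1] for tier %s", t)
    if (abs(sum(rp) - 1) > 1e-9) stop_sp("referral probabilities for %s do not sum to 1", t)
  }
  if (any(p$sorting < 0 | p$sorting > 1)) stop_sp("sorting probability outside [0,1]")
  if (abs(sum(p$sorting) - 1) > 1e-9) stop_sp("sorting probabilities must sum to 1 (got %.12f)", sum(p$sorting))
  if (p$p_household_diabetes < 0 || p$p_household_diabetes > 1) {
    stop_sp("p_household_diabetes outside [0,1]")
  }
  invisible(p)
}

#' Read generator parameters from a YAML file
#'
#' Any field present in the file overrides the corresponding
#' [generator_params()] default.
#'
#' @param path YAML file path.
#' @return an `sp_generator_params`.
#' @export
load_generator_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- generator_params()
  for (nm in names(cfg)) {
    if (!nm %in% names(defaults)) stop_sp("unknown generator parameter '%s'", nm)
    val <- cfg[[nm]]
    if (nm %in% c("n_per_tier", "sorting")) val <- unlist(val)
    if (nm %in% c("item_probs", "referral_probs")) val <- lapply(val, unlist)
    if (nm %in% c("diagnosis_coef", "treatment_coef")) {
      val <- lapply(val, function(x) if (length(x) > 1 || is.list(x)) unlist(x) else x)
    }
    defaults[[nm]] <- val
  }
  do.call(generator_params, unclass(defaults))
}

## per-tier provider covariate distributions (moment-matched to the audit's
## provider-characteristics table)
provider_dist <- list(
  VC  = list(age = c(48.1, 7.9),  income = c(2358.3, 995.9),
             patients = c(5.2, 6.5),
             male = 34 / 46, bachelor = 0 / 46, cert = 11 / 46,
             major = 26 / 46, training = 11 / 46, online = 20 / 46),
  THC = list(age = c(44.7, 8.4),  income = c(4563.1, 1352.9),
             patients = c(6.3, 5.7),
             male = 32 / 49, bachelor = 7 / 49, cert = 45 / 49,
             major = 39 / 49, training = 7 / 49, online = 27 / 49),
  CH  = list(age = c(49.5, 11.8), income = c(7151.6, 3277.1),
             patients = c(26.6, 41.5),
             male = 15 / 31, bachelor = 11 / 31, cert = 30 / 31,
             major = 24 / 31, training = 6 / 31, online = 25 / 31)
)

rtrunc_norm_int <- function(n, mean, sd, lo, hi) {
  x <- round(stats::rnorm(n, mean, sd))
  pmin(pmax(x, lo), hi)
}

rlnorm_matched <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

rnbinom_matched <- function(n, mean, sd) {
  v <- sd^2
  if (v <= mean) return(stats::rpois(n, mean))
  stats::rnbinom(n, mu = mean, size = mean^2 / (v - mean))
}

#' Generate a synthetic SP-audit cohort
#'
#' Draws a provider roster from tier-stratified covariate distributions, one
#' SP interaction per provider, and a household sorting table, under the
#' data-generating model the correlate analysis assumes: checklist items are
#' independent per-item coin flips with tier-specific probabilities;
#' diagnosis is correct with probability
#' `plogis(a_tier + b1*NRQE + b2*certificate + b3*income_z)`; treatment is
#' correct with probability `plogis(c_tier + d*NRQE)`; referral is an
#' independent per-tier categorical draw; household first-visit choices are
#' multinomial. Records are materialized so that re-scoring them with the
#' default [treatment_policy()] recovers the drawn outcome labels exactly
#' (treated visits carry a correct-class drug; untreated visits never carry
#' both advice flags). Identical `params` (including seed) give identical
#' output; the global RNG state is left untouched.
#'
#' @param params an [generator_params()].
#' @param checklist checklist whose item ids the interactions use.
#' @return list with `providers`, `interactions`, `households` data.frames
#'   in the canonical schemas.
#' @export
generate_cohort <- function(params = generator_params(),
                            checklist = load_checklist()) {
  validate_generator_params(params)
  with_local_seed(params$seed, {
    providers <- do.call(rbind, lapply(TIERS, function(t) {
      n <- params$n_per_tier[[t]]
      d <- provider_dist[[t]]
      if (n == 0) return(NULL)
      data.frame(
        provider_id = sprintf("S-%s-%04d", t, seq_len(n)),
        tier = t,
        age = rtrunc_norm_int(n, d$age[1], d$age[2], 22, 78),
        male = stats::runif(n) < d$male,
        bachelor_or_higher = stats::runif(n) < d$bachelor,
        practicing_certificate = stats::runif(n) < d$cert,
        western_medicine_major = stats::runif(n) < d$major,
        income = round(rlnorm_matched(n, d$income[1], d$income[2]), 1),
        diabetes_patients_2wk = rnbinom_matched(n, d$patients[1], d$patients[2]),
        monthly_diabetes_training = stats::runif(n) < d$training,
        online_training = stats::runif(n) < d$online,
        stringsAsFactors = FALSE
      )
    }))
    rownames(providers) <- NULL
    n_all <- nrow(providers)
    income_z <- as.numeric(scale(providers$income))

    item_ids <- checklist$items$item_id
    k <- length(item_ids)
    items_used <- character(n_all)
    nrqe <- integer(n_all)
    for (t in TIERS) {
      idx <- which(providers$tier == t)
      if (!length(idx)) next
      pr <- params$item_probs[[t]][match(item_ids, names(params$item_probs[[t]]))]
      if (anyNA(pr)) stop_sp("item_probs missing checklist item(s) for tier %s", t)
      use <- matrix(stats::runif(length(idx) * k), length(idx), k) <
        matrix(pr, length(idx), k, byrow = TRUE)
      nrqe[idx] <- rowSums(use)
      items_used[idx] <- apply(use, 1, function(u) join_tokens(item_ids[u]))
    }

    dint <- params$diagnosis_coef$intercept[providers$tier]
    eta_d <- dint + params$diagnosis_coef$nrqe * nrqe +
      params$diagnosis_coef$certificate * providers$practicing_certificate +
      params$diagnosis_coef$income_z * income_z
    diag_correct <- stats::runif(n_all) < stats::plogis(eta_d)

    tint <- params$treatment_coef$intercept[providers$tier]
    eta_t <- tint + params$treatment_coef$nrqe * nrqe
    treated <- stats::runif(n_all) < stats::plogis(eta_t)

    referral_to <- character(n_all)
    for (t in TIERS) {
      idx <- which(providers$tier == t)
      if (!length(idx)) next
      rp <- params$referral_probs[[t]]
      referral_to[idx] <- sample(names(rp), length(idx), replace = TRUE, prob = rp)
    }

    ## materialize drugs/advice consistently with the drawn treatment label
    u_drug <- stats::runif(n_all)
    drugs <- ifelse(treated, "metformin",
                    ifelse(u_drug < 0.25, "dexamethasone",
                           ifelse(u_drug < 0.60, "vitamin_b", "")))
    lifestyle <- stats::runif(n_all) < 0.55
    monitoring <- stats::runif(n_all) < 0.50
    monitoring[!treated & lifestyle] <- FALSE

    interactions <- data.frame(
      interaction_id = sprintf("SI-%04d", seq_len(n_all)),
      provider_id = providers$provider_id,
      tier = providers$tier,
      items_used = items_used,
      diagnosis = ifelse(diag_correct, "correct", "incorrect"),
      drugs = drugs,
      lifestyle_advice = lifestyle,
      glucose_monitoring_advice = monitoring,
      referral_to = referral_to,
      stringsAsFactors = FALSE
    )

    nh <- params$n_households
    choice <- sample(TIERS, nh, replace = TRUE, prob = params$sorting[TIERS])
    households <- data.frame(
      household_id = sprintf("H-%04d", seq_len(nh)),
      first_visit_choice = choice,
      has_diabetes_member = stats::runif(nh) < params$p_household_diabetes,
      stringsAsFactors = FALSE
    )
    sp_log("simulate", sprintf("generated %d providers, %d households (seed %d)",
                               n_all, nh, params$seed))
    list(providers = validate_providers(providers),
         interactions = validate_interactions(interactions),
         households = validate_households(households))
  })
}
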