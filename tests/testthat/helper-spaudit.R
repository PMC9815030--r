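options(spaudit.quiet = TRUE)

## a two-item checklist written to a temp YAML
write_mini_checklist <- function(items = list(
  list(id = "q1", kind = "question", label = "q1", essential = TRUE),
  list(id = "e1", kind = "examination", label = "e1", essential = FALSE))) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(denominator_mode = "component_sum", items = items), path)
  path
}

## one canonical interaction row
make_record <- function(id = "I1", tier = "VC", items = character(0),
                        diagnosis = "correct", drugs = character(0),
                        lifestyle = FALSE, monitoring = FALSE,
                        referral = "none") {
  data.frame(interaction_id = id, provider_id = paste0("P", id), tier = tier,
             items_used = paste(items, collapse = ";"), diagnosis = diagnosis,
             drugs = paste(drugs, collapse = ";"),
             lifestyle_advice = lifestyle,
             glucose_monitoring_advice = monitoring,
             referral_to = referral, stringsAsFactors = FALSE)
}

## published significance classification (p < 0.05) per table row; the
## share-of-items (ANRQE) row is excluded: its published denominator is not
## reconstructible (documented in the methods vignette)
published_sig_classification <- c(
  age = FALSE, male = FALSE, bachelor_or_higher = TRUE,
  practicing_certificate = TRUE, western_medicine_major = TRUE,
  income = TRUE, diabetes_patients_2wk = TRUE,
  monthly_diabetes_training = FALSE, online_training = TRUE,
  n_questions = FALSE, n_examinations = FALSE, nrqe = FALSE,
  correct_diagnosis = TRUE, correct_treatment = FALSE, n_drugs = FALSE,
  correct_drugs = TRUE, harmful_drugs = TRUE, lifestyle_advice = FALSE,
  glucose_monitoring_advice = FALSE, referred = TRUE
)

## random feasible cascade parameters for a given policy
random_cascade_params <- function(policy) {
  q <- tier_quality(runif(1), runif(1), runif(1))
  if (policy == "conditional_on_failure") {
    room_vc <- 1
  } else {
    room_vc <- 1 - q[["VC"]]
  }
  w <- runif(2)
  vc_out <- runif(1, 0, room_vc)
  vc_thc <- vc_out * w[1] / sum(w)
  vc_ch <- vc_out * w[2] / sum(w)
  thc_ch <- runif(1, 0, if (policy == "conditional_on_failure") 1 else 1 - q[["THC"]])
  ch_out <- runif(1, 0, if (policy == "conditional_on_failure") 1 else 1 - q[["CH"]])
  r <- referral_rates(vc_thc, vc_ch, vc_thc_ch = runif(1, 0, vc_thc),
                      thc_ch = thc_ch, ch_out = ch_out)
  s_raw <- runif(3)
  s_raw <- s_raw / sum(s_raw)
  ## exact unit sum for the validator
  s <- sorting_distribution(s_raw[1], s_raw[2], 1 - s_raw[1] - s_raw[2])
  list(s = s, q = q, r = r)
}
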