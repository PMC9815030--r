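#' Score the consultation process of one interaction
#'
#' Counts the recommended questions and examinations a provider used,
#' yielding the process-quality outcomes: `n_questions`, `n_examinations`,
#' their sum NRQE (number of recommended questions and examinations), and
#' the adherence proportion ANRQE = NRQE / denominator.
#'
#' @param items_used character vector of checklist `item_id`s used during
#'   the visit (a set; duplicates are an error).
#' @param checklist an [sp_checklist][load_checklist].
#' @return a list with `n_questions`, `n_examinations`, `nrqe`, `anrqe`.
#' @examples
#' cl <- load_checklist()
#' score_process(c("q_age", "q_diet", "e_fpg"), cl)
#' @export
score_process <- function(items_used, checklist) {
  stopifnot(inherits(checklist, "sp_checklist"))
  items_used <- as.character(items_used)
  if (anyDuplicated(items_used)) {
    stop_sp("items_used contains duplicates: %s",
            paste(unique(items_used[duplicated(items_used)]), collapse = ", "))
  }
  unknown <- setdiff(items_used, checklist$items$item_id)
  if (length(unknown)) {
    stop_sp("item(s) not in checklist: %s", paste(unknown, collapse = ", "))
  }
  kind <- checklist$items$kind[match(items_used, checklist$items$item_id)]
  nq <- sum(kind == "question")
  ne <- sum(kind == "examination")
  list(n_questions = nq, n_examinations = ne, nrqe = nq + ne,
       anrqe = (nq + ne) / checklist_denominator(checklist))
}

#' Classify the treatment given during one interaction
#'
#' Applies a [treatment_policy()] to the dispensed drugs, advice flags and
#' referral outcome of a visit.
#'
#' @param drugs character vector of dispensed drug names (possibly empty).
#' @param rules an [sp_drug_rules][load_drug_rules].
#' @param policy an [sp_treatment_policy][treatment_policy].
#' @param lifestyle_advice,glucose_monitoring_advice logical advice flags.
#' @param referred logical; was the patient referred onward.
#' @return list with `correct_treatment` (logical), `correct_drugs`
#'   (logical, `NA` when nothing was dispensed), `harmful_drugs` (logical),
#'   `dispensed_any` (logical).
#' @export
classify_treatment <- function(drugs, rules, policy = treatment_policy(),
                               lifestyle_advice = FALSE,
                               glucose_monitoring_advice = FALSE,
                               referred = FALSE) {
  stopifnot(inherits(rules, "sp_drug_rules"),
            inherits(policy, "sp_treatment_policy"))
  drugs <- normalize_drug(as.character(drugs))
  drugs <- drugs[nzchar(drugs)]
  unknown <- setdiff(drugs, names(rules))
  if (length(unknown)) {
    stop_sp("drug(s) not in rule set: %s", paste(unknown, collapse = ", "))
  }
  cls <- unname(rules[drugs])
  dispensed_any <- length(drugs) > 0
  harmful <- any(cls == "harmful")
  correct_drugs <- if (!dispensed_any) NA else {
    if (policy$drug_rule == "at_least_one_correct") any(cls == "correct")
    else all(cls == "correct")
  }
  treated <- isTRUE(correct_drugs) ||
    (policy$advice_counts_as_treatment &&
       isTRUE(lifestyle_advice) && isTRUE(glucose_monitoring_advice)) ||
    (policy$referral_counts_as_treatment && isTRUE(referred))
  if (policy$require_no_harmful && harmful) treated <- FALSE
  list(correct_treatment = treated, correct_drugs = correct_drugs,
       harmful_drugs = harmful, dispensed_any = dispensed_any)
}

#' Score a cohort of interaction records
#'
#' Applies [score_process()] and [classify_treatment()] to every row of an
#' interaction table, yielding one scored row per record (order-preserving).
#' The first invalid record aborts the run, naming its `interaction_id`.
#'
#' @param records interaction data.frame in the package's canonical schema
#'   (see [read_interactions()]); `items_used` and `drugs` are
#'   semicolon-separated token fields.
#' @param checklist an [sp_checklist][load_checklist].
#' @param rules an [sp_drug_rules][load_drug_rules].
#' @param policy an [sp_treatment_policy][treatment_policy].
#' @return a data.frame of class `sp_scored` with one row per record:
#'   `interaction_id`, `provider_id`, `tier`, `n_questions`,
#'   `n_examinations`, `nrqe`, `anrqe`, `correct_diagnosis` (logical, `NA`
#'   when no diagnosis was stated), `dispensed_any`, `n_drugs`,
#'   `correct_drugs` (`NA` iff nothing dispensed), `harmful_drugs`,
#'   `correct_treatment`, `lifestyle_advice`, `glucose_monitoring_advice`,
#'   `referred`.
#' @export
score_interactions <- function(records,
                               checklist = load_checklist(),
                               rules = load_drug_rules(),
                               policy = treatment_policy()) {
  records <- validate_interactions(records)
  n <- nrow(records)
  if (n == 0) {
    scored <- empty_scored()
  } else {
    items_list <- lapply(records$items_used, split_tokens)
    drugs_list <- lapply(records$drugs, split_tokens)
    nq <- ne <- nd <- integer(n)
    correct_drugs <- harmful <- treated <- logical(n)
    referred <- records$referral_to != "none"
    for (i in seq_len(n)) {
      res <- tryCatch({
        proc <- score_process(items_list[[i]], checklist)
        trt <- classify_treatment(drugs_list[[i]], rules, policy,
                                  lifestyle_advice = records$lifestyle_advice[i],
                                  glucose_monitoring_advice = records$glucose_monitoring_advice[i],
                                  referred = referred[i])
        c(proc, trt)
      }, error = function(e) {
        stop_sp("record '%s': %s", records$interaction_id[i], conditionMessage(e))
      })
      nq[i] <- res$n_questions
      ne[i] <- res$n_examinations
      nd[i] <- length(drugs_list[[i]])
      correct_drugs[i] <- res$correct_drugs
      harmful[i] <- res$harmful_drugs
      treated[i] <- res$correct_treatment
    }
    scored <- data.frame(
      interaction_id = records$interaction_id,
      provider_id = records$provider_id,
      tier = records$tier,
      n_questions = nq,
      n_examinations = ne,
      nrqe = nq + ne,
      anrqe = (nq + ne) / checklist_denominator(checklist),
      correct_diagnosis = ifelse(records$diagnosis == "missing", NA,
                                 records$diagnosis == "correct"),
      dispensed_any = nd > 0,
      n_drugs = nd,
      correct_drugs = correct_drugs,
      harmful_drugs = harmful,
      correct_treatment = treated,
      lifestyle_advice = records$lifestyle_advice,
      glucose_monitoring_advice = records$glucose_monitoring_advice,
      referred = referred,
      stringsAsFactors = FALSE
    )
  }
  scored$tier <- as_tier(scored$tier)
  class(scored) <- c("sp_scored", "data.frame")
  tab <- table(scored$tier)
  sp_log("score", sprintf("scored %d interactions (%s)", n,
                          paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  scored
}

empty_scored <- function() {
  data.frame(interaction_id = character(0), provider_id = character(0),
             tier = character(0), n_questions = integer(0),
             n_examinations = integer(0), nrqe = integer(0), anrqe = numeric(0),
             correct_diagnosis = logical(0), dispensed_any = logical(0),
             n_drugs = integer(0), correct_drugs = logical(0),
             harmful_drugs = logical(0), correct_treatment = logical(0),
             lifestyle_advice = logical(0), glucose_monitoring_advice = logical(0),
             referred = logical(0), stringsAsFactors = FALSE)
}
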