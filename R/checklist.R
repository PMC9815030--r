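#' Load a consultation checklist from YAML
#'
#' A checklist defines the guideline standard a standardized-patient (SP)
#' interaction is scored against: an ordered set of recommended history
#' *questions* and physical/laboratory *examinations*, each with a stable
#' `item_id` and an `essential` flag. The packaged default (19 questions,
#' 13 examinations) represents the national first-visit standard for an
#' undiagnosed type 2 diabetes case.
#'
#' @param path path to a checklist YAML file; defaults to the packaged
#'   checklist.
#' @return an object of class `sp_checklist`: a list with `items`
#'   (data.frame: `item_id`, `kind`, `label`, `essential`),
#'   `denominator_mode` (`"component_sum"` or `"fixed_total"`) and
#'   `fixed_total`.
#' @details The adherence proportion ANRQE divides the item count NRQE by a
#'   denominator: in `component_sum` mode the number of checklist items
#'   (32 for the default list); in `fixed_total` mode the configured
#'   `fixed_total` (31 in the packaged file, the alternative total some
#'   reports quote for this guideline).
#' @export
load_checklist <- function(path = system.file("extdata", "checklist.yaml",
                                              package = "spaudit")) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$items) || length(cfg$items) == 0) {
    stop_sp("checklist config has no items")
  }
  items <- do.call(rbind, lapply(cfg$items, function(it) {
    for (f in c("id", "kind")) {
      if (is.null(it[[f]])) stop_sp("checklist item missing field '%s'", f)
    }
    if (!it$kind %in% c("question", "examination")) {
      stop_sp("unknown checklist item kind '%s' for item '%s'", it$kind, it$id)
    }
    data.frame(item_id = it$id, kind = it$kind,
               label = it$label %||% it$id,
               essential = isTRUE(it$essential),
               stringsAsFactors = FALSE)
  }))
  dup <- items$item_id[duplicated(items$item_id)]
  if (length(dup)) stop_sp("duplicate checklist item_id: %s", paste(unique(dup), collapse = ", "))
  if (!any(items$kind == "question") || !any(items$kind == "examination")) {
    stop_sp("checklist must contain at least one question and one examination")
  }
  mode <- cfg$denominator_mode %||% "component_sum"
  if (!mode %in% c("component_sum", "fixed_total")) {
    stop_sp("unknown denominator_mode '%s'", mode)
  }
  fixed_total <- as.integer(cfg$fixed_total %||% nrow(items))
  if (mode == "fixed_total" && (is.na(fixed_total) || fixed_total < 1)) {
    stop_sp("fixed_total must be a positive integer in fixed_total mode")
  }
  structure(list(items = items, denominator_mode = mode,
                 fixed_total = fixed_total),
            class = "sp_checklist")
}

#' @export
print.sp_checklist <- function(x, ...) {
  cat(sprintf("<sp_checklist> %d questions + %d examinations (denominator: %s = %d)\n",
              sum(x$items$kind == "question"), sum(x$items$kind == "examination"),
              x$denominator_mode, checklist_denominator(x)))
  invisible(x)
}

checklist_denominator <- function(checklist) {
  if (checklist$denominator_mode == "fixed_total") checklist$fixed_total
  else nrow(checklist$items)
}

#' Load drug classification rules from YAML
#'
#' Maps normalized drug names to the classes `correct` (guideline
#' glucose-lowering therapy), `neutral`, or `harmful` (contraindicated for
#' the case). Names are normalized by case-folding and stripping whitespace;
#' matching is exact after normalization.
#'
#' @param path path to a drugs YAML file with top-level keys `correct`,
#'   `neutral`, `harmful`; defaults to the packaged rules.
#' @return an object of class `sp_drug_rules`: a named character vector
#'   mapping normalized drug name to class.
#' @export
load_drug_rules <- function(path = system.file("extdata", "drugs.yaml",
                                               package = "spaudit")) {
  cfg <- yaml::read_yaml(path)
  classes <- c("correct", "neutral", "harmful")
  rules <- character(0)
  for (cl in classes) {
    nm <- normalize_drug(unlist(cfg[[cl]] %||% character(0)))
    rules[nm] <- cl
  }
  all_names <- normalize_drug(unlist(cfg[classes]))
  dup <- all_names[duplicated(all_names)]
  if (length(dup)) stop_sp("drug listed under more than one class: %s",
                           paste(unique(dup), collapse = ", "))
  structure(rules, class = "sp_drug_rules")
}

normalize_drug <- function(x) tolower(gsub("\\s+", "", x))

#' Construct an explicit treatment-classification policy
#'
#' The audit's "correct treatment" outcome is a judgment call that the
#' original guideline leaves under-specified; this object makes every choice
#' explicit. Under the default policy a visit counts as correctly treated
#' when no harmful drug is dispensed AND either (a) at least one
#' correct-class drug is dispensed, or (b) the provider gives both lifestyle
#' advice and glucose-monitoring advice (first-line non-pharmacological T2D
#' management). Referral is tabulated separately and does not count as
#' treatment by default.
#'
#' @param require_no_harmful if TRUE, any harmful drug vetoes correct
#'   treatment.
#' @param drug_rule `"at_least_one_correct"` or `"all_correct"`: how
#'   dispensed drugs must be classified for the pharmacological route.
#' @param referral_counts_as_treatment if TRUE, a referred visit counts as
#'   correctly treated (subject to the harmful-drug veto).
#' @param advice_counts_as_treatment if TRUE, joint lifestyle +
#'   glucose-monitoring advice counts as correct non-pharmacological
#'   treatment (subject to the veto).
#' @return an object of class `sp_treatment_policy`.
#' @export
treatment_policy <- function(require_no_harmful = TRUE,
                             drug_rule = c("at_least_one_correct", "all_correct"),
                             referral_counts_as_treatment = FALSE,
                             advice_counts_as_treatment = TRUE) {
  drug_rule <- match.arg(drug_rule)
  stopifnot(is.logical(require_no_harmful), length(require_no_harmful) == 1,
            is.logical(referral_counts_as_treatment),
            is.logical(advice_counts_as_treatment))
  structure(list(require_no_harmful = require_no_harmful,
                 drug_rule = drug_rule,
                 referral_counts_as_treatment = referral_counts_as_treatment,
                 advice_counts_as_treatment = advice_counts_as_treatment),
            class = "sp_treatment_policy")
}

#' @export
print.sp_treatment_policy <- function(x, ...) {
  cat("<sp_treatment_policy>\n")
  for (nm in names(x)) cat(sprintf("  %-30s %s\n", nm, x[[nm]]))
  invisible(x)
}
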