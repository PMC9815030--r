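## Canonical CSV schemas. Token-list fields (items_used, drugs) are
## semicolon-separated strings so the tables round-trip losslessly.

schema_interactions <- list(
  interaction_id = "character", provider_id = "character", tier = "character",
  items_used = "character", diagnosis = "character", drugs = "character",
  lifestyle_advice = "logical", glucose_monitoring_advice = "logical",
  referral_to = "character"
)

schema_providers <- list(
  provider_id = "character", tier = "character", age = "numeric",
  male = "logical", bachelor_or_higher = "logical",
  practicing_certificate = "logical", western_medicine_major = "logical",
  income = "numeric", diabetes_patients_2wk = "numeric",
  monthly_diabetes_training = "logical", online_training = "logical"
)

schema_households <- list(
  household_id = "character", first_visit_choice = "character",
  has_diabetes_member = "logical"
)

coerce_schema <- function(df, schema, what) {
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop_sp("%s table is missing column(s): %s", what, paste(missing, collapse = ", "))
  }
  df <- df[names(schema)]
  for (col in names(schema)) {
    raw <- df[[col]]
    df[[col]] <- switch(schema[[col]],
      character = { x <- as.character(raw); x[is.na(x)] <- ""; x },
      numeric = {
        x <- suppressWarnings(as.numeric(raw))
        bad <- which(is.na(x) & !is.na(raw))
        if (length(bad)) stop_sp("%s: non-numeric value in column '%s' at row %d",
                                 what, col, bad[1])
        x
      },
      logical = {
        x <- if (is.logical(raw)) raw else as.logical(toupper(as.character(raw)))
        bad <- which(is.na(x))
        if (length(bad)) stop_sp("%s: non-logical value in column '%s' at row %d",
                                 what, col, bad[1])
        x
      })
  }
  df
}

validate_interactions <- function(df) {
  df <- coerce_schema(df, schema_interactions, "interactions")
  as_tier(df$tier)
  bad <- which(!df$diagnosis %in% c("correct", "incorrect", "missing"))
  if (length(bad)) stop_sp("interactions: bad diagnosis value '%s' at row %d",
                           df$diagnosis[bad[1]], bad[1])
  bad <- which(!df$referral_to %in% c("none", "THC", "CH", "other"))
  if (length(bad)) stop_sp("interactions: bad referral_to value '%s' at row %d",
                           df$referral_to[bad[1]], bad[1])
  bad <- which(df$referral_to == "THC" & df$tier != "VC")
  if (length(bad)) stop_sp("interactions: referral_to=THC only legal for tier VC (row %d, id '%s')",
                           bad[1], df$interaction_id[bad[1]])
  if (anyDuplicated(df$interaction_id)) stop_sp("interactions: duplicate interaction_id")
  invisible(df)
}

validate_providers <- function(df) {
  df <- coerce_schema(df, schema_providers, "providers")
  as_tier(df$tier)
  if (any(df$age < 20 | df$age > 80)) stop_sp("providers: age outside [20, 80]")
  if (any(df$income <= 0)) stop_sp("providers: income must be positive")
  if (any(df$diabetes_patients_2wk < 0)) stop_sp("providers: negative patient count")
  invisible(df)
}

validate_households <- function(df) {
  df <- coerce_schema(df, schema_households, "households")
  bad <- which(!df$first_visit_choice %in% TIERS)
  if (length(bad)) stop_sp("households: bad first_visit_choice '%s' at row %d",
                           df$first_visit_choice[bad[1]], bad[1])
  invisible(df)
}

read_table_checked <- function(path, schema, validator, what) {
  if (!file.exists(path)) stop_sp("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  validator(df)
}

#' Read and write the canonical CSV tables
#'
#' Schema-checked readers and writers for the three tabular inputs:
#' SP-interaction records, provider rosters, and household sorting
#' responses. Reading a written table returns the identical canonical
#' data.frame (lossless round-trip); a missing column or a malformed value
#' raises an error naming the column and row.
#'
#' @param path CSV file path.
#' @param df a data.frame in the corresponding canonical schema.
#' @return the readers return a validated data.frame; the writers return
#'   `path` invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_interactions <- function(path) {
  read_table_checked(path, schema_interactions, validate_interactions, "interactions")
}

#' @rdname table_io
#' @export
read_providers <- function(path) {
  read_table_checked(path, schema_providers, validate_providers, "providers")
}

#' @rdname table_io
#' @export
read_households <- function(path) {
  read_table_checked(path, schema_households, validate_households, "households")
}

#' @rdname table_io
#' @export
write_interactions <- function(df, path) {
  df <- validate_interactions(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
write_providers <- function(df, path) {
  df <- validate_providers(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
write_households <- function(df, path) {
  df <- validate_households(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
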