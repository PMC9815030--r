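#' Define the layout of a tier-comparison table
#'
#' A table spec is an ordered set of rows, each naming a column of the input
#' table, how its cell is rendered (`mean_sd` or `count_pct`) and, for count
#' rows, which denominator applies: the full tier sample (`tier_n`), the
#' non-missing subset (`non_missing`), or the records that dispensed drugs
#' (`dispensing_subset`).
#'
#' @param variable character vector of column names.
#' @param label display label per row (defaults to `variable`).
#' @param cell `"mean_sd"` or `"count_pct"`, recycled.
#' @param denominator `"tier_n"`, `"non_missing"` or `"dispensing_subset"`,
#'   recycled; only meaningful for `count_pct` rows, except that
#'   `dispensing_subset` also restricts `mean_sd` rows (used for the
#'   drugs-per-dispensing-visit row).
#' @return a data.frame of class `sp_table_spec`.
#' @export
tier_table_spec <- function(variable, label = variable,
                            cell = "count_pct", denominator = "tier_n") {
  n <- length(variable)
  spec <- data.frame(variable = variable, label = label,
                     cell = rep_len(cell, n),
                     denominator = rep_len(denominator, n),
                     stringsAsFactors = FALSE)
  bad <- !spec$cell %in% c("mean_sd", "count_pct")
  if (any(bad)) stop_sp("unknown cell type: %s", spec$cell[bad][1])
  bad <- !spec$denominator %in% c("tier_n", "non_missing", "dispensing_subset")
  if (any(bad)) stop_sp("unknown denominator rule: %s", spec$denominator[bad][1])
  class(spec) <- c("sp_table_spec", "data.frame")
  spec
}

#' Published layouts of the two audit tables
#'
#' `provider_table_spec()` is the provider-characteristics table (age,
#' gender, education, certification, major, income, patient volume,
#' training); `quality_table_spec()` is the care-quality table (process
#' counts, diagnosis, treatment, drugs, advice, referral). The
#' `dispensing_subset` denominator applies to the drugs-dispensed and
#' correct-drugs rows only; the harmful-drugs and advice rows use the full
#' tier denominator even though reports label them "(if any)" — an
#' inconsistency of the published layout that is reproduced deliberately.
#'
#' @return an `sp_table_spec`.
#' @export
provider_table_spec <- function() {
  tier_table_spec(
    variable = c("age", "male", "bachelor_or_higher", "practicing_certificate",
                 "western_medicine_major", "income", "diabetes_patients_2wk",
                 "monthly_diabetes_training", "online_training"),
    label = c("Age", "Gender (male)", "Bachelor's degree or higher",
              "Practicing certificate", "Western medicine major",
              "Income (Yuan)", "Diabetes patients in past 2 weeks",
              "Diabetes training monthly or more", "Online training"),
    cell = c("mean_sd", "count_pct", "count_pct", "count_pct", "count_pct",
             "mean_sd", "mean_sd", "count_pct", "count_pct")
  )
}

#' @rdname provider_table_spec
#' @export
quality_table_spec <- function() {
  tier_table_spec(
    variable = c("n_questions", "n_examinations", "nrqe", "anrqe",
                 "correct_diagnosis", "correct_treatment", "n_drugs",
                 "correct_drugs", "harmful_drugs", "lifestyle_advice",
                 "glucose_monitoring_advice", "referred"),
    label = c("Number of recommended questions",
              "Number of recommended examinations",
              "Recommended questions and examinations (NRQE)",
              "Share of recommended items used (ANRQE)",
              "Correct diagnosis", "Correct treatment",
              "Number of drugs dispensed (if any)", "Correct drugs (if any)",
              "Harmful drugs", "Lifestyle guidance",
              "Blood glucose monitoring advice", "Referral"),
    cell = c("mean_sd", "mean_sd", "mean_sd", "mean_sd", "count_pct",
             "count_pct", "mean_sd", "count_pct", "count_pct", "count_pct",
             "count_pct", "count_pct"),
    denominator = c("tier_n", "tier_n", "tier_n", "tier_n", "non_missing",
                    "tier_n", "dispensing_subset", "dispensing_subset",
                    "tier_n", "tier_n", "tier_n", "tier_n")
  )
}

#' Between-tier significance test for one table row
#'
#' Count rows use Pearson's chi-square test of independence on the k-by-2
#' table without continuity correction, switching to Fisher's exact test
#' when any expected cell is below 5. Continuous rows use the one-way ANOVA
#' F-test. Degenerate rows (no variation anywhere) return p = 1 by
#' convention, with a log line.
#'
#' @param values list (one element per tier) of numeric or logical vectors
#'   (`NA`s removed).
#' @param cell `"count_pct"` (logical/0-1 values) or `"mean_sd"`.
#' @return list with `p_value` and `method`.
#' @export
between_tier_test <- function(values, cell = c("count_pct", "mean_sd")) {
  cell <- match.arg(cell)
  values <- lapply(values, function(v) v[!is.na(v)])
  if (length(values) < 2 || any(!vapply(values, length, 1L))) {
    stop_sp("between_tier_test needs >= 2 non-empty groups")
  }
  flat <- unlist(values)
  if (length(unique(flat)) == 1) {
    sp_log("table", "degenerate row (no variation): p = 1 by convention", "WARN")
    return(list(p_value = 1, method = "degenerate"))
  }
  if (cell == "count_pct") {
    k <- vapply(values, function(v) sum(v != 0), 1)
    n <- vapply(values, length, 1)
    tab <- rbind(k, n - k)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      list(p_value = stats::fisher.test(tab)$p.value, method = "fisher")
    } else {
      list(p_value = suppressWarnings(
             stats::chisq.test(tab, correct = FALSE)$p.value),
           method = "chisq")
    }
  } else {
    g <- factor(rep(seq_along(values), lengths(values)))
    fit <- stats::aov(flat ~ g)
    list(p_value = summary(fit)[[1]][1, "Pr(>F)"], method = "anova")
  }
}

#' Build a tier-stratified comparison table
#'
#' Computes, for each spec row and each tier, the group mean and sample SD
#' (n-1 denominator) or the count and percentage under the row's denominator
#' rule, plus a between-tier p-value from [between_tier_test()]. Cell values
#' are carried at full precision; use [format_tier_table()] for the
#' one-decimal display rendering.
#'
#' @param data a scored-interaction or provider data.frame containing a
#'   `tier` column and every `spec` variable.
#' @param spec an [tier_table_spec()] (or one of the packaged layouts).
#' @return a data.frame of class `sp_tier_table`: one row per spec row and
#'   tier with columns `variable`, `label`, `cell`, `tier`, `n` (denominator),
#'   `count`, `pct`, `mean`, `sd`, `p_value`, `method`.
#' @export
build_tier_table <- function(data, spec) {
  stopifnot(inherits(spec, "sp_table_spec"))
  if (!"tier" %in% names(data)) stop_sp("data has no 'tier' column")
  tier <- as_tier(data$tier)
  if (nlevels(droplevels(tier)) < 2) stop_sp("grouping variable needs >= 2 non-empty levels")
  missing_vars <- setdiff(spec$variable, names(data))
  if (length(missing_vars)) stop_sp("data lacks column(s): %s",
                                    paste(missing_vars, collapse = ", "))
  tiers <- levels(droplevels(tier))
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    row <- spec[i, ]
    vals <- lapply(tiers, function(t) {
      v <- data[[row$variable]][tier == t]
      if (row$denominator == "dispensing_subset") {
        if (!"dispensed_any" %in% names(data)) {
          stop_sp("dispensing_subset rule needs a 'dispensed_any' column")
        }
        v <- v[data$dispensed_any[tier == t]]
      }
      v[!is.na(v)]
    })
    names(vals) <- tiers
    test <- between_tier_test(vals, row$cell)
    cells <- lapply(tiers, function(t) {
      v <- vals[[t]]
      n <- length(v)
      if (row$cell == "count_pct") {
        cnt <- sum(v != 0)
        if (n == 0 && cnt > 0) stop_sp("zero denominator with nonzero count in row '%s'", row$variable)
        data.frame(variable = row$variable, label = row$label, cell = row$cell,
                   tier = t, n = n, count = cnt,
                   pct = if (n == 0) 0 else 100 * cnt / n,
                   mean = NA_real_, sd = NA_real_,
                   p_value = test$p_value, method = test$method,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(variable = row$variable, label = row$label, cell = row$cell,
                   tier = t, n = n, count = NA_integer_, pct = NA_real_,
                   mean = mean(v), sd = stats::sd(v),
                   p_value = test$p_value, method = test$method,
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, cells)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sp_tier_table", "data.frame")
  out
}

#' Render a tier table for display
#'
#' Formats each cell as `count (pct%)` or `mean (sd)` with half-up rounding
#' to one decimal, and the p-value column as in published tables
#' (`< 0.001` below that threshold).
#'
#' @param x an `sp_tier_table` from [build_tier_table()].
#' @return a data.frame with one row per variable and one column per tier
#'   plus `p_value`.
#' @export
format_tier_table <- function(x) {
  stopifnot(inherits(x, "sp_tier_table"))
  tiers <- unique(x$tier)
  vars <- unique(x$variable)
  out <- data.frame(variable = vars,
                    label = x$label[match(vars, x$variable)],
                    stringsAsFactors = FALSE)
  for (t in tiers) {
    out[[t]] <- vapply(vars, function(v) {
      r <- x[x$variable == v & x$tier == t, ]
      if (r$cell == "count_pct") {
        sprintf("%d (%.1f%%)", r$count, round_half_up(r$pct, 1))
      } else {
        sprintf("%.1f (%.1f)", round_half_up(r$mean, 1), round_half_up(r$sd, 1))
      }
    }, character(1))
  }
  out$p_value <- vapply(vars, function(v) {
    p <- x$p_value[x$variable == v][1]
    if (p < 0.001) "< 0.001" else sprintf("%.3f", p)
  }, character(1))
  rownames(out) <- NULL
  out
}

#' @export
print.sp_tier_table <- function(x, ...) {
  print(format_tier_table(x), row.names = FALSE)
  invisible(x)
}

#' Write a tier table as CSV and aligned markdown
#'
#' @param x an `sp_tier_table`.
#' @param csv_path,md_path output paths (either may be `NULL` to skip).
#' @return invisibly, the formatted table.
#' @export
write_tier_table <- function(x, csv_path = NULL, md_path = NULL) {
  fmt <- format_tier_table(x)
  if (!is.null(csv_path)) utils::write.csv(fmt, csv_path, row.names = FALSE)
  if (!is.null(md_path)) {
    cols <- names(fmt)
    widths <- pmax(nchar(cols), vapply(fmt, function(c) max(nchar(c), 0), 1))
    pad <- function(v, w) formatC(v, width = w, flag = "-")
    lines <- c(
      paste0("| ", paste(mapply(pad, cols, widths), collapse = " | "), " |"),
      paste0("|", paste(vapply(widths, function(w) strrep("-", w + 2), ""), collapse = "|"), "|"),
      vapply(seq_len(nrow(fmt)), function(i) {
        paste0("| ", paste(mapply(pad, unlist(fmt[i, ]), widths), collapse = " | "), " |")
      }, character(1))
    )
    writeLines(lines, md_path)
  }
  invisible(fmt)
}
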