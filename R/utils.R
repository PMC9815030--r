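#' Round half away from zero
#'
#' Display rounding used throughout the package for table cells. Unlike
#' [base::round()] (round-half-to-even), ties go up, matching how field
#' reports print one-decimal percentages and means.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(0.05, 1)  # 0.1, where round(0.05, 1) gives 0
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit a machine-parsable log line
#'
#' Writes `timestamp | stage | level | message` to the message stream.
#' Suppressed when `options(spaudit.quiet = TRUE)`.
#'
#' @param stage short pipeline-stage token (e.g. "score", "cascade").
#' @param msg message text.
#' @param level one of "INFO", "WARN".
#' @return invisibly, the formatted line.
#' @export
sp_log <- function(stage, msg, level = "INFO") {
  line <- sprintf("%s | %s | %s | %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, level, msg)
  if (!isTRUE(getOption("spaudit.quiet", FALSE))) message(line)
  invisible(line)
}

## stable hash of an R object (used to stamp config provenance in artifacts)
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(x), collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

stop_sp <- function(...) stop(sprintf(...), call. = FALSE)

## split a ";"-joined token field into a character vector (empty -> character(0))
split_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

join_tokens <- function(x) paste(x, collapse = ";")

TIERS <- c("VC", "THC", "CH")

as_tier <- function(x) {
  x <- as.character(x)
  bad <- !x %in% TIERS
  if (any(bad)) stop_sp("unknown tier value(s): %s", paste(unique(x[bad]), collapse = ", "))
  factor(x, levels = TIERS)
}

## run code with a locally-seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
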