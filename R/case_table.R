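# Case metadata: one row per animal, with group membership, age, sex and
# semiquantitative extracellular amyloid-beta / pre-tangle tau scores from
# the original neuropathology grading ("+" mild, "++" moderate, "+++"
# severe, "-" none; sex "?" = unknown).

SCORE_LEVELS <- c("none", "mild", "moderate", "severe")
GROUP_LEVELS <- c("Young", "Aged", "CDS")
SEX_LEVELS <- c("F", "M", "Unknown")

score_from_token <- function(tok, row, col) {
  tok <- trimws(tok)
  # U+2212 minus sign appears in some exports alongside ASCII "-"
  tok[tok %in% c("-", "−", "")] <- "none"
  tok[tok == "+"] <- "mild"
  tok[tok == "++"] <- "moderate"
  tok[tok == "+++"] <- "severe"
  bad <- !(tok %in% SCORE_LEVELS)
  if (any(bad))
    stop(sprintf("row %d: unknown %s token '%s'", row[bad][1], col,
                 tok[bad][1]), call. = FALSE)
  factor(tok, levels = SCORE_LEVELS, ordered = TRUE)
}

#' Parse a case-metadata table
#'
#' Reads a delimited text table with columns `case_id`, `group`,
#' `age_years`, `sex`, `ab_score`, `tau_score`. Group must be one of
#' `Young`, `Aged`, `CDS`; sex tokens `F`, `M` and `?` (mapped to
#' `Unknown`); pathology scores use the semiquantitative notation
#' `-`/`+`/`++`/`+++` mapped onto the ordered levels
#' `none < mild < moderate < severe`.
#'
#' @param path path to a tab- or comma-separated file (delimiter inferred
#'   from the header line).
#' @return a `data.frame` of class `case_table`, one row per case, with
#'   `group`/`sex` as factors and scores as ordered factors. Empty file
#'   (header only) gives zero rows.
#' @export
parse_case_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE,
                          check.names = TRUE, quote = "\"",
                          comment.char = "")
  need <- c("case_id", "group", "age_years", "sex", "ab_score", "tau_score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("case table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  n <- nrow(df)
  rows <- seq_len(n)
  if (n == 0L) {
    out <- data.frame(case_id = character(0), group = factor(character(0), GROUP_LEVELS),
                      age_years = numeric(0), sex = factor(character(0), SEX_LEVELS),
                      ab_score = factor(character(0), SCORE_LEVELS, ordered = TRUE),
                      tau_score = factor(character(0), SCORE_LEVELS, ordered = TRUE))
    class(out) <- c("case_table", "data.frame")
    return(out)
  }
  grp <- trimws(df$group)
  bad <- !(grp %in% GROUP_LEVELS)
  if (any(bad))
    stop(sprintf("row %d: unknown group token '%s'", rows[bad][1],
                 grp[bad][1]), call. = FALSE)
  sex <- trimws(df$sex)
  sex[sex == "?"] <- "Unknown"
  bad <- !(sex %in% SEX_LEVELS)
  if (any(bad))
    stop(sprintf("row %d: unknown sex token '%s'", rows[bad][1],
                 sex[bad][1]), call. = FALSE)
  age <- suppressWarnings(as.numeric(df$age_years))
  bad <- is.na(age) | age <= 0
  if (any(bad))
    stop(sprintf("row %d: age_years must be a positive number, got '%s'",
                 rows[bad][1], df$age_years[bad][1]), call. = FALSE)
  out <- data.frame(
    case_id = df$case_id,
    group = factor(grp, levels = GROUP_LEVELS),
    age_years = age,
    sex = factor(sex, levels = SEX_LEVELS),
    ab_score = score_from_token(df$ab_score, rows, "ab_score"),
    tau_score = score_from_token(df$tau_score, rows, "tau_score"),
    stringsAsFactors = FALSE)
  class(out) <- c("case_table", "data.frame")
  out
}

#' Serialize a case table back to canonical delimited text
#'
#' Inverse of [parse_case_table()] on its canonical form: scores rendered as
#' `-`/`+`/`++`/`+++`, unknown sex as `?`.
#'
#' @param records a `case_table` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
format_case_table <- function(records, path) {
  tok <- c(none = "-", mild = "+", moderate = "++", severe = "+++")
  out <- data.frame(
    case_id = records$case_id,
    group = as.character(records$group),
    age_years = records$age_years,
    sex = ifelse(as.character(records$sex) == "Unknown", "?",
                 as.character(records$sex)),
    ab_score = tok[as.character(records$ab_score)],
    tau_score = tok[as.character(records$tau_score)])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Path to the packaged 25-case cohort fixture
#'
#' The case-metadata table shipped with the package: 25 cats in three groups
#' (7 young, 10 aged, 8 with cognitive dysfunction syndrome) with ages,
#' sexes and semiquantitative amyloid/tau scores.
#'
#' @return file path of the installed fixture.
#' @export
case_table_fixture <- function() {
  system.file("extdata", "case_table.tsv", package = "gliaquant",
              mustWork = TRUE)
}
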