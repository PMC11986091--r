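#' Read gold annotations from a TSV file
#'
#' Gold annotations record, per entry, the tokens expected to be
#' transformed and their targets. The `expected` column holds either a full
#' ATC code ("ATC code expected" tokens), `NAME_ONLY` for recognized
#' medication names without a code, or `STUDY:<term>` / `INFO:<term>` for
#' side-channel terms.
#'
#' @param path Path to a UTF-8 TSV with columns `entry_id`, `token`,
#'   `expected` (extra columns are preserved).
#' @return A data.frame of gold annotations.
#' @export
load_gold <- function(path) {
  df <- read_tsv_checked(path, c("entry_id", "token", "expected"))
  if (nrow(df) == 0L) stop("gold file has no annotation rows: ", path)
  df
}

#' Write gold annotations to a TSV file
#' @param gold A data.frame with columns `entry_id`, `token`, `expected`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  stopifnot(all(c("entry_id", "token", "expected") %in% names(gold)))
  write_tsv_atomic(gold, path)
}

gold_expected_codes <- function(gold_rows) {
  exp <- gold_rows$expected
  is_code <- !(exp == "NAME_ONLY" | startsWith(exp, "STUDY:") |
                 startsWith(exp, "INFO:"))
  gold_rows[is_code, , drop = FALSE]
}

#' Classify one standardized entry against its gold annotation
#'
#' Implements the three-way outcome taxonomy. A gold token expecting an ATC
#' code is *successfully transformed* iff its code appears in the
#' `AntineoplasticMedication` or `AdditionalMedication` column. An entry is
#' an *error in transformation* iff at least one expected transformation is
#' missing. An entry is *no useful information* iff it was not an error and
#' its output provides neither an ATC code nor any content in the
#' `Medication`, `Study` or `Info` columns. All remaining entries are
#' *successfully transformed*.
#'
#' @param record A `standardized_record` (see [assemble_record()]).
#' @param gold_rows The gold annotation rows of the same entry.
#' @return A list with the entry bucket, per-token counts, the missed
#'   tokens, and whether the entry carried additional (Study/Info)
#'   information.
#' @export
classify_entry <- function(record, gold_rows) {
  stopifnot(inherits(record, "standardized_record"))
  if (nrow(gold_rows) > 0L &&
      any(gold_rows$entry_id != record$entry_id)) {
    stop("gold/record entry_id mismatch: record '", record$entry_id,
         "' vs gold '",
         paste(unique(gold_rows$entry_id), collapse = "', '"), "'")
  }
  expected <- gold_expected_codes(gold_rows)
  out_codes <- c(record$antineoplastic_medication,
                 record$additional_medication)
  ok <- expected$expected %in% out_codes
  has_content <- length(out_codes) > 0L ||
    length(record$medication) > 0L ||
    length(record$study) > 0L ||
    length(record$info) > 0L
  bucket <- if (any(!ok)) {
    "error_in_transformation"
  } else if (!has_content) {
    "no_useful_information"
  } else {
    "successfully_transformed"
  }
  list(entry_id = record$entry_id,
       bucket = bucket,
       n_expected_tokens = nrow(expected),
       n_token_success = sum(ok),
       n_token_fail = sum(!ok),
       failed_tokens = expected$token[!ok],
       has_additional_info = length(record$study) > 0L ||
         length(record$info) > 0L)
}

pct1 <- function(num, den) round(100 * num / den, 1)

#' Aggregate per-entry outcomes into evaluation totals and rates
#'
#' Produces the two-level summary: entry-level counts over the three
#' buckets, and token-level counts where the denominator is the number of
#' "ATC code expected" tokens plus one token for each
#' no-useful-information entry (each such entry counts as one token).
#' Rates are percentages rounded to one decimal place; with zero entries
#' the rates are `NULL`.
#'
#' @param outcomes List of per-entry outcomes from [classify_entry()].
#' @return An object of class `atc_evaluation` with elements
#'   `entry_counts`, `token_counts`, `n_entries_with_additional_info` and
#'   `rates`.
#' @export
summarize_outcomes <- function(outcomes) {
  buckets <- vapply(outcomes, `[[`, character(1), "bucket")
  n_entries <- length(outcomes)
  n_no_useful <- sum(buckets == "no_useful_information")
  entry_counts <- list(
    total = n_entries,
    successfully_transformed = sum(buckets == "successfully_transformed"),
    error_in_transformation = sum(buckets == "error_in_transformation"),
    no_useful_information = n_no_useful
  )
  n_success <- sum(vapply(outcomes, `[[`, integer(1), "n_token_success"))
  n_fail <- sum(vapply(outcomes, `[[`, integer(1), "n_token_fail"))
  token_counts <- list(
    total = n_success + n_fail + n_no_useful,
    successfully_transformed = n_success,
    error_in_transformation = n_fail,
    no_useful_information = n_no_useful
  )
  rates <- if (n_entries == 0L) NULL else list(
    entry_success_pct = pct1(entry_counts$successfully_transformed, n_entries),
    entry_error_pct = pct1(entry_counts$error_in_transformation, n_entries),
    entry_no_useful_pct = pct1(n_no_useful, n_entries),
    token_success_pct = if (token_counts$total > 0L)
      pct1(n_success, token_counts$total) else NULL,
    token_error_pct = if (token_counts$total > 0L)
      pct1(n_fail, token_counts$total) else NULL,
    token_no_useful_pct = if (token_counts$total > 0L)
      pct1(n_no_useful, token_counts$total) else NULL,
    additional_info_pct = pct1(
      sum(vapply(outcomes, `[[`, logical(1), "has_additional_info")),
      n_entries)
  )
  structure(
    list(entry_counts = entry_counts,
         token_counts = token_counts,
         n_entries_with_additional_info = sum(
           vapply(outcomes, `[[`, logical(1), "has_additional_info")),
         rates = rates,
         outcomes = outcomes),
    class = "atc_evaluation"
  )
}

#' Evaluate a standardized table against gold annotations
#'
#' Matches each per-entry record of a [standardize()] result with its gold
#' annotation rows by `entry_id`, classifies every entry
#' ([classify_entry()]) and aggregates ([summarize_outcomes()]). Gold rows
#' whose `entry_id` matches no record are a hard error (orphans are
#' listed); records without gold rows are treated as expecting nothing.
#'
#' @param result A table returned by [standardize()] (or a list of
#'   `standardized_record` objects).
#' @param gold A gold annotation data.frame (see [load_gold()]).
#' @return An `atc_evaluation` object.
#' @export
evaluate_standardization <- function(result, gold) {
  records <- if (is.data.frame(result)) standardized_records(result) else result
  ids <- vapply(records, `[[`, character(1), "entry_id")
  orphans <- setdiff(unique(gold$entry_id), ids)
  if (length(orphans) > 0L) {
    stop("gold annotations reference unknown entry_id(s): ",
         paste(utils::head(orphans, 10L), collapse = ", "),
         if (length(orphans) > 10L) " ...")
  }
  gold_by_id <- split(gold, gold$entry_id)
  outcomes <- lapply(records, function(rec) {
    rows <- gold_by_id[[rec$entry_id]]
    if (is.null(rows)) rows <- gold[0L, , drop = FALSE]
    classify_entry(rec, rows)
  })
  summarize_outcomes(outcomes)
}

eval_table_lines <- function(x) {
  fmt <- function(n, d) sprintf("%d (%s%%)", n,
                                formatC(100 * n / d, format = "f", digits = 1))
  ec <- x$entry_counts; tc <- x$token_counts
  rows <- rbind(
    c("Data entries", fmt(ec$total, ec$total),
      fmt(ec$successfully_transformed, ec$total),
      fmt(ec$error_in_transformation, ec$total),
      fmt(ec$no_useful_information, ec$total)),
    c("Tokens", fmt(tc$total, tc$total),
      fmt(tc$successfully_transformed, tc$total),
      fmt(tc$error_in_transformation, tc$total),
      fmt(tc$no_useful_information, tc$total))
  )
  header <- c("", "Overall", "Successfully transformed",
              "Failed to transform", "No useful information")
  m <- rbind(header, rows)
  widths <- apply(nchar(m), 2, max)
  lines <- apply(m, 1, function(r)
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "))
  c(lines,
    sprintf("Entries with additional information (Study/Info): %d (%s%%)",
            x$n_entries_with_additional_info,
            formatC(100 * x$n_entries_with_additional_info /
                      max(ec$total, 1L), format = "f", digits = 1)))
}

#' @export
print.atc_evaluation <- function(x, ...) {
  if (x$entry_counts$total == 0L) {
    cat("<atc_evaluation> empty (no entries)\n")
    return(invisible(x))
  }
  cat(eval_table_lines(x), sep = "\n")
  invisible(x)
}

#' Write an evaluation report as JSON and text
#'
#' The JSON file carries the counts and rates; the text file shows the
#' two-level, three-bucket table (entry level and token level) plus the
#' additional-information extraction count. Re-running on identical inputs
#' reproduces both files byte-identically.
#'
#' @param x An `atc_evaluation`.
#' @param json_path Output path for the JSON report (`NULL` to skip).
#' @param text_path Output path for the text table (`NULL` to skip).
#' @return Invisibly, the list of written paths.
#' @export
write_evaluation_report <- function(x, json_path = NULL, text_path = NULL) {
  stopifnot(inherits(x, "atc_evaluation"))
  paths <- list()
  if (!is.null(json_path)) {
    payload <- list(entry_counts = x$entry_counts,
                    token_counts = x$token_counts,
                    n_entries_with_additional_info =
                      x$n_entries_with_additional_info,
                    rates = x$rates)
    write_lines_atomic(
      jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA),
      json_path)
    paths$json <- json_path
  }
  if (!is.null(text_path)) {
    write_lines_atomic(eval_table_lines(x), text_path)
    paths$text <- text_path
  }
  invisible(paths)
}
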