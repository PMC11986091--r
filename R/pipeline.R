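#' Expand regimens and abbreviations (transformation step 1)
#'
#' Matches the preprocessed tokens of one entry against the RAD. Multi-token
#' phrase keys are tried longest-first at each position, then single tokens
#' (including glob keys). A matched `EXPANSION` key is replaced in place by
#' its substance-name tokens in dictionary payload order; `STUDY`, `INFO`
#' and `MEDICATION` keys are removed from the token stream and their display
#' terms routed to the corresponding side channel. Unmatched tokens pass
#' through unchanged.
#'
#' After substitution, exact duplicate tokens within the entry are
#' deduplicated keeping the first occurrence, so a single medication entry
#' like "5-FU (Fluorouracil)" — whose two tokens both expand or match to
#' Fluorouracil — yields that substance once.
#'
#' @param tokens Character vector of preprocessed uppercase tokens.
#' @param rad A `rad_dictionary`.
#' @return A list with elements `tokens` (post-expansion, deduplicated),
#'   `study`, `info` and `medication` (character vectors of routed display
#'   terms, deduplicated in match order).
#' @export
rad_stage <- function(tokens, rad) {
  stopifnot(inherits(rad, "rad_dictionary"))
  out <- character(0)
  study <- character(0); info <- character(0); medication <- character(0)
  max_k <- rad_max_key_tokens(rad)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    hit <- NULL; hit_len <- 0L
    for (k in seq(min(max_k, n - i + 1L), 1L)) {
      phrase <- paste(tokens[i:(i + k - 1L)], collapse = " ")
      e <- rad_lookup(phrase, rad)
      if (!is.null(e)) { hit <- e; hit_len <- k; break }
    }
    if (is.null(hit)) {
      out <- c(out, tokens[i])
      i <- i + 1L
    } else {
      switch(hit$kind,
        EXPANSION  = { out <- c(out, hit$tokens) },
        STUDY      = { study <- c(study, hit$payload) },
        INFO       = { info <- c(info, hit$payload) },
        MEDICATION = { medication <- c(medication, hit$payload) }
      )
      i <- i + hit_len
    }
  }
  list(tokens = unique(out),
       study = unique(study),
       info = unique(info),
       medication = unique(medication))
}

#' Look up ATC codes for post-RAD tokens (transformation step 2)
#'
#' Each token receives its full candidate code set from the ATC dictionary
#' (union over exact and glob matches). Tokens with no match are routed as
#' `RESIDUAL`; they are kept for dictionary refinement and evaluation but
#' never exported to the output table.
#'
#' @param tokens Character vector of post-RAD tokens.
#' @param atc An `atc_dictionary`.
#' @return A list of token matches, each a list with elements `token`,
#'   `codes` (sorted character vector, possibly empty) and `routing`
#'   (`"ATC"` or `"RESIDUAL"`).
#' @export
atc_stage <- function(tokens, atc) {
  stopifnot(inherits(atc, "atc_dictionary"))
  lapply(tokens, function(tk) {
    codes <- atc_lookup(tk, atc)
    list(token = tk, codes = codes,
         routing = if (length(codes) > 0L) "ATC" else "RESIDUAL")
  })
}

#' Resolve a multi-code conflict to a single ATC code
#'
#' A substance listed under several ATC codes is reduced to one: if any
#' candidate starts with `L` (antineoplastic and immunomodulating agents),
#' the alphabetically first `L` code is retained — the tool's primary focus
#' is cancer therapy. Otherwise the alphabetically first code overall is
#' selected.
#'
#' @param codes Non-empty character vector of candidate codes.
#' @return A single code string.
#' @examples
#' resolve_multi_code(c("L01BA01", "M01CX0")) # Methotrexate rule
#' resolve_multi_code(c("N02BE01", "A02BC01"))
#' @export
resolve_multi_code <- function(codes) {
  codes <- unique(as.character(codes))
  if (length(codes) == 0L) stop("cannot resolve an empty code set")
  l_codes <- codes[is_antineoplastic(codes)]
  if (length(l_codes) > 0L) return(min(l_codes))
  min(codes)
}

#' Assemble the standardized record of one entry
#'
#' Applies per-token multi-code resolution, then distributes the results:
#' resolved codes starting with `L` go to `antineoplastic_medication`, all
#' other resolved codes to `additional_medication` (both deduplicated and
#' sorted alphabetically); RAD-routed terms fill `medication` (sorted),
#' `study` and `info` (match order); unmatched tokens are retained as
#' `residual_tokens` for evaluation only.
#'
#' @param original_text The verbatim input string, echoed unchanged.
#' @param matches Token matches from [atc_stage()].
#' @param routed Side channels from [rad_stage()] (elements `study`, `info`,
#'   `medication`).
#' @param entry_id Opaque row identifier.
#' @return A list of class `standardized_record`.
#' @export
assemble_record <- function(original_text, matches,
                            routed = list(study = character(0),
                                          info = character(0),
                                          medication = character(0)),
                            entry_id = NA_character_) {
  resolved <- vapply(
    Filter(function(m) m$routing == "ATC", matches),
    function(m) resolve_multi_code(m$codes), character(1)
  )
  residual <- vapply(
    Filter(function(m) m$routing == "RESIDUAL", matches),
    function(m) m$token, character(1)
  )
  structure(
    list(entry_id = as.character(entry_id),
         original_text = original_text,
         antineoplastic_medication = sort(unique(resolved[is_antineoplastic(resolved)])),
         additional_medication = sort(unique(resolved[!is_antineoplastic(resolved)])),
         medication = sort(unique(routed$medication)),
         study = unique(routed$study),
         info = unique(routed$info),
         residual_tokens = residual),
    class = "standardized_record"
  )
}

#' @export
print.standardized_record <- function(x, ...) {
  cat("<standardized_record>", x$entry_id, "\n",
      " text:          ", x$original_text, "\n",
      " antineoplastic:", paste(x$antineoplastic_medication, collapse = ", "), "\n",
      " additional:    ", paste(x$additional_medication, collapse = ", "), "\n",
      " medication:    ", paste(x$medication, collapse = ", "), "\n",
      " study:         ", paste(x$study, collapse = ", "), "\n",
      " info:          ", paste(x$info, collapse = ", "), "\n",
      " residual:      ", paste(x$residual_tokens, collapse = ", "), "\n")
  invisible(x)
}

standardize_one <- function(text, atc, rad, stop, protected, entry_id) {
  tokens <- preprocess_entry(text, stop, protected)
  routed <- rad_stage(tokens, rad)
  matches <- atc_stage(routed$tokens, atc)
  assemble_record(text, matches, routed, entry_id = entry_id)
}

#' The five derived output column names
#' @return Character vector of length 5.
#' @export
OUTPUT_COLUMNS <- c("AntineoplasticMedication", "AdditionalMedication",
                    "Medication", "Study", "Info")

#' Standardize a table of free-text medication entries
#'
#' Runs the full pipeline — transliteration, tokenization, stoplist
#' filtering, RAD expansion with deduplication, ATC lookup, multi-code
#' resolution — over every row and assembles the output table: the original
#' entry column (byte-identical) plus the five derived columns
#' `AntineoplasticMedication`, `AdditionalMedication`, `Medication`,
#' `Study` and `Info`. Multi-value cells are joined with `joiner`; empty
#' cells are empty strings. The run is deterministic: identical inputs,
#' dictionaries and configuration give identical output.
#'
#' Per-row problems never abort the run; they are collected in the
#' `"log"` attribute. The full per-entry records (including residual
#' tokens, which are not exported) are available in the `"records"`
#' attribute for evaluation and dictionary refinement.
#'
#' @param entries A character vector of entries, or a data.frame whose
#'   `column` (default: first) holds the free text.
#' @param atc An `atc_dictionary`.
#' @param rad A `rad_dictionary`.
#' @param stop An `atc_stoplist` (default [default_stoplist()]).
#' @param column For data.frame input, the name of the text column.
#' @param joiner String joining multiple values within one cell.
#' @return A data.frame with one row per input row, the original column
#'   first, then the five derived columns; attributes `"records"` (list of
#'   `standardized_record`) and `"log"` (character vector of messages).
#' @examples
#' atc <- atc_dictionary("L01XA01", "Cisplatin")
#' rad <- rad_dictionary("Studie", "STUDY", "Studie")
#' standardize(c("Cisplatin 100mg Studie"), atc, rad)
#' @export
standardize <- function(entries, atc, rad, stop = default_stoplist(),
                        column = NULL, joiner = ", ") {
  stopifnot(inherits(atc, "atc_dictionary"), inherits(rad, "rad_dictionary"),
            nzchar(joiner))
  if (is.data.frame(entries)) {
    if (is.null(column)) column <- attr(entries, "entry_column")
    if (is.null(column)) column <- names(entries)[1L]
    if (!column %in% names(entries)) {
      stop("input column '", column, "' not found; available columns: ",
           paste(names(entries), collapse = ", "))
    }
    texts <- as.character(entries[[column]])
    ids <- rownames(entries)
  } else {
    texts <- as.character(entries)
    if (is.null(column)) column <- "Medication_freetext"
    ids <- NULL
  }
  if (is.null(ids)) ids <- as.character(seq_along(texts))

  log <- character(0)
  conflicts <- check_stoplist(stop, atc, rad)
  if (length(conflicts) > 0L) {
    log <- c(log, paste0("stoplist matches protected dictionary key(s): ",
                         paste(conflicts, collapse = ", ")))
  }
  log <- c(log, atc$warnings, rad$warnings)

  protected <- protected_keys(atc, rad)
  records <- vector("list", length(texts))
  for (i in seq_along(texts)) {
    rec <- tryCatch(
      standardize_one(texts[i], atc, rad, stop, protected, ids[i]),
      error = function(e) {
        structure(list(entry_id = ids[i], original_text = texts[i],
                       antineoplastic_medication = character(0),
                       additional_medication = character(0),
                       medication = character(0), study = character(0),
                       info = character(0), residual_tokens = character(0),
                       failed = conditionMessage(e)),
                  class = "standardized_record")
      })
    if (!is.null(rec$failed)) {
      log <- c(log, paste0("entry ", ids[i], " failed: ", rec$failed))
    }
    if (length(rec$residual_tokens) > 0L) {
      log <- c(log, paste0("entry ", ids[i], " residual token(s): ",
                           paste(rec$residual_tokens, collapse = ", ")))
    }
    records[[i]] <- rec
  }

  join <- function(field) vapply(records, function(r)
    paste(r[[field]], collapse = joiner), character(1))
  out <- data.frame(texts,
                    AntineoplasticMedication = join("antineoplastic_medication"),
                    AdditionalMedication = join("additional_medication"),
                    Medication = join("medication"),
                    Study = join("study"),
                    Info = join("info"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[1L] <- column
  attr(out, "records") <- records
  attr(out, "log") <- log
  out
}

#' Extract the per-entry records of a standardized table
#'
#' @param result A table returned by [standardize()].
#' @return List of `standardized_record` objects.
#' @export
standardized_records <- function(result) {
  recs <- attr(result, "records")
  if (is.null(recs)) stop("no 'records' attribute; was this produced by standardize()?")
  recs
}
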