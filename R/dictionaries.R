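#' The fourteen first-level ATC anatomical group letters
#'
#' First level of the WHO ATC classification: one letter per anatomical
#' main group (A alimentary tract, B blood, C cardiovascular, ..., L
#' antineoplastic and immunomodulating agents, ..., V various).
#'
#' @format Character vector of length 14.
#' @export
ATC_ANATOMICAL_LETTERS <- c("A", "B", "C", "D", "G", "H", "J",
                            "L", "M", "N", "P", "R", "S", "V")

# character-length of a code at each of the five hierarchical levels
ATC_LEVEL_NCHAR <- c(1L, 3L, 4L, 5L, 7L)

ATC_LEVEL_REGEX <- c(
  "^[A-Z]$",
  "^[A-Z][0-9]{2}$",
  "^[A-Z][0-9]{2}[A-Z]$",
  "^[A-Z][0-9]{2}[A-Z]{2}$",
  "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
)

#' Validate ATC codes and derive their hierarchical level
#'
#' A full (level-5) ATC code has seven characters: one letter, two digits,
#' two letters, two digits (e.g. `L01BA01`). Shorter prefixes are valid at
#' levels 1–4 with lengths 1, 3, 4 and 5 characters. The first character
#' must be one of the fourteen anatomical group letters
#' ([ATC_ANATOMICAL_LETTERS]).
#'
#' @param codes Character vector of candidate codes (uppercase).
#' @return A data.frame with columns `code`, `valid` (logical) and `level`
#'   (integer 1–5, `NA` when invalid).
#' @examples
#' validate_atc_code(c("L01BA01", "M01CX0", "Z99XX99"))
#' @export
validate_atc_code <- function(codes) {
  codes <- as.character(codes)
  n <- length(codes)
  level <- rep(NA_integer_, n)
  for (lv in 1:5) {
    sel <- !is.na(codes) & nchar(codes) == ATC_LEVEL_NCHAR[lv] &
      grepl(ATC_LEVEL_REGEX[lv], codes)
    level[sel] <- lv
  }
  ok_letter <- substr(codes, 1L, 1L) %in% ATC_ANATOMICAL_LETTERS
  level[!ok_letter] <- NA_integer_
  data.frame(code = codes, valid = !is.na(level), level = level,
             stringsAsFactors = FALSE)
}

#' Hierarchical prefixes of a full ATC code
#'
#' Returns the five prefixes of a level-5 code, one per hierarchical level
#' (e.g. `L01BA01` yields `L`, `L01`, `L01B`, `L01BA`, `L01BA01`).
#'
#' @param code A single valid level-5 ATC code.
#' @return Character vector of length 5.
#' @export
atc_prefixes <- function(code) {
  v <- validate_atc_code(code)
  if (!isTRUE(v$valid) || v$level != 5L) {
    stop("not a valid level-5 ATC code: ", code)
  }
  substring(code, 1L, ATC_LEVEL_NCHAR)
}

#' Is a code antineoplastic (ATC chapter L)?
#'
#' @param codes Character vector of codes.
#' @return Logical vector: `TRUE` where the first character is `L`.
#' @export
is_antineoplastic <- function(codes) {
  startsWith(as.character(codes), "L")
}

#' Normalize a dictionary key or surface pattern
#'
#' Applies the same normalization as input preprocessing: transliteration,
#' hyphen deletion (fusing the flanks), removal of punctuation/symbols and
#' uppercasing. Multi-token phrases keep single spaces between words; the
#' glob wildcard `*` is preserved.
#'
#' @param x Character vector of keys or patterns.
#' @return Normalized character vector.
#' @export
normalize_key <- function(x) {
  x <- transliterate_german(as.character(x))
  x <- gsub("-", "", x, fixed = TRUE)
  x <- toupper(gsub("[^A-Za-z0-9*[:space:]]+", " ", x))
  gsub("[[:space:]]+", " ", trimws(x))
}

glob_to_regex <- function(pattern) {
  # normalized patterns only contain [A-Z0-9* ]; escape anything else
  rx <- gsub("([^A-Za-z0-9* ])", "\\\\\\1", pattern)
  paste0("^", gsub("*", "[A-Z0-9]*", rx, fixed = TRUE), "$")
}

#' Match a token against a dictionary pattern
#'
#' Patterns without the wildcard `*` match by exact equality; `*` matches
#' zero or more characters from `[A-Z0-9]`. Both sides are expected in
#' normalized (uppercase, hyphen-free) form.
#'
#' @param token Character vector of tokens.
#' @param pattern A single pattern.
#' @return Logical vector, one element per token.
#' @examples
#' match_pattern("MITOMYCIN", "MITOMYC*")
#' @export
match_pattern <- function(token, pattern) {
  stopifnot(length(pattern) == 1L)
  if (!grepl("*", pattern, fixed = TRUE)) {
    return(token == pattern)
  }
  grepl(glob_to_regex(pattern), token)
}

# ---- ATC dictionary ---------------------------------------------------------

new_atc_dictionary <- function(entries, name_of, warnings = character(0)) {
  structure(
    list(entries = entries,
         name_of = name_of,
         glob = names(entries)[grepl("*", names(entries), fixed = TRUE)],
         warnings = warnings),
    class = "atc_dictionary"
  )
}

#' Build an ATC dictionary from vectors
#'
#' Maps surface patterns (normalized through the same rules as input text)
#' to sets of ATC codes. One pattern may map to several codes — the
#' classical example is a substance listed both under its antineoplastic
#' chapter-L code and under another chapter. Structurally invalid codes are
#' kept with a warning by default (real registries contain pseudo-codes);
#' `strict = TRUE` turns the warning into an error.
#'
#' @param code Character vector of ATC codes.
#' @param name Character vector of canonical display names, parallel to
#'   `code`.
#' @param pattern Optional character vector of surface patterns; empty or
#'   `NA` entries default to the normalized name. May contain the glob
#'   wildcard `*`.
#' @param strict Error (rather than warn) on structurally invalid codes.
#' @return An object of class `atc_dictionary`.
#' @examples
#' atc_dictionary(code = c("L01BA01", "M01CX0"),
#'                name = c("Methotrexat", "Methotrexat"))
#' @export
atc_dictionary <- function(code, name, pattern = NULL, strict = FALSE) {
  code <- toupper(trimws(as.character(code)))
  name <- trimws(as.character(name))
  stopifnot(length(code) == length(name))
  if (is.null(pattern)) pattern <- rep("", length(code))
  pattern <- as.character(pattern)
  pattern[is.na(pattern) | !nzchar(trimws(pattern))] <-
    name[is.na(pattern) | !nzchar(trimws(pattern))]
  pattern <- normalize_key(pattern)

  warnings <- character(0)
  v <- validate_atc_code(code)
  bad <- unique(code[!v$valid])
  if (length(bad) > 0L) {
    msg <- paste0("structurally invalid ATC code(s) kept: ",
                  paste(bad, collapse = ", "))
    if (strict) stop(msg)
    warnings <- c(warnings, msg)
    warning(msg, call. = FALSE)
  }

  keep <- !duplicated(paste(pattern, code, sep = "\r"))
  pattern <- pattern[keep]; code <- code[keep]; name <- name[keep]

  entries <- lapply(split(code, pattern), function(x) sort(unique(x)))
  name_of <- stats::setNames(name, code)
  name_of <- name_of[!duplicated(names(name_of))]
  new_atc_dictionary(entries[order(names(entries))], name_of, warnings)
}

#' @export
print.atc_dictionary <- function(x, ...) {
  cat("<atc_dictionary>", length(x$entries), "patterns,",
      length(x$name_of), "codes",
      if (length(x$glob)) paste0("(", length(x$glob), " glob)"), "\n")
  invisible(x)
}

#' Read an ATC dictionary from a TSV file
#'
#' Expects tab-separated columns `code`, `name` and optionally `pattern`
#' (defaulting to the normalized name); `#` starts a comment line.
#' Patterns are normalized with the same transliterate/uppercase/hyphen
#' rules applied to input text, so matching is symmetric.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param strict Error on structurally invalid codes instead of warning.
#' @return An `atc_dictionary`; load warnings are kept in `$warnings`.
#' @export
load_atc_dictionary <- function(path, strict = FALSE) {
  df <- read_tsv_checked(path, c("code", "name"))
  if (!"pattern" %in% names(df)) df$pattern <- ""
  if (nrow(df) == 0L) {
    return(new_atc_dictionary(list(), stats::setNames(character(0), character(0))))
  }
  suppressWarnings(
    atc_dictionary(df$code, df$name, df$pattern, strict = strict)
  )
}

#' Write an ATC dictionary to a TSV file
#'
#' Inverse of [load_atc_dictionary()]; loading the written file yields an
#' identical dictionary.
#'
#' @param x An `atc_dictionary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atc_dictionary <- function(x, path) {
  stopifnot(inherits(x, "atc_dictionary"))
  rows <- do.call(rbind, c(list(
    data.frame(code = character(0), name = character(0),
               pattern = character(0), stringsAsFactors = FALSE)),
    lapply(names(x$entries), function(p) {
      codes <- x$entries[[p]]
      data.frame(code = codes,
                 name = unname(x$name_of[codes]),
                 pattern = p, stringsAsFactors = FALSE)
    })))
  rows$name[is.na(rows$name)] <- ""
  write_tsv_atomic(rows, path)
}

#' Read an ATC dictionary from the nested-list YAML dialect
#'
#' Alternative reader mirroring a nested-list dictionary structure:
#' top-level keys are ATC codes, values are lists of surface patterns; the
#' first pattern doubles as the canonical display name.
#'
#' @inheritParams load_atc_dictionary
#' @return An `atc_dictionary`.
#' @export
load_atc_dictionary_yaml <- function(path, strict = FALSE) {
  y <- yaml::read_yaml(path)
  if (length(y) == 0L) {
    return(new_atc_dictionary(list(), stats::setNames(character(0), character(0))))
  }
  code <- character(0); name <- character(0); pattern <- character(0)
  for (cd in names(y)) {
    pats <- as.character(unlist(y[[cd]]))
    if (length(pats) == 0L) next
    code <- c(code, rep(cd, length(pats)))
    name <- c(name, rep(pats[1L], length(pats)))
    pattern <- c(pattern, pats)
  }
  suppressWarnings(atc_dictionary(code, name, pattern, strict = strict))
}

#' Look up the ATC codes of one token
#'
#' Returns the union of code sets over all matching patterns: the exact
#' entry for the token, if any, plus every glob pattern that matches.
#'
#' @param token A single normalized token.
#' @param atc An `atc_dictionary`.
#' @return Sorted character vector of codes (empty when unmatched).
#' @export
atc_lookup <- function(token, atc) {
  stopifnot(inherits(atc, "atc_dictionary"), length(token) == 1L)
  codes <- atc$entries[[token]]
  if (is.null(codes)) codes <- character(0)
  for (g in atc$glob) {
    if (match_pattern(token, g)) codes <- c(codes, atc$entries[[g]])
  }
  sort(unique(codes))
}

# ---- Regimens and abbreviations dictionary (RAD) ----------------------------

RAD_KINDS <- c("EXPANSION", "STUDY", "INFO", "MEDICATION")

new_rad_dictionary <- function(entries, warnings = character(0)) {
  structure(list(entries = entries, warnings = warnings),
            class = "rad_dictionary")
}

#' Build a regimens-and-abbreviations dictionary (RAD)
#'
#' The RAD is the first transformation stage: it expands regimen acronyms
#' (e.g. a combination-chemotherapy protocol name) into their constituent
#' substance names, resolves abbreviations and hyphenated aliases, and
#' routes non-substance terms to side channels. Each key carries exactly
#' one target kind:
#'
#' * `EXPANSION` — one or more canonical substance names (semicolon
#'   separated in `payload`) that replace the matched token(s);
#' * `STUDY` — a study-indicator term (e.g. "Studie") reported verbatim;
#' * `INFO` — a supplementary-therapy term (e.g. "TACE") reported verbatim;
#' * `MEDICATION` — a recognized medication name that has no ATC code.
#'
#' Keys are normalized (transliterated, hyphen-free, uppercase) and may be
#' multi-token phrases, which are matched longest-first before single
#' tokens. When an ATC dictionary is supplied, expansion names that resolve
#' to no code are collected as load warnings.
#'
#' @param key Character vector of surface keys.
#' @param kind Character vector in
#'   `c("EXPANSION", "STUDY", "INFO", "MEDICATION")`.
#' @param payload Character vector: semicolon-separated substance names for
#'   `EXPANSION`, the verbatim display term otherwise.
#' @param atc Optional `atc_dictionary` used to cross-check expansions.
#' @return An object of class `rad_dictionary`.
#' @examples
#' rad_dictionary("5-FU", "EXPANSION", "Fluorouracil")
#' @export
rad_dictionary <- function(key, kind, payload, atc = NULL) {
  key_n <- normalize_key(key)
  kind <- toupper(trimws(as.character(kind)))
  payload <- as.character(payload)
  stopifnot(length(key_n) == length(kind), length(kind) == length(payload))
  bad <- setdiff(unique(kind), RAD_KINDS)
  if (length(bad) > 0L) {
    stop("unknown RAD kind(s): ", paste(bad, collapse = ", "))
  }
  warnings <- character(0)
  entries <- list()
  for (i in seq_along(key_n)) {
    k <- key_n[i]
    if (!nzchar(k)) stop("empty RAD key after normalization (row ", i, ")")
    if (kind[i] == "EXPANSION") {
      names_i <- trimws(strsplit(payload[i], ";", fixed = TRUE)[[1]])
      names_i <- names_i[nzchar(names_i)]
      if (length(names_i) == 0L) {
        stop("EXPANSION entry '", key[i], "' has an empty payload")
      }
      tokens_i <- normalize_key(names_i)
      if (!is.null(atc)) {
        unresolved <- names_i[vapply(tokens_i, function(tk)
          length(atc_lookup(tk, atc)) == 0L, logical(1))]
        if (length(unresolved) > 0L) {
          warnings <- c(warnings, paste0(
            "expansion of '", k, "' has name(s) unresolvable in the ATC ",
            "dictionary: ", paste(unresolved, collapse = ", ")))
        }
      }
      entries[[k]] <- list(kind = "EXPANSION", payload = names_i,
                           tokens = tokens_i)
    } else {
      term <- payload[i]
      if (is.na(term) || !nzchar(trimws(term))) term <- key[i]
      entries[[k]] <- list(kind = kind[i], payload = trimws(term),
                           tokens = character(0))
    }
  }
  new_rad_dictionary(entries, warnings)
}

#' @export
print.rad_dictionary <- function(x, ...) {
  kinds <- vapply(x$entries, `[[`, character(1), "kind")
  cat("<rad_dictionary>", length(x$entries), "keys (",
      paste(names(table(kinds)), table(kinds), collapse = ", "), ")\n")
  invisible(x)
}

#' Read a RAD from a TSV file
#'
#' Expects tab-separated columns `key`, `kind` and `payload` (semicolon
#' separated names for `EXPANSION` rows); `#` starts a comment line.
#' Unknown kinds and empty expansion payloads are hard errors; expansion
#' names unresolvable in the supplied ATC dictionary produce warnings
#' collected in `$warnings`.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param atc Optional `atc_dictionary` for cross-checking expansions.
#' @return A `rad_dictionary`.
#' @export
load_rad <- function(path, atc = NULL) {
  df <- read_tsv_checked(path, c("key", "kind", "payload"))
  if (nrow(df) == 0L) return(new_rad_dictionary(list()))
  rad_dictionary(df$key, df$kind, df$payload, atc = atc)
}

#' Write a RAD to a TSV file
#'
#' Inverse of [load_rad()]; loading the written file yields an identical
#' dictionary.
#'
#' @param x A `rad_dictionary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rad <- function(x, path) {
  stopifnot(inherits(x, "rad_dictionary"))
  df <- data.frame(
    key = names(x$entries),
    kind = vapply(x$entries, `[[`, character(1), "kind"),
    payload = vapply(x$entries, function(e)
      paste(e$payload, collapse = "; "), character(1)),
    stringsAsFactors = FALSE
  )
  write_tsv_atomic(df, path)
}

#' Read a RAD from the nested-list YAML dialect
#'
#' Top-level keys are `KIND: payload` strings (e.g.
#' `"EXPANSION: Fluorouracil"` or `"STUDY: Studie"`); values are lists of
#' surface keys mapped to that target.
#'
#' @inheritParams load_rad
#' @return A `rad_dictionary`.
#' @export
load_rad_yaml <- function(path, atc = NULL) {
  y <- yaml::read_yaml(path)
  if (length(y) == 0L) return(new_rad_dictionary(list()))
  key <- character(0); kind <- character(0); payload <- character(0)
  for (hdr in names(y)) {
    parts <- regmatches(hdr, regexpr(":", hdr, fixed = TRUE), invert = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("malformed RAD YAML heading (expected 'KIND: payload'): ", hdr)
    }
    keys <- as.character(unlist(y[[hdr]]))
    key <- c(key, keys)
    kind <- c(kind, rep(trimws(parts[1L]), length(keys)))
    payload <- c(payload, rep(trimws(parts[2L]), length(keys)))
  }
  rad_dictionary(key, kind, payload, atc = atc)
}

# longest key length in tokens, for phrase matching
rad_max_key_tokens <- function(rad) {
  if (length(rad$entries) == 0L) return(0L)
  max(lengths(strsplit(names(rad$entries), " ", fixed = TRUE)))
}

rad_lookup <- function(phrase, rad) {
  e <- rad$entries[[phrase]]
  if (!is.null(e)) return(e)
  # glob keys are single-token only
  if (!grepl(" ", phrase, fixed = TRUE)) {
    for (k in names(rad$entries)) {
      if (grepl("*", k, fixed = TRUE) && match_pattern(phrase, k)) {
        return(rad$entries[[k]])
      }
    }
  }
  NULL
}
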