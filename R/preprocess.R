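#' Transliterate German umlauts and special characters
#'
#' Replaces the German characters ä, ö, ü, ß with their conventional ASCII
#' digraphs "ae", "oe", "ue", "ss". Uppercase forms are mapped to uppercase
#' digraphs (Ä to "AE", Ö to "OE", Ü to "UE", ẞ to "SS") because
#' transliteration runs before tokens are uppercased and clinical free text
#' contains capitalized words. All other characters pass through unchanged.
#'
#' The operation is idempotent: applying it twice gives the same result as
#' applying it once.
#'
#' @param text Character vector (UTF-8). `NA` values are kept as `NA`.
#' @return Character vector of the same length, free of the characters
#'   ä, ö, ü, ß, Ä, Ö, Ü, ẞ.
#' @examples
#' transliterate_german("Erhaltungstherapie über 5 Tage")
#' @export
transliterate_german <- function(text) {
  if (length(text) == 0L) return(character(0))
  out <- text
  subs <- c(
    "ä" = "ae", "ö" = "oe", "ü" = "ue", "ß" = "ss",
    "Ä" = "AE", "Ö" = "OE", "Ü" = "UE", "ẞ" = "SS"
  )
  for (ch in names(subs)) {
    out <- gsub(ch, subs[[ch]], out, fixed = TRUE)
  }
  out
}

#' Tokenize a transliterated medication string
#'
#' Splits free text into uppercase tokens consisting only of `A-Z0-9`.
#' Hyphens are deleted *without* splitting, so the flanking parts fuse into
#' one token ("5-FU" becomes the single token "5FU") and abbreviation
#' identity is preserved. Every other non-alphanumeric character
#' (punctuation, symbols, non-ASCII letters) acts as a delimiter: it is
#' deleted and splits the surrounding text.
#'
#' @param text A single character string, already transliterated (see
#'   [transliterate_german()]).
#' @return Character vector of uppercase tokens in surface order; length
#'   zero if the text holds no alphanumeric content.
#' @examples
#' tokenize_entry("5-FU (Fluorouracil)")
#' tokenize_entry("Cisplatin + Etoposid")
#' @export
tokenize_entry <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- gsub("-", "", text, fixed = TRUE)
  x <- gsub("[^A-Za-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toupper(toks[nzchar(toks)])
}

#' Construct a stoplist of noise tokens
#'
#' A stoplist holds exact literals (unit words, time words) and regular
#' expressions for whole noise classes (pure numbers, number+unit fusions
#' such as "100MG"). Both are matched against uppercase tokens.
#'
#' @param literals Character vector of exact uppercase noise tokens.
#' @param patterns Character vector of regular expressions, each applied
#'   anchored to the whole token.
#' @return An object of class `atc_stoplist`.
#' @seealso [default_stoplist()], [load_stoplist()], [filter_tokens()]
#' @export
stoplist <- function(literals = character(0), patterns = character(0)) {
  structure(
    list(literals = toupper(unique(as.character(literals))),
         patterns = unique(as.character(patterns))),
    class = "atc_stoplist"
  )
}

#' Default noise-token stoplist
#'
#' The shipped starting list covers measurement units (MG, ML, G, IE), time
#' references (TAG, TAGE, WOCHE, ZYKLUS, TAEGLICH) and two pattern classes:
#' pure numbers (`^\d+$`) and short number+letter fusions such as "100MG" or
#' "2X" (`^\d+[A-Z]{1,3}$`). Dictionary keys are always protected from
#' removal (see [filter_tokens()]), so tokens like "5FU" survive even though
#' the second pattern matches them.
#'
#' @return An `atc_stoplist` object.
#' @export
default_stoplist <- function() {
  stoplist(
    literals = c("MG", "ML", "G", "IE",
                 "TAG", "TAGE", "WOCHE", "ZYKLUS", "TAEGLICH"),
    patterns = c("^\\d+$", "^\\d+[A-Z]{1,3}$")
  )
}

#' @export
print.atc_stoplist <- function(x, ...) {
  cat("<atc_stoplist>", length(x$literals), "literals,",
      length(x$patterns), "patterns\n")
  invisible(x)
}

#' Read a stoplist from a TSV file
#'
#' Expects two tab-separated columns `kind` (LITERAL or PATTERN) and
#' `value`; lines starting with `#` are comments. Literals are normalized
#' to uppercase.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return An `atc_stoplist` object.
#' @export
load_stoplist <- function(path) {
  df <- read_tsv_checked(path, c("kind", "value"))
  kind <- toupper(df$kind)
  bad <- setdiff(unique(kind), c("LITERAL", "PATTERN"))
  if (length(bad) > 0L) {
    stop("unknown stoplist kind(s): ", paste(bad, collapse = ", "))
  }
  stoplist(literals = df$value[kind == "LITERAL"],
           patterns = df$value[kind == "PATTERN"])
}

#' Write a stoplist to a TSV file
#'
#' Inverse of [load_stoplist()].
#'
#' @param x An `atc_stoplist` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stoplist <- function(x, path) {
  stopifnot(inherits(x, "atc_stoplist"))
  df <- data.frame(
    kind = c(rep("LITERAL", length(x$literals)),
             rep("PATTERN", length(x$patterns))),
    value = c(x$literals, x$patterns),
    stringsAsFactors = FALSE
  )
  write_tsv_atomic(df, path)
}

stoplist_matches <- function(tokens, stop) {
  if (length(tokens) == 0L) return(logical(0))
  hit <- tokens %in% stop$literals
  for (p in stop$patterns) {
    hit <- hit | grepl(p, tokens)
  }
  hit
}

#' Remove noise tokens, protecting dictionary keys
#'
#' Drops every token matched by a stoplist literal or pattern unless the
#' token is a known dictionary key (the protected set). Dictionary
#' membership wins over the stoplist because only genuinely undesired
#' tokens may be discarded: "5FU" must survive the number+letters pattern
#' to be expanded later. Relative token order is preserved.
#'
#' @param tokens Character vector of uppercase tokens.
#' @param stop An `atc_stoplist`.
#' @param protected Character vector of dictionary keys exempt from removal
#'   (see [protected_keys()]).
#' @return The filtered token vector.
#' @export
filter_tokens <- function(tokens, stop = default_stoplist(),
                          protected = character(0)) {
  stopifnot(inherits(stop, "atc_stoplist"))
  if (length(tokens) == 0L) return(character(0))
  drop <- stoplist_matches(tokens, stop) & !(tokens %in% protected)
  tokens[!drop]
}

#' Collect the token protection set of loaded dictionaries
#'
#' Returns every single-token key plus every constituent token of
#' multi-token phrase keys, across the ATC dictionary and the RAD. These
#' tokens are exempt from stoplist filtering. Glob patterns (containing
#' `*`) are excluded: protection is exact-match only.
#'
#' @param atc An `atc_dictionary`, or `NULL`.
#' @param rad A `rad_dictionary`, or `NULL`.
#' @return Character vector of protected tokens.
#' @export
protected_keys <- function(atc = NULL, rad = NULL) {
  keys <- character(0)
  if (!is.null(atc)) keys <- c(keys, names(atc$entries))
  if (!is.null(rad)) keys <- c(keys, names(rad$entries))
  keys <- keys[!grepl("*", keys, fixed = TRUE)]
  unique(unlist(strsplit(keys, " ", fixed = TRUE)))
}

#' Report stoplist entries that collide with dictionary keys
#'
#' A stoplist literal or pattern that matches a dictionary key would, without
#' the protection mechanism, silently delete meaningful tokens. This check
#' lists such collisions so curated lists can be reviewed. Collisions are not
#' errors — [filter_tokens()] never removes protected keys — but pattern
#' collisions beyond the shipped defaults usually indicate an overly broad
#' pattern.
#'
#' @inheritParams filter_tokens
#' @param atc An `atc_dictionary`, or `NULL`.
#' @param rad A `rad_dictionary`, or `NULL`.
#' @return Character vector of dictionary tokens matched by the stoplist
#'   (empty when there is no collision).
#' @export
check_stoplist <- function(stop, atc = NULL, rad = NULL) {
  keys <- protected_keys(atc, rad)
  keys[stoplist_matches(keys, stop)]
}

#' Preprocess one raw entry into tokens
#'
#' Runs the full deterministic normalization chain: transliteration,
#' tokenization (hyphen fusion, punctuation removal, uppercasing) and
#' stoplist filtering with dictionary-key protection.
#'
#' @param text A single free-text medication string.
#' @inheritParams filter_tokens
#' @return Character vector of clean uppercase tokens.
#' @examples
#' preprocess_entry("Cisplatin 100mg täglich")
#' @export
preprocess_entry <- function(text, stop = default_stoplist(),
                             protected = character(0)) {
  filter_tokens(tokenize_entry(transliterate_german(text)), stop, protected)
}
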