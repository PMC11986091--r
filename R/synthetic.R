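# Synthetic toy dictionaries and gold-labelled corpora. The real WIdO ATC
# dictionary is licensed and cannot be shipped; these generators produce
# structurally faithful stand-ins (valid level-5 codes, regimen acronyms,
# abbreviations, umlaut decorations) with gold labels derived from the
# generative choices only — never from the pipeline under test.

# run code under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic corpus generator
#'
#' Bundles every tunable of the fixture generator. All randomness flows
#' from the single `seed`.
#'
#' @param seed Integer seed; the shipped default keeps fixture-based runs
#'   reproducible.
#' @param n_entries Number of free-text entries to generate.
#' @param n_substances Number of invented substances in the toy ATC
#'   dictionary.
#' @param n_regimens Number of regimen acronyms in the toy RAD.
#' @param regimen_fraction Probability that an entry is a regimen acronym
#'   rather than plain substance names.
#' @param study_fraction Probability of appending a study indicator term.
#' @param info_fraction Probability of appending a supplementary-info term.
#' @param dose_annotation_rate Probability of appending dosage/time noise.
#' @param typo_rate Probability, per surface token, of corrupting it with
#'   one adjacent-letter transposition unknown to all dictionaries.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 20250410,
                             n_entries = 500,
                             n_substances = 50,
                             n_regimens = 8,
                             regimen_fraction = 0.15,
                             study_fraction = 0.10,
                             info_fraction = 0.10,
                             dose_annotation_rate = 0.30,
                             typo_rate = 0) {
  cfg <- list(seed = as.integer(seed), n_entries = as.integer(n_entries),
              n_substances = as.integer(n_substances),
              n_regimens = as.integer(n_regimens),
              regimen_fraction = regimen_fraction,
              study_fraction = study_fraction,
              info_fraction = info_fraction,
              dose_annotation_rate = dose_annotation_rate,
              typo_rate = typo_rate)
  probs <- cfg[c("regimen_fraction", "study_fraction", "info_fraction",
                 "dose_annotation_rate", "typo_rate")]
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
    stop("all fractions/rates must lie in [0, 1]")
  }
  if (cfg$n_entries < 0L || cfg$n_substances < 1L || cfg$n_regimens < 1L) {
    stop("counts must be positive (n_entries may be zero)")
  }
  structure(cfg, class = "synthetic_config")
}

SYLLABLES <- c("ba", "be", "bo", "da", "de", "do", "fa", "fi", "ga", "go",
               "ka", "ke", "ki", "la", "le", "li", "lo", "ma", "me", "mi",
               "mo", "na", "ne", "ni", "no", "pa", "pe", "po", "ra", "re",
               "ri", "ro", "sa", "se", "si", "ta", "te", "ti", "to", "va")

NAME_SUFFIXES <- c("mab", "platin", "ukatin", "citabin", "rubicin",
                   "taxel", "tinib", "lumid")

title_case <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

invent_names <- function(n, taken = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    stem <- paste(sample(SYLLABLES, sample(2:3, 1L), replace = TRUE),
                  collapse = "")
    nm <- title_case(paste0(stem, sample(NAME_SUFFIXES, 1L)))
    if (!(toupper(nm) %in% c(toupper(out), toupper(taken)))) {
      out <- c(out, nm)
    }
  }
  out
}

invent_code <- function(letter, taken) {
  repeat {
    code <- paste0(letter, sprintf("%02d", sample(0:99, 1L)),
                   paste(sample(LETTERS, 2L, replace = TRUE), collapse = ""),
                   sprintf("%02d", sample(0:99, 1L)))
    if (!(code %in% taken)) return(code)
  }
}

#' Generate a toy ATC dictionary
#'
#' Invents `n_substances` pronounceable substance names (with drug-like
#' suffixes such as -mab, -platin, -ukatin; no real drug names) and assigns
#' each a structurally valid level-5 ATC code — about 70% in chapter L,
#' the remainder spread over the other anatomical groups. At least one
#' name is mapped to two codes (one chapter-L, one not) so that multi-code
#' resolution is exercised. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return An `atc_dictionary`.
#' @export
build_toy_atc <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_substances
    names_ <- invent_names(n)
    letters1 <- ifelse(stats::runif(n) < 0.7, "L",
                       sample(setdiff(ATC_ANATOMICAL_LETTERS, "L"), n,
                              replace = TRUE))
    # guarantee both chapters are represented
    letters1[1L] <- "L"
    if (n > 1L) letters1[2L] <- "A"
    codes <- character(n)
    for (i in seq_len(n)) codes[i] <- invent_code(letters1[i], codes)
    # one substance carries a second, non-L code to force resolution
    dual <- which(letters1 == "L")[1L]
    extra_code <- invent_code("M", codes)
    atc_dictionary(code = c(codes, extra_code),
                   name = c(names_, names_[dual]))
  })
}

#' Generate a toy regimens-and-abbreviations dictionary
#'
#' Builds, on top of a toy ATC dictionary: `n_regimens` invented regimen
#' acronyms each expanding to 2–3 substances; abbreviation keys (prefix
#' truncations of substance names); one hyphenated alias of the form
#' `5-<Name>`; the three study-indicator keys (Studie, Register,
#' Protokoll); supplementary-info keys (TACE, Chemotherapie,
#' Erhaltungstherapie and the phrase "best supportive care"); and one
#' recognized medication name without an ATC code. Deterministic given
#' `config$seed`.
#'
#' @param atc A toy `atc_dictionary` from [build_toy_atc()].
#' @param config A [synthetic_config()].
#' @return A `rad_dictionary` whose `"meta"` attribute records the
#'   generated surface forms for use by [generate_entries()].
#' @export
build_toy_rad <- function(atc, config) {
  stopifnot(inherits(atc, "atc_dictionary"),
            inherits(config, "synthetic_config"))
  with_seed(config$seed + 1L, {
    patterns <- names(atc$entries)
    display <- unname(vapply(patterns, function(p)
      atc$name_of[[atc$entries[[p]][1L]]], character(1)))

    key <- character(0); kind <- character(0); payload <- character(0)

    # routing terms, stoplist words and phrase parts must stay unambiguous
    reserved <- c("STUDIE", "REGISTER", "PROTOKOLL",
                  "TACE", "CHEMOTHERAPIE", "ERHALTUNGSTHERAPIE",
                  "BEST", "SUPPORTIVE", "CARE",
                  default_stoplist()$literals, "UEBER")

    # regimen acronyms -> 2-3 substances
    acronyms <- character(0)
    while (length(acronyms) < config$n_regimens) {
      a <- paste(sample(LETTERS, sample(4:6, 1L), replace = TRUE),
                 collapse = "")
      if (!(a %in% c(acronyms, patterns, reserved))) acronyms <- c(acronyms, a)
    }
    regimen_payloads <- lapply(acronyms, function(a) {
      sample(display, sample(2:3, 1L))
    })
    key <- c(key, acronyms)
    kind <- c(kind, rep("EXPANSION", length(acronyms)))
    payload <- c(payload, vapply(regimen_payloads, paste,
                                 character(1), collapse = "; "))

    # abbreviations: prefix truncations of long substance names
    long_idx <- which(nchar(patterns) >= 9L)
    abbrev_idx <- utils::head(long_idx, 5L)
    abbrev_keys <- character(0)
    abbrev_of <- character(0)
    for (i in abbrev_idx) {
      k <- substr(patterns[i], 1L, sample(5:6, 1L))
      if (k %in% c(patterns, key, abbrev_keys, reserved)) next
      abbrev_keys <- c(abbrev_keys, k)
      abbrev_of <- c(abbrev_of, display[i])
    }
    key <- c(key, abbrev_keys)
    kind <- c(kind, rep("EXPANSION", length(abbrev_keys)))
    payload <- c(payload, abbrev_of)

    # one hyphenated alias, e.g. "5-Baditaxel"
    alias_idx <- sample(seq_along(display), 1L)
    alias_surface <- paste0("5-", display[alias_idx])
    key <- c(key, alias_surface)
    kind <- c(kind, "EXPANSION")
    payload <- c(payload, display[alias_idx])

    study_terms <- c("Studie", "Register", "Protokoll")
    info_terms <- c("TACE", "Chemotherapie", "Erhaltungstherapie")
    key <- c(key, study_terms, info_terms, "best supportive care")
    kind <- c(kind, rep("STUDY", 3L), rep("INFO", 4L))
    payload <- c(payload, study_terms, info_terms, "best supportive care")

    # a recognized medication name lacking an ATC code
    med_name <- invent_names(1L, taken = display)
    key <- c(key, med_name)
    kind <- c(kind, "MEDICATION")
    payload <- c(payload, med_name)

    rad <- rad_dictionary(key, kind, payload, atc = atc)
    attr(rad, "meta") <- list(
      acronyms = acronyms,
      regimen_payloads = stats::setNames(regimen_payloads, acronyms),
      abbrev_keys = abbrev_keys,
      abbrev_of = abbrev_of,
      alias_surface = alias_surface,
      alias_name = display[alias_idx],
      medication_name = med_name,
      study_terms = study_terms,
      info_terms = info_terms,
      substance_display = display,
      substance_pattern = patterns
    )
    rad
  })
}

# the resolution rule re-derived independently of the pipeline:
# prefer the alphabetically first chapter-L code, else the first overall
gold_resolve <- function(codes) {
  l <- codes[startsWith(codes, "L")]
  if (length(l) > 0L) min(l) else min(codes)
}

transpose_unknown <- function(surface, atc, rad) {
  chars <- strsplit(surface, "")[[1]]
  positions <- sample(seq_len(length(chars) - 1L))
  for (p in positions) {
    sw <- chars
    sw[c(p, p + 1L)] <- sw[c(p + 1L, p)]
    cand <- paste(sw, collapse = "")
    if (toupper(cand) == toupper(surface)) next
    tok <- normalize_key(cand)
    if (length(atc_lookup(tok, atc)) == 0L && is.null(rad_lookup(tok, rad))) {
      return(cand)
    }
  }
  NULL
}

DOSE_POOL <- c("100mg", "250 mg", "40 mg", "1,5 g", "2x täglich",
               "500 ml", "1 Zyklus", "über 5 Tage")

#' Generate a gold-labelled synthetic corpus
#'
#' Each entry is either one regimen acronym (probability
#' `regimen_fraction`) or 1–4 distinct substances; substance surfaces may
#' appear as abbreviations or as the hyphenated alias, occasionally in the
#' redundant "alias (full name)" form that exercises deduplication. With
#' the configured probabilities, entries are decorated with dosage/time
#' noise (including umlaut words), study indicators and
#' supplementary-info terms, joined with varying separators and optional
#' parentheses. With probability `typo_rate`, each surface token is
#' corrupted by one adjacent-letter transposition verified to be unknown
#' to both dictionaries; its gold tokens are marked `expect_fail`.
#'
#' Gold annotations and gold records are computed from the generative
#' choices (with an independent copy of the L-priority resolution rule),
#' never by running the pipeline.
#'
#' @param atc A toy `atc_dictionary`.
#' @param rad A toy `rad_dictionary` from [build_toy_rad()].
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_corpus`: list with `entries`
#'   (data.frame `entry_id`, `Medication`), `gold` (data.frame `entry_id`,
#'   `token`, `expected`, `expect_fail`), `gold_records` (list of expected
#'   five-column records at `typo_rate = 0`) and `config`.
#' @export
generate_entries <- function(atc, rad, config) {
  stopifnot(inherits(atc, "atc_dictionary"), inherits(rad, "rad_dictionary"),
            inherits(config, "synthetic_config"))
  meta <- attr(rad, "meta")
  if (is.null(meta)) stop("rad lacks generator metadata; use build_toy_rad()")
  with_seed(config$seed + 2L, {
    n <- config$n_entries
    entries <- data.frame(entry_id = character(n), Medication = character(n),
                          stringsAsFactors = FALSE)
    gold_list <- vector("list", n)
    gold_records <- vector("list", n)

    for (i in seq_len(n)) {
      id <- as.character(i)
      parts <- character(0)       # surface fragments, in order
      g_tok <- character(0); g_exp <- character(0); g_fail <- logical(0)
      study_terms <- character(0); info_terms <- character(0)

      add_substance_gold <- function(display_name, failed) {
        tok <- normalize_key(display_name)
        code <- gold_resolve(atc$entries[[tok]])
        g_tok <<- c(g_tok, tok)
        g_exp <<- c(g_exp, code)
        g_fail <<- c(g_fail, failed)
      }

      if (stats::runif(1) < config$regimen_fraction) {
        acr <- sample(meta$acronyms, 1L)
        surface <- acr
        failed <- FALSE
        if (stats::runif(1) < config$typo_rate) {
          cand <- transpose_unknown(surface, atc, rad)
          if (!is.null(cand)) { surface <- cand; failed <- TRUE }
        }
        parts <- surface
        for (nm in meta$regimen_payloads[[acr]]) {
          add_substance_gold(nm, failed)
        }
      } else {
        k <- sample(1:4, 1L, prob = c(0.45, 0.30, 0.15, 0.10))
        k <- min(k, length(meta$substance_display))
        idx <- sample(seq_along(meta$substance_display), k)
        for (j in idx) {
          nm <- meta$substance_display[j]
          surface <- nm
          failed <- FALSE
          # a typo is applied to the plain name; compound alias surfaces
          # would leave the parenthesized full name intact and recoverable
          if (stats::runif(1) < config$typo_rate) {
            cand <- transpose_unknown(nm, atc, rad)
            if (!is.null(cand)) { surface <- cand; failed <- TRUE }
          }
          if (!failed) {
            # render via abbreviation or hyphenated alias when available
            if (nm %in% meta$abbrev_of && stats::runif(1) < 0.25) {
              kk <- meta$abbrev_keys[match(nm, meta$abbrev_of)]
              surface <- title_case(tolower(kk))
            } else if (identical(nm, meta$alias_name) &&
                       stats::runif(1) < 0.5) {
              surface <- if (stats::runif(1) < 0.5) {
                paste0(meta$alias_surface, " (", nm, ")")
              } else {
                meta$alias_surface
              }
            }
          }
          if (stats::runif(1) < 0.15 && !grepl("(", surface, fixed = TRUE)) {
            surface <- paste0("(", surface, ")")
          }
          parts <- c(parts, surface)
          add_substance_gold(nm, failed)
        }
      }

      if (stats::runif(1) < config$dose_annotation_rate) {
        parts <- c(parts, sample(DOSE_POOL, 1L))
      }
      if (stats::runif(1) < config$study_fraction) {
        term <- sample(meta$study_terms, 1L)
        parts <- c(parts, term)
        study_terms <- c(study_terms, term)
      }
      if (stats::runif(1) < config$info_fraction) {
        term <- sample(meta$info_terms, 1L)
        parts <- c(parts, term)
        info_terms <- c(info_terms, term)
      }

      sep <- sample(c(" + ", ", ", " "), 1L)
      text <- paste(parts, collapse = sep)

      entries$entry_id[i] <- id
      entries$Medication[i] <- text

      gold_i <- data.frame(entry_id = character(0), token = character(0),
                           expected = character(0), expect_fail = logical(0),
                           stringsAsFactors = FALSE)
      if (length(g_tok) > 0L) {
        keep <- !duplicated(g_tok)
        gold_i <- data.frame(entry_id = id, token = g_tok[keep],
                             expected = g_exp[keep],
                             expect_fail = g_fail[keep],
                             stringsAsFactors = FALSE)
      }
      if (length(study_terms) > 0L) {
        gold_i <- rbind(gold_i, data.frame(
          entry_id = id, token = normalize_key(study_terms),
          expected = paste0("STUDY:", study_terms),
          expect_fail = FALSE, stringsAsFactors = FALSE))
      }
      if (length(info_terms) > 0L) {
        gold_i <- rbind(gold_i, data.frame(
          entry_id = id, token = normalize_key(info_terms),
          expected = paste0("INFO:", info_terms),
          expect_fail = FALSE, stringsAsFactors = FALSE))
      }
      gold_list[[i]] <- gold_i

      codes <- unique(g_exp[!duplicated(g_tok)])
      gold_records[[i]] <- list(
        entry_id = id,
        original_text = text,
        antineoplastic_medication = sort(unique(codes[startsWith(codes, "L")])),
        additional_medication = sort(unique(codes[!startsWith(codes, "L")])),
        medication = character(0),
        study = unique(study_terms),
        info = unique(info_terms)
      )
    }

    gold <- if (n > 0L) do.call(rbind, gold_list) else
      data.frame(entry_id = character(0), token = character(0),
                 expected = character(0), expect_fail = logical(0),
                 stringsAsFactors = FALSE)
    structure(list(entries = entries, gold = gold,
                   gold_records = gold_records, config = config),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus>", nrow(x$entries), "entries,",
      nrow(x$gold), "gold rows (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Build and write a complete fixture set
#'
#' Generates the toy ATC dictionary, toy RAD, default stoplist and a
#' gold-labelled corpus, and writes five files into `dir`:
#' `atc_dictionary.tsv`, `rad.tsv`, `stoplist.tsv`, `entries.csv` and
#' `gold.tsv` — in exactly the formats the production loaders read.
#' Identical configurations produce byte-identical directories.
#'
#' @param config A [synthetic_config()].
#' @param dir Target directory (created if missing).
#' @return Invisibly, a list with the written `paths` and the in-memory
#'   `atc`, `rad`, `stoplist` and `corpus` objects.
#' @export
make_fixtures <- function(config = synthetic_config(), dir) {
  if (!dir.exists(dir)) {
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
      stop("cannot create fixture directory: ", dir)
    }
  }
  atc <- build_toy_atc(config)
  rad <- build_toy_rad(atc, config)
  stop_ <- default_stoplist()
  corpus <- generate_entries(atc, rad, config)
  paths <- list(
    atc = file.path(dir, "atc_dictionary.tsv"),
    rad = file.path(dir, "rad.tsv"),
    stoplist = file.path(dir, "stoplist.tsv"),
    entries = file.path(dir, "entries.csv"),
    gold = file.path(dir, "gold.tsv")
  )
  write_atc_dictionary(atc, paths$atc)
  write_rad(rad, paths$rad)
  write_stoplist(stop_, paths$stoplist)
  write_delim_atomic(corpus$entries[, c("Medication", "entry_id")],
                     paths$entries)
  write_tsv_atomic(corpus$gold, paths$gold)
  invisible(list(paths = paths, atc = atc, rad = rad, stoplist = stop_,
                 corpus = corpus))
}
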