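---
title: "Standardizing free-text medication entries into ATC codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing free-text medication entries into ATC codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Medication administration in oncology records is often documented as free
text: substance names in varying spellings and casings, regimen acronyms
standing for whole combination protocols, dosages, routes, study markers
and other annotations, all mixed into a single column. Analyzing treatment
patterns requires mapping this text onto a standardized vocabulary. The WHO
Anatomical Therapeutic Chemical (ATC) classification is the natural target:
a full level-5 code has seven characters — one letter (the anatomical main
group, one of fourteen), two digits, two letters, two digits — e.g.
`L01BA01`. Chapter `L` collects the antineoplastic and immunomodulating
agents, which is why separating `L` codes from everything else is the
organizing principle of the output.

`atcmapr` implements a deterministic, dictionary-based pipeline for German
clinical free text. A dictionary approach is transparent (every mapping is
a reviewable dictionary row), cheap to run, reproducible, and easy to adapt
to a new site by editing two TSV files. The trade-off is equally clear: it
cannot recover tokens it has never seen, including misspellings.

## The pipeline

Each entry passes through five deterministic stages:

1. **Transliteration.** German umlauts and eszett (ä, ö, ü, ß, and their
   uppercase forms) are rewritten as `ae`, `oe`, `ue`, `ss`. This runs
   before uppercasing, so uppercase umlauts are mapped to uppercase
   digraphs.
2. **Tokenization.** Text is split into uppercase tokens over `[A-Z0-9]`.
   Hyphens are deleted *without* splitting, so `5-FU` becomes the single
   token `5FU` — splitting would destroy abbreviation identity. Every
   other non-alphanumeric character is a delimiter.
3. **Stoplist filtering.** Units, time words and number/unit fusions (the
   shipped defaults: MG, ML, G, IE, TAG, TAGE, WOCHE, ZYKLUS, TAEGLICH,
   plus the patterns `^\d+$` and `^\d+[A-Z]{1,3}$`) are removed. Tokens
   that are dictionary keys are protected from removal: `5FU` matches the
   number+letters pattern, but since it is a RAD key it survives.
   Dictionary membership always wins over the stoplist.
4. **RAD stage.** The regimens-and-abbreviations dictionary maps keys to
   one of four targets: `EXPANSION` (replace the token by one or more
   canonical substance names — this is how a regimen acronym becomes its
   constituents), `STUDY`, `INFO` (route the term to a side channel) or
   `MEDICATION` (a recognized name with no ATC code). Multi-token phrase
   keys (e.g. "best supportive care") are matched longest-first.
   Afterwards exact duplicates within the entry are removed keeping the
   first occurrence, so `5-FU (Fluorouracil)` yields Fluorouracil once.
5. **ATC stage and resolution.** Each remaining token receives its full
   candidate code set from the ATC dictionary. A token with several codes
   is resolved *per token*: if any candidate starts with `L`, the
   alphabetically first `L` code is kept (the tool's focus is cancer
   therapy); otherwise the alphabetically first code overall. Ties among
   several `L` codes fall back to the same alphabetical rule, which keeps
   the two branches of the rule consistent. Tokens matching nothing are
   retained internally as *residuals* — they drive dictionary refinement
   and evaluation but are never exported.

The output table echoes the original column byte-for-byte and adds five
columns: `AntineoplasticMedication` (sorted `L` codes),
`AdditionalMedication` (sorted non-`L` codes), `Medication` (recognized
names without a code), `Study` and `Info` (routed terms, verbatim). Cells
with several values are joined with `", "` by default; empty cells are
empty strings rather than NA, so the CSV round-trips without NA
conventions.

## Dictionary semantics

Patterns and keys are stored in the same normalized form the preprocessing
produces (transliterated, hyphen-free, uppercase), so matching is
symmetric by construction. Matching is **exact by default**; a pattern may
opt into glob matching with `*` (matching zero or more of `[A-Z0-9]`),
e.g. `MITOMYC*` to catch truncated documentation. Exact-by-default was a
deliberate choice: silent prefix matching across a whole drug vocabulary
risks false merges between similarly named substances, so globs must be
enabled entry by entry.

Structurally invalid codes in a user-supplied dictionary are kept with a
warning (strict mode turns this into an error): real-world registries
contain pseudo-codes, and downstream routing only inspects the first
letter. The validator itself is exposed as `validate_atc_code()`.

The licensed WIdO ATC dictionary is not and cannot be bundled. The loaders
read a documented TSV format (`code`, `name`, `pattern`), plus an optional
nested-list YAML dialect, so a licensed dictionary can be dropped in.

## Evaluation taxonomy

`evaluate_standardization()` compares output records with gold
annotations. A gold token expecting an ATC code counts as *successfully
transformed* iff its code appears in either code column. An entry is an
*error in transformation* iff at least one expected transformation is
missing; it is *no useful information* iff it was not an error and its
output provides no code and no Medication/Study/Info content; all other
entries are successes. At the token level only "ATC code expected" tokens
enter the denominator, and each no-useful-information entry counts as one
token. Rates are reported as percentages with one decimal. The number of
entries with additional (Study/Info) information is reported separately.

## The synthetic corpus generator

Real evaluation data cannot be shipped, so the package generates
structurally faithful fixtures: invented substance names (pronounceable
syllable stems with drug-like suffixes such as *-mab*, *-platin*,
*-ukatin*; deliberately no real drug names), each with a structurally
valid level-5 code, about 70% in chapter `L`; at least one substance
carries both an `L` and a non-`L` code so resolution is always exercised.
The toy RAD contains regimen acronyms expanding to 2–3 substances,
prefix abbreviations, one hyphenated `5-<Name>` alias, the study keys
(Studie, Register, Protokoll) and info keys (TACE, Chemotherapie,
Erhaltungstherapie, "best supportive care"), and one uncoded medication
name.

Entries hold one regimen or 1–4 substances (skewed toward one or two, as
in routine administration records), decorated with the configured
probabilities: dosage/time noise (including umlaut words, to exercise
transliteration), study markers, info terms, varying separators,
parentheses. Defaults: 500 entries, 50 substances, 8 regimens, regimen
fraction 0.15, study and info fractions 0.10 each, dose annotation rate
0.30, typo rate 0, seed 20250410. These defaults are declared modelling
assumptions — realistic shapes for a single-center oncology extract — not
estimates of any particular data set.

Typos follow the error type that dominates manual data entry: a single
adjacent-letter transposition, applied per surface token with probability
`typo_rate` and verified to be unknown to both dictionaries, so the
marginal failure probability per expected token equals `typo_rate`. A
corrupted regimen acronym makes all its expanded tokens fail together;
this mild clustering slightly widens the variance of observed failure
rates relative to a pure binomial, which the tests absorb by using a 99%
interval. Gold labels are computed from the generative choices alone —
including an independent copy of the L-priority resolution rule — never
by running the pipeline, so closed-loop tests are genuinely two-sided.

What the generator does *not* emulate: prescription-frequency statistics,
German grammatical structure beyond umlauts and decorations, misspellings
other than transpositions, and entries with no information at all (the
no-useful-information bucket is exercised by handcrafted unit tests
instead). Perfect closed-loop recovery therefore demonstrates internal
consistency of the pipeline, not expected accuracy on real clinical text,
where unknown abbreviations and misspellings dominate the error budget.

## Numerical and design choices

* **Deduplication** is entry-wide (not merely adjacent) and keeps the
  first occurrence; applying it twice changes nothing.
* **Decimal commas** ("1,5") split into two numeric tokens and are then
  stoplist-filtered; dosage is discarded by design, so this loss is
  accepted.
* **Multi-word substance names** are handled at the dictionary stage via
  multi-token phrase keys, not by the tokenizer; single tokens remain the
  unit of preprocessing.
* **Six-character pseudo-codes** (seen in the wild for Methotrexate's
  alternative code) are accepted by the loaders with a warning and
  treated as non-`L` additional medication; the validator reports them
  invalid.
* **Determinism**: there is no randomness anywhere in the pipeline; the
  generator derives all randomness from one seed and restores the
  caller's RNG state.
* **Problem sizes** used by the shipped checks: closed-loop recovery on
  500 clean entries, degradation on 2000 entries at a 20% typo rate,
  idempotence fuzzing on 10,000 random strings — sizes at which the
  binomial intervals are tight enough to be informative while the whole
  suite stays fast.

## Worked example

```{r}
library(atcmapr)

atc <- suppressWarnings(atc_dictionary(
  code = c("L01BA01", "M01CX0", "L01BC02", "L01XA01", "A04AA01"),
  name = c("Methotrexat", "Methotrexat", "Fluorouracil", "Cisplatin",
           "Ondansetron")))
rad <- rad_dictionary(
  key = c("5-FU", "Studie", "TACE"),
  kind = c("EXPANSION", "STUDY", "INFO"),
  payload = c("Fluorouracil", "Studie", "TACE"), atc = atc)

standardize(c("Methotrexat 15mg", "5-FU (Fluorouracil)",
              "Cisplatin + Ondansetron, Studie"), atc, rad)
```

Methotrexat carries two candidate codes; only the chapter-`L` code is
retained. The hyphenated abbreviation and its spelled-out form collapse to
a single Fluorouracil mapping. Cisplatin and Ondansetron separate into the
antineoplastic and additional columns, and the study marker is routed to
`Study`.

## Limitations

No fuzzy or edit-distance recovery of residual tokens; no level-1–4
rollup reporting; no dosage or route extraction; German-oriented
normalization only. These are scope decisions, not oversights: the
refinement loop for residual tokens is the supported path for adapting
the dictionaries to a new site.
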