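# atcmapr

Dictionary-based standardization of (German) free-text medication entries
into the WHO Anatomical Therapeutic Chemical (ATC) classification.

## The problem

Oncology treatment documentation is frequently free text: substance names
in inconsistent spellings, chemotherapy regimen acronyms, dosages, study
markers and supplementary remarks mixed into one column. Researchers
analyzing treatment patterns need those entries mapped onto the ATC
system, whose level-5 codes have the shape *letter, two digits, two
letters, two digits* (e.g. `L01BA01`); the leading letter is one of
fourteen anatomical main groups, with chapter `L` holding the
antineoplastic and immunomodulating agents.

`atcmapr` is for clinical data scientists and pharmacoepidemiologists who
need this mapping to be transparent, deterministic and site-adaptable. It
implements:

- text normalization (umlaut transliteration ä→ae, ö→oe, ü→ue, ß→ss;
  tokenization with hyphen fusion so `5-FU` → `5FU`; a protected,
  editable stoplist for units and time words);
- a regimens-and-abbreviations dictionary (RAD) stage that expands
  acronyms into constituent substances, resolves abbreviations and
  routes study/info terms to side channels, with within-entry
  deduplication;
- ATC dictionary lookup (exact by default, per-entry opt-in `*` globs)
  with multi-code resolution: if a substance maps to several codes, the
  alphabetically first chapter-`L` code wins, else the alphabetically
  first code overall;
- a five-column structured output (`AntineoplasticMedication`,
  `AdditionalMedication`, `Medication`, `Study`, `Info`) appended to the
  verbatim input column;
- an evaluation module implementing the three-way outcome taxonomy
  (successfully transformed / error in transformation / no useful
  information) at entry and token level against gold annotations;
- a synthetic-fixture generator producing structurally valid toy
  dictionaries and gold-labelled corpora (the real WIdO ATC dictionary is
  licensed and not bundled).

## Worked example

```r
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
#>               Medication_freetext AntineoplasticMedication AdditionalMedication
#> 1                Methotrexat 15mg                  L01BA01
#> 2             5-FU (Fluorouracil)                  L01BC02
#> 3 Cisplatin + Ondansetron, Studie                  L01XA01              A04AA01
#>   Medication  Study Info
#> 1
#> 2
#> 3            Studie
```

Reading the output: Methotrexat carries two candidate codes (`L01BA01`
and the pseudo-code `M01CX0`); only the chapter-`L` code is retained. The
dose token `15MG` is stoplist noise. `5-FU` and `Fluorouracil` collapse
to one substance after RAD expansion and deduplication. Cisplatin (an
`L` code) and the antiemetic Ondansetron (`A04AA01`) separate into their
respective columns, and `Studie` is routed to the `Study` column instead
of being lost.

A command-line front end (`inst/cli/atcmap.R`, installed to
`system.file("cli", "atcmap.R", package = "atcmapr")`) wraps the same
functions with subcommands `standardize`, `evaluate`, `make-fixtures`
and `validate-dicts`.

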