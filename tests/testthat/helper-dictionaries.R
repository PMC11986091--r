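# Handcrafted tiny dictionaries used across the unit tests. The
# Methotrexate entry deliberately carries the six-character pseudo-code
# alongside its chapter-L code to exercise warn-and-keep loading and
# L-priority resolution.

tiny_atc <- function() {
  suppressWarnings(atc_dictionary(
    code = c("L01BA01", "M01CX0", "L01XA01", "L01BC02", "L01CB01",
             "V03AF03", "A04AA01", "L01DC03"),
    name = c("Methotrexat", "Methotrexat", "Cisplatin", "Fluorouracil",
             "Etoposid", "Calciumfolinat", "Ondansetron", "Mitomycin"),
    pattern = c("", "", "", "", "", "", "", "MITOMYC*")
  ))
}

tiny_rad <- function(atc = tiny_atc()) {
  rad_dictionary(
    key = c("5-FU", "FOLFOX", "Studie", "TACE",
            "best supportive care", "Neostat"),
    kind = c("EXPANSION", "EXPANSION", "STUDY", "INFO",
             "INFO", "MEDICATION"),
    payload = c("Fluorouracil",
                "Fluorouracil; Calciumfolinat; Etoposid",
                "Studie", "TACE", "best supportive care", "Neostat"),
    atc = atc
  )
}

# independent validity oracle: direct regex per level plus the letter set
oracle_valid_atc <- function(code) {
  rx <- c("^[A-Z]$", "^[A-Z][0-9]{2}$", "^[A-Z][0-9]{2}[A-Z]$",
          "^[A-Z][0-9]{2}[A-Z]{2}$", "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$")
  any(vapply(rx, grepl, logical(1), x = code)) &&
    substr(code, 1, 1) %in% c("A", "B", "C", "D", "G", "H", "J", "L",
                              "M", "N", "P", "R", "S", "V")
}

# independent resolution oracle: filter to the L subset when non-empty,
# then take the alphabetical minimum
oracle_resolve <- function(codes) {
  l <- grep("^L", codes, value = TRUE)
  sort(if (length(l) > 0) l else codes)[1]
}

record_matches_gold <- function(rec, gold_rec) {
  identical(rec$original_text, gold_rec$original_text) &&
    identical(rec$antineoplastic_medication,
              gold_rec$antineoplastic_medication) &&
    identical(rec$additional_medication, gold_rec$additional_medication) &&
    identical(rec$medication, gold_rec$medication) &&
    identical(rec$study, gold_rec$study) &&
    identical(rec$info, gold_rec$info)
}

random_free_text <- function(n) {
  pool <- c(letters, LETTERS, 0:9, "ä", "ö", "ü", "ß", "Ä", "Ö", "Ü",
            " ", "-", "+", "(", ")", ",", ".", "/", ";")
  vapply(seq_len(n), function(i) {
    paste(sample(pool, sample(0:30, 1), replace = TRUE), collapse = "")
  }, character(1))
}
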