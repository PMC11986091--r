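cfg_small <- function(n_entries = 80, ...) {
  synthetic_config(n_entries = n_entries, ...)
}

test_that("config rejects out-of-range probabilities and counts", {
  expect_error(synthetic_config(typo_rate = 1.2), "0, 1")
  expect_error(synthetic_config(regimen_fraction = -0.1), "0, 1")
  expect_error(synthetic_config(n_substances = 0), "positive")
})

test_that("toy ATC dictionary is structurally valid and L-dominated", {
  cfg <- cfg_small()
  atc <- build_toy_atc(cfg)
  expect_length(atc$entries, cfg$n_substances)
  codes <- unlist(atc$entries, use.names = FALSE)
  expect_true(all(validate_atc_code(codes)$valid))
  expect_true(all(validate_atc_code(codes)$level == 5L))
  frac_l <- mean(is_antineoplastic(names(atc$name_of)))
  expect_gt(frac_l, 0.5)
  expect_lt(frac_l, 0.9)
})

test_that("toy ATC dictionary contains a multi-code name mixing chapters", {
  atc <- build_toy_atc(cfg_small())
  sizes <- lengths(atc$entries)
  multi <- atc$entries[sizes >= 2L]
  expect_gte(length(multi), 1L)
  has_mixed <- any(vapply(multi, function(cs)
    any(is_antineoplastic(cs)) && any(!is_antineoplastic(cs)), logical(1)))
  expect_true(has_mixed)
})

test_that("generators are deterministic in the seed", {
  cfg <- cfg_small(seed = 4242)
  a1 <- build_toy_atc(cfg); a2 <- build_toy_atc(cfg)
  expect_identical(a1, a2)
  r1 <- build_toy_rad(a1, cfg); r2 <- build_toy_rad(a2, cfg)
  expect_identical(r1$entries, r2$entries)
  c1 <- generate_entries(a1, r1, cfg); c2 <- generate_entries(a2, r2, cfg)
  expect_identical(c1$entries, c2$entries)
  expect_identical(c1$gold, c2$gold)
  # a different seed changes the corpus
  cfg2 <- cfg_small(seed = 4243)
  c3 <- generate_entries(a1, r1, cfg2)
  expect_false(identical(c1$entries$Medication, c3$entries$Medication))
})

test_that("toy RAD covers regimens, abbreviations, aliases and routing keys", {
  cfg <- cfg_small()
  atc <- build_toy_atc(cfg)
  rad <- build_toy_rad(atc, cfg)
  kinds <- vapply(rad$entries, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "STUDY"), 3L)
  expect_true(all(c("STUDIE", "REGISTER", "PROTOKOLL") %in%
                    names(rad$entries)))
  expect_true(all(c("TACE", "CHEMOTHERAPIE", "ERHALTUNGSTHERAPIE") %in%
                    names(rad$entries)))
  expect_gte(sum(kinds == "EXPANSION"), cfg$n_regimens)
  # every expansion payload resolves in the toy ATC dictionary
  expect_length(rad$warnings, 0L)
  # the hyphenated alias normalized to a hyphen-free key
  meta <- attr(rad, "meta")
  alias_key <- normalize_key(meta$alias_surface)
  expect_false(grepl("-", alias_key, fixed = TRUE))
  expect_true(alias_key %in% names(rad$entries))
})

test_that("corpus entries hold 1-4 substance tokens with in-dictionary gold codes", {
  cfg <- cfg_small(seed = 99)
  atc <- build_toy_atc(cfg)
  rad <- build_toy_rad(atc, cfg)
  corpus <- generate_entries(atc, rad, cfg)
  expect_identical(nrow(corpus$entries), cfg$n_entries)
  code_rows <- corpus$gold[!grepl("^(STUDY|INFO):", corpus$gold$expected) &
                             corpus$gold$expected != "NAME_ONLY", ]
  per_entry <- table(code_rows$entry_id)
  expect_true(all(per_entry >= 1 & per_entry <= 4))
  all_codes <- unlist(atc$entries, use.names = FALSE)
  expect_true(all(code_rows$expected %in% all_codes))
})

test_that("gold records are consistent with the gold annotations", {
  cfg <- cfg_small(seed = 7)
  atc <- build_toy_atc(cfg)
  rad <- build_toy_rad(atc, cfg)
  corpus <- generate_entries(atc, rad, cfg)
  for (i in sample(seq_len(cfg$n_entries), 20)) {
    gr <- corpus$gold_records[[i]]
    rows <- corpus$gold[corpus$gold$entry_id == gr$entry_id, ]
    codes <- rows$expected[!grepl("^(STUDY|INFO):", rows$expected)]
    expect_setequal(c(gr$antineoplastic_medication,
                      gr$additional_medication), unique(codes))
    expect_identical(gr$original_text,
                     corpus$entries$Medication[i])
  }
})

test_that("typo corruption makes tokens unknown to both dictionaries", {
  cfg <- cfg_small(seed = 13, typo_rate = 0.5, n_entries = 60)
  atc <- build_toy_atc(cfg)
  rad <- build_toy_rad(atc, cfg)
  corpus <- generate_entries(atc, rad, cfg)
  failed <- corpus$gold[corpus$gold$expect_fail, ]
  expect_gt(nrow(failed), 0L)
  # the corrupted surface no longer matches anything: the pipeline must
  # miss exactly the expect_fail tokens
  out <- standardize(corpus$entries, atc, rad, column = "Medication")
  ev <- evaluate_standardization(out, corpus$gold)
  expect_identical(ev$token_counts$error_in_transformation, nrow(failed))
})

test_that("decoration fractions are realized within sampling error", {
  cfg <- synthetic_config(n_entries = 600, seed = 21,
                          study_fraction = 0.2, info_fraction = 0.15)
  atc <- build_toy_atc(cfg)
  rad <- build_toy_rad(atc, cfg)
  corpus <- generate_entries(atc, rad, cfg)
  n <- cfg$n_entries
  frac_study <- sum(startsWith(corpus$gold$expected, "STUDY:")) / n
  frac_info <- sum(startsWith(corpus$gold$expected, "INFO:")) / n
  expect_lt(abs(frac_study - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  expect_lt(abs(frac_info - 0.15), 3 * sqrt(0.15 * 0.85 / n))
})

test_that("generated text never crashes preprocessing", {
  for (seed in c(1, 2, 3, 4, 5)) {
    cfg <- synthetic_config(n_entries = 25, seed = seed, typo_rate = 0.3)
    atc <- build_toy_atc(cfg)
    rad <- build_toy_rad(atc, cfg)
    corpus <- generate_entries(atc, rad, cfg)
    prot <- protected_keys(atc, rad)
    for (txt in corpus$entries$Medication) {
      expect_no_error(preprocess_entry(txt, default_stoplist(), prot))
    }
  }
})

test_that("fixture directories are complete and reproducible", {
  cfg <- synthetic_config(n_entries = 15, seed = 314)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- make_fixtures(cfg, d1)
  fx2 <- make_fixtures(cfg, d2)
  expect_length(fx1$paths, 5L)
  for (nm in names(fx1$paths)) {
    expect_true(file.exists(fx1$paths[[nm]]))
    expect_identical(readLines(fx1$paths[[nm]]),
                     readLines(fx2$paths[[nm]]))
  }
  # the files round-trip through the production loaders
  atc <- load_atc_dictionary(fx1$paths$atc)
  rad <- load_rad(fx1$paths$rad, atc = atc)
  expect_identical(atc$entries, fx1$atc$entries)
  expect_identical(rad$entries, fx1$rad$entries)
  expect_identical(load_stoplist(fx1$paths$stoplist), fx1$stoplist)
  entries <- read_entries(fx1$paths$entries)
  expect_identical(entries$Medication, fx1$corpus$entries$Medication)
  gold <- load_gold(fx1$paths$gold)
  expect_identical(gold$expected, fx1$corpus$gold$expected)
})

test_that("an empty corpus still writes valid headed files", {
  cfg <- synthetic_config(n_entries = 0, seed = 1)
  d <- withr::local_tempdir()
  fx <- make_fixtures(cfg, d)
  entries <- utils::read.csv(fx$paths$entries, colClasses = "character")
  expect_identical(nrow(entries), 0L)
  expect_identical(names(entries), c("Medication", "entry_id"))
})
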