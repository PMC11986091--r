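make_record <- function(id, anti = character(0), addl = character(0),
                        med = character(0), study = character(0),
                        info = character(0), residual = character(0),
                        text = "x") {
  structure(list(entry_id = id, original_text = text,
                 antineoplastic_medication = anti,
                 additional_medication = addl, medication = med,
                 study = study, info = info, residual_tokens = residual),
            class = "standardized_record")
}

gold_rows <- function(id, token = character(0), expected = character(0)) {
  data.frame(entry_id = rep(id, length(token)), token = token,
             expected = expected, stringsAsFactors = FALSE)
}

test_that("entries are classified into the three-way taxonomy", {
  # expected code present -> success at both levels
  out <- classify_entry(make_record("1", anti = "L01BA01"),
                        gold_rows("1", "METHOTREXAT", "L01BA01"))
  expect_identical(out$bucket, "successfully_transformed")
  expect_identical(out$n_token_success, 1L)

  # one of two expected codes missing -> error, one failed token
  out <- classify_entry(make_record("2", anti = "L01XA01"),
                        gold_rows("2", c("CISPLATIN", "ETOPOSID"),
                                  c("L01XA01", "L01CB01")))
  expect_identical(out$bucket, "error_in_transformation")
  expect_identical(out$n_token_fail, 1L)
  expect_identical(out$failed_tokens, "ETOPOSID")

  # nothing expected, nothing produced -> no useful information
  out <- classify_entry(make_record("3"), gold_rows("3"))
  expect_identical(out$bucket, "no_useful_information")

  # nothing expected but side-channel content -> still useful
  out <- classify_entry(make_record("4", info = "TACE"), gold_rows("4"))
  expect_identical(out$bucket, "successfully_transformed")
  expect_true(out$has_additional_info)
})

test_that("expected codes satisfied by either code column count as success", {
  out <- classify_entry(make_record("1", addl = "A04AA01"),
                        gold_rows("1", "ONDANSETRON", "A04AA01"))
  expect_identical(out$bucket, "successfully_transformed")
})

test_that("entry_id mismatch between record and gold is a hard error", {
  expect_error(classify_entry(make_record("1"),
                              gold_rows("2", "X", "L01BA01")),
               "mismatch")
})

test_that("every entry lands in exactly one bucket", {
  recs <- list(make_record("1", anti = "L01BA01"),
               make_record("2"), make_record("3", study = "Studie"),
               make_record("4", anti = "L01XA01"))
  gold <- rbind(gold_rows("1", "METHOTREXAT", "L01BA01"),
                gold_rows("4", c("CISPLATIN", "ETOPOSID"),
                          c("L01XA01", "L01CB01")))
  ev <- evaluate_standardization(recs, gold)
  ec <- ev$entry_counts
  expect_identical(ec$successfully_transformed + ec$error_in_transformation +
                     ec$no_useful_information, ec$total)
  expect_identical(ec$total, 4L)
})

test_that("aggregation reproduces hand-computed rates to one decimal", {
  # 10 entries, 9 fully correct, 1 with a missed token
  recs <- c(lapply(1:9, function(i)
    make_record(as.character(i), anti = "L01BA01")),
    list(make_record("10", anti = character(0))))
  gold <- do.call(rbind, lapply(1:10, function(i)
    gold_rows(as.character(i), "METHOTREXAT", "L01BA01")))
  ev <- evaluate_standardization(recs, gold)
  expect_identical(ev$rates$entry_success_pct, 90.0)
  expect_identical(ev$rates$token_success_pct, 90.0)
  expect_identical(ev$entry_counts$error_in_transformation, 1L)
})

test_that("no-useful-information entries each count as one token", {
  recs <- list(make_record("1", anti = "L01BA01"), make_record("2"))
  gold <- gold_rows("1", "METHOTREXAT", "L01BA01")
  ev <- evaluate_standardization(recs, gold)
  expect_identical(ev$token_counts$total, 2L)
  expect_identical(ev$token_counts$no_useful_information, 1L)
  expect_identical(ev$rates$token_success_pct, 50.0)
})

test_that("token-level aggregates equal direct recomputation from outcomes", {
  set.seed(99)
  fx <- make_fixtures(synthetic_config(n_entries = 60, typo_rate = 0.3,
                                       seed = 777),
                      withr::local_tempdir())
  out <- standardize(fx$corpus$entries, fx$atc, fx$rad, fx$stoplist,
                     column = "Medication")
  ev <- evaluate_standardization(out, fx$corpus$gold)
  succ <- sum(vapply(ev$outcomes, `[[`, integer(1), "n_token_success"))
  fail <- sum(vapply(ev$outcomes, `[[`, integer(1), "n_token_fail"))
  expect_identical(ev$token_counts$successfully_transformed, succ)
  expect_identical(ev$token_counts$error_in_transformation, fail)
  buckets <- vapply(ev$outcomes, `[[`, character(1), "bucket")
  expect_identical(ev$entry_counts$successfully_transformed,
                   sum(buckets == "successfully_transformed"))
})

test_that("adding a correct RAD entry never lowers success rates", {
  atc <- tiny_atc()
  rad_small <- rad_dictionary("Studie", "STUDY", "Studie", atc = atc)
  rad_big <- rad_dictionary(c("Studie", "Cispla"),
                            c("STUDY", "EXPANSION"),
                            c("Studie", "Cisplatin"), atc = atc)
  texts <- c("Cispla 50mg", "Methotrexat", "Cisplatin Studie")
  gold <- rbind(gold_rows("1", "CISPLATIN", "L01XA01"),
                gold_rows("2", "METHOTREXAT", "L01BA01"),
                gold_rows("3", "CISPLATIN", "L01XA01"))
  ev_small <- evaluate_standardization(standardize(texts, atc, rad_small),
                                       gold)
  ev_big <- evaluate_standardization(standardize(texts, atc, rad_big), gold)
  expect_gte(ev_big$rates$token_success_pct,
             ev_small$rates$token_success_pct)
  expect_gte(ev_big$rates$entry_success_pct,
             ev_small$rates$entry_success_pct)
  expect_identical(ev_big$rates$token_success_pct, 100.0)
})

test_that("gold annotations referencing unknown entries are rejected", {
  recs <- list(make_record("1", anti = "L01BA01"))
  gold <- gold_rows("42", "METHOTREXAT", "L01BA01")
  expect_error(evaluate_standardization(recs, gold), "unknown entry_id")
})

test_that("evaluation reports serialize deterministically", {
  recs <- list(make_record("1", anti = "L01BA01"),
               make_record("2", study = "Studie"))
  gold <- gold_rows("1", "METHOTREXAT", "L01BA01")
  ev <- evaluate_standardization(recs, gold)
  j1 <- withr::local_tempfile(fileext = ".json")
  t1 <- withr::local_tempfile(fileext = ".txt")
  j2 <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(ev, j1, t1)
  write_evaluation_report(ev, j2)
  expect_identical(readLines(j1), readLines(j2))
  parsed <- jsonlite::read_json(j1)
  expect_equal(parsed$entry_counts$total, 2)
  expect_equal(parsed$n_entries_with_additional_info, 1)
  expect_true(any(grepl("Successfully transformed", readLines(t1))))
})
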