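test_that("generic completion: first day of month, or 1 January", {
  expect_equal(impute_generic(partial_date(2015, 6)), as.Date("2015-06-01"))
  expect_equal(impute_generic(partial_date(2015)), as.Date("2015-01-01"))
  expect_equal(impute_generic(partial_date(2015, 6, 11)),
               as.Date("2015-06-11"))
  expect_error(impute_generic(partial_date(NA)), "year")
})

test_that("drug starts never overlap the previous interval: end + 1 day", {
  r <- impute_drug_start(partial_date(2015, 6), as.Date("2015-06-10"))
  expect_equal(r$imputed, as.Date("2015-06-11"))
  expect_equal(r$strategy, "prev_interval")
  # no previous interval: plain first-day rule
  r <- impute_drug_start(partial_date(2015, 6))
  expect_equal(r$imputed, as.Date("2015-06-01"))
  # candidate already after the previous end: constraint inactive
  r <- impute_drug_start(partial_date(2015, 6), as.Date("2015-05-20"))
  expect_equal(r$imputed, as.Date("2015-06-01"))
  expect_equal(r$strategy, "generic")
  # shift contradicting the recorded year is flagged, candidate kept
  r <- impute_drug_start(partial_date(2016), as.Date("2016-12-31"))
  expect_true(r$conflict)
  expect_equal(r$imputed, as.Date("2016-01-01"))
  # complete dates pass through untouched with no strategy
  r <- impute_drug_start(partial_date(2015, 6, 11), as.Date("2015-06-10"))
  expect_equal(r$imputed, as.Date("2015-06-11"))
  expect_equal(r$strategy, "none")
})

test_that("lab dates anchor at drug initiation when the known parts agree", {
  tl <- reference_timeline(drug_initiation = as.Date("2015-06-15"),
                           drug_end = as.Date("2016-02-10"),
                           study_end = as.Date("2016-03-01"))
  r <- impute_lab_date(partial_date(2015, 6), "DRUG INITIATION", tl)
  expect_equal(r$imputed, as.Date("2015-06-15"))
  expect_equal(r$strategy, "reference_comparison")
  # disagreeing month falls through to generic completion
  r <- impute_lab_date(partial_date(2015, 7), "DRUG INITIATION", tl)
  expect_equal(r$imputed, as.Date("2015-07-01"))
  expect_equal(r$strategy, "generic")
})

test_that("last-available lab dates take min(drug end, study end)", {
  tl <- reference_timeline(drug_end = as.Date("2016-02-10"),
                           study_end = as.Date("2016-03-01"))
  r <- impute_lab_date(NULL, "LAST AVAILABLE", tl)
  expect_equal(r$imputed, as.Date("2016-02-10"))
  # the study end can be the earlier bound
  tl2 <- reference_timeline(drug_end = as.Date("2016-05-10"),
                            study_end = as.Date("2016-03-01"))
  expect_equal(impute_lab_date(NULL, "LAST AVAILABLE", tl2)$imputed,
               as.Date("2016-03-01"))
  # complete input is the identity
  r <- impute_lab_date(partial_date(2016, 3, 4), "LAST AVAILABLE", tl)
  expect_equal(r$imputed, as.Date("2016-03-04"))
  expect_equal(r$strategy, "none")
  # no year, no applicable anchor: unresolvable
  r <- impute_lab_date(NULL, "UNKNOWN LABEL", reference_timeline())
  expect_true(is.na(r$imputed))
})

test_that("death dates: completeness first, then the source hierarchy", {
  # fewer missing parts wins regardless of source rank
  cand <- death_candidates(c("crf_death_details", "crf_fatal_ae"),
                           partial_date(c(2016, 2016), c(3, 3),
                                        c(NA, 15)))
  r <- impute_death_date(cand, as.Date("2016-01-01"))
  expect_equal(r$imputed, as.Date("2016-03-15"))
  # equal completeness: CRF death details > fatal AE > safety database
  cand <- death_candidates(c("safety_db", "crf_death_details"),
                           partial_date(c(2016, 2016), c(4, 3)))
  r <- impute_death_date(cand, NULL)
  expect_equal(r$imputed, as.Date("2016-03-01"))
  expect_match(r$note, "crf_death_details")
})

test_that("imputed partial death dates are floored at last available information", {
  cand <- death_candidates(c("crf_death_details", "safety_db"),
                           partial_date(c(2016, 2016), c(3, 4)))
  r <- impute_death_date(cand, as.Date("2016-03-20"))
  expect_equal(r$imputed, as.Date("2016-03-20"))
  expect_match(r$note, "floored")
  # a recorded complete date is never moved by the floor
  cand <- death_candidates("crf_death_details", partial_date(2016, 3, 5))
  r <- impute_death_date(cand, as.Date("2016-03-20"))
  expect_equal(r$imputed, as.Date("2016-03-05"))
})

test_that("with no usable candidate the date of last available information is used", {
  empty <- death_candidates(character(0), partial_date(integer(0)))
  r <- impute_death_date(empty, as.Date("2016-05-02"))
  expect_equal(r$imputed, as.Date("2016-05-02"))
  yearless <- death_candidates("safety_db", partial_date(NA))
  expect_equal(impute_death_date(yearless, as.Date("2016-05-02"))$imputed,
               as.Date("2016-05-02"))
  expect_error(impute_death_date(empty, NULL), "cannot place death")
})

test_that("death-date selection is invariant under candidate permutations", {
  set.seed(7)
  src <- c("crf_death_details", "crf_fatal_ae", "safety_db", "crf_fatal_ae")
  pd <- partial_date(c(2016, 2016, 2016, 2016), c(3, NA, 4, 3),
                     c(NA, NA, 2, 14))
  cand <- death_candidates(src, pd)
  base <- impute_death_date(cand, as.Date("2016-01-01"))
  for (i in 1:10) {
    perm <- sample(nrow(cand))
    r <- impute_death_date(cand[perm, ], as.Date("2016-01-01"))
    expect_equal(r$imputed, base$imputed)
    expect_equal(r$strategy, base$strategy)
  }
})

test_that("timepoint labels resolve through the configured anchor table", {
  tl <- reference_timeline(last_available_info = as.Date("2016-05-02"),
                           enrollment = as.Date("2015-01-10"))
  expect_equal(impute_by_timepoint("BEFORE DISCONTINUATION", tl),
               as.Date("2016-05-02"))
  expect_equal(impute_by_timepoint("WITHIN 3 MONTHS OF BASELINE", tl),
               as.Date("2015-01-10"))
  expect_null(impute_by_timepoint("UNKNOWN LABEL", tl))
  # configured offsets shift the anchor
  tp <- list("T1" = list(anchor = "enrollment", offset_days = 14L))
  expect_equal(impute_by_timepoint("T1", tl, tp), as.Date("2015-01-24"))
})

test_that("imputing an already-complete date is the identity with no strategy", {
  r <- impute_lab_date(partial_date(2016, 3, 4), NA_character_,
                       reference_timeline())
  expect_equal(r$strategy, "none")
  r2 <- impute_drug_start(partial_date(2016, 3, 4))
  expect_equal(r2$strategy, "none")
})
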