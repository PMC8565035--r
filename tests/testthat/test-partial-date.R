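test_that("ISO-8601 prefixes parse to the right components", {
  pd <- parse_partial_date(c("2016", "2015-06", "2015-06-11"))
  expect_equal(pd$year, c(2016L, 2015L, 2015L))
  expect_equal(pd$month, c(NA, 6L, 6L))
  expect_equal(pd$day, c(NA, NA, 11L))
  expect_false(any(attr(pd, "failed")))
})

test_that("non-conforming strings are parse failures carrying the verbatim text", {
  bad <- c("2016-02-30", "15 Jun 2016", "06/11/2015", "2016-13", "20160611",
           "junk")
  pd <- parse_partial_date(bad)
  expect_true(all(attr(pd, "failed")))
  expect_true(all(is.na(pd$year)))
  expect_identical(attr(pd, "verbatim"), bad)
  # blank is absence, not failure
  blank <- parse_partial_date(c("", NA))
  expect_false(any(attr(blank, "failed")))
})

test_that("constructor enforces the component-dependency invariants", {
  expect_error(partial_date(2015, NA, 11), "day present")
  expect_error(partial_date(NA, 6), "month present")
  expect_error(partial_date(2015, 13), "out of range")
  expect_error(partial_date(2015, 2, 30), "invalid calendar")
})

test_that("parse(format(p)) is the identity over generated partial dates", {
  set.seed(42)
  for (i in 1:200) {
    y <- sample(1900:2099, 1)
    m <- if (runif(1) < 0.3) NA_integer_ else sample(1:12, 1)
    d <- if (is.na(m) || runif(1) < 0.3) NA_integer_ else
      sample(1:28, 1)
    p <- partial_date(y, m, d)
    q <- parse_partial_date(format(p))
    expect_equal(q$year, p$year)
    expect_equal(q$month, p$month)
    expect_equal(q$day, p$day)
  }
})

test_that("missing-component counts drive completeness helpers", {
  pd <- partial_date(c(2015, 2015, 2015, NA), c(6, 6, NA, NA),
                     c(11, NA, NA, NA))
  expect_equal(pd_n_missing(pd), c(0L, 1L, 2L, 3L))
  expect_equal(pd_complete(pd), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(as.Date(pd)[1], as.Date("2015-06-11"))
  expect_true(all(is.na(as.Date(pd)[2:4])))
})

test_that("free-text date extraction recognises the documented dialects", {
  # expected values computed by hand from the dialect definitions
  expect_equal(format(extract_date_from_text("dose changed 2015-06-11 per chart")),
               "2015-06-11")
  expect_equal(format(extract_date_from_text("seen Jan 2016")), "2016-01")
  expect_equal(format(extract_date_from_text("started 15 Jun 2016")),
               "2016-06-15")
  expect_equal(format(extract_date_from_text("visit on 06/11/2015")),
               "2015-06-11")
  expect_equal(format(extract_date_from_text("around 2014-03")), "2014-03")
  expect_equal(format(extract_date_from_text("sometime in 2014")), "2014")
  expect_true(is.na(extract_date_from_text("patient stable")$year))
  # an impossible calendar date in text is not a date
  expect_true(is.na(extract_date_from_text("noted 2015-02-30 here")$day))
  # record identifiers are not years
  expect_true(is.na(extract_date_from_text("sample A2015X batch")$year))
})
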