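test_that("a study directory loads one table per domain, DM required", {
  st <- local_study(list(
    DM = dm_row("P1"),
    AE = data.frame(USUBJID = "P1", AESEQ = 1, AEPTCD = "10038435",
                    AEDECOD = "Renal impairment", AESTDTC = "2015-06",
                    AEENDTC = "", AESEV = "MODERATE", AEREL = "NO",
                    AEOUT = "")))
  expect_s3_class(st, "study_dataset")
  expect_named(st$tables, c("AE", "DM"), ignore.order = TRUE)

  dir <- withr::local_tempdir()
  utils::write.csv(dm_row("P1")[, -1], file.path(dir, "AE.csv"),
                   row.names = FALSE)
  expect_error(read_study(dir), "DM")
})

test_that("unknown domain files load as generic domains with a warning", {
  dir <- withr::local_tempdir()
  utils::write.csv(dm_row("P1"), file.path(dir, "DM.csv"), row.names = FALSE)
  utils::write.csv(data.frame(USUBJID = "P1", ZZSEQ = 1, ZZDECOD = "thing",
                              ZZSTDTC = "2015-01-02"),
                   file.path(dir, "ZZ.csv"), row.names = FALSE)
  expect_warning(st <- read_study(dir), "ZZ")
  expect_true("ZZ" %in% names(st$tables))
  rec <- as_sdtm_records(st)
  expect_equal(rec$vocab[rec$domain == "ZZ"], "free-text")
})

test_that("normalised records carry ISO prefixes, occur flags and keys verbatim", {
  st <- local_study(list(
    DM = dm_row("P1"),
    AE = data.frame(USUBJID = "P1", AESEQ = c(1, 2), AEPTCD = "10038435",
                    AEDECOD = "Renal impairment",
                    AESTDTC = c("2015-06", "not a date"), AEENDTC = "",
                    AESEV = "", AEREL = "", AEOUT = ""),
    MH = data.frame(USUBJID = "P1", MHSEQ = 1, MHPTCD = "10020772",
                    MHDECOD = "Hypertension", MHOCCUR = "N", MHSTDTC = "")))
  rec <- as_sdtm_records(st)
  ae1 <- rec[rec$domain == "AE" & rec$seq == 1, ]
  pd <- parse_partial_date(ae1$start_raw)
  expect_equal(pd$year, 2015L)
  expect_equal(pd$month, 6L)
  expect_true(is.na(pd$day))
  # unparseable date strings stay verbatim, flagged, never dropped
  ae2 <- rec[rec$domain == "AE" & rec$seq == 2, ]
  expect_equal(ae2$start_raw, "not a date")
  expect_true(attr(parse_partial_date(ae2$start_raw), "failed"))
  expect_equal(rec$occur_flag[rec$domain == "MH"], "N")
  expect_false(anyDuplicated(rec_key <- paste(rec$patient_id, rec$domain,
                                              rec$seq)) > 0)
})

test_that("write_study(read_study(d)) round-trips every field value", {
  gen <- generate_registry(registry_config(n_patients = 15, seed = 3))
  d1 <- withr::local_tempdir()
  write_study(gen$study, d1)
  st2 <- read_study(d1, gen$mapping_config)
  for (dom in names(gen$study$tables)) {
    a <- gen$study$tables[[dom]]
    b <- st2$tables[[dom]]
    for (col in names(a))
      expect_identical(as.character(a[[col]]), as.character(b[[col]]),
                       info = paste(dom, col))
  }
  expect_identical(sort(st2$violator_ids), sort(gen$study$violator_ids))
  # write -> read -> write reaches a byte-stable fixed point
  d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  write_study(st2, d2)
  write_study(read_study(d2, gen$mapping_config), d3)
  for (f in setdiff(list.files(d2), "VIOLATORS.csv"))
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d3, f)), info = f)
})

test_that("config overrides redirect variable-name conventions", {
  cfg <- mapping_config(var_overrides = list(AE = list(start = "AEDAT")))
  expect_equal(domain_var("AE", "start", cfg), "AEDAT")
  expect_equal(domain_var("AE", "end", cfg), "AEENDTC")
  st <- local_study(list(
    DM = dm_row("P1"),
    AE = data.frame(USUBJID = "P1", AESEQ = 1, AEPTCD = "10038435",
                    AEDECOD = "x", AEDAT = "2016-02-01", AEENDTC = "")),
    config = cfg)
  rec <- as_sdtm_records(st, cfg)
  expect_equal(rec$start_raw[rec$domain == "AE"], "2016-02-01")
})
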