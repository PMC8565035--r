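test_that("redundancy percentages round to the nearest whole percent", {
  expect_equal(redundancy_pct(10659, 3698), 65L)
  expect_equal(redundancy_pct(4013, 2704), 33L)
  expect_equal(redundancy_pct(449, 337), 25L)
  expect_equal(redundancy_pct(100, 100), 0L)
  expect_true(is.na(redundancy_pct(0, 0)))
})

test_that("redundancy is scale-invariant", {
  set.seed(5)
  for (i in 1:50) {
    b <- sample(1:500, 1)
    a <- b + sample(0:500, 1)
    k <- sample(2:9, 1)
    expect_equal(redundancy_pct(k * a, k * b), redundancy_pct(a, b))
  }
})

test_that("exclusion accounting reproduces n and percent to one decimal", {
  r <- exclusion_accounting(2722, 46, 2)
  expect_equal(r$n_mapped, 2674)
  expect_equal(r$pct_mapped, 98.2)
  r <- exclusion_accounting(3142, 85, 25)
  expect_equal(r$n_mapped, 3032)
  expect_equal(r$pct_mapped, 96.5)
  r <- exclusion_accounting(10, 0, 0)
  expect_equal(r$n_mapped, 10)
  expect_equal(r$pct_mapped, 100.0)
  expect_error(exclusion_accounting(10, 8, 5), "ledger corruption")
})

test_that("aggregation sums per-registry counts element-wise", {
  mk <- function(recs, cdm) qa_counts("condition", 10, 5, 1, recs, cdm, recs)
  reports <- list(mk(128858, 62048), mk(41960, 41993), mk(28347, 4616))
  tot <- aggregate_counts(reports)
  expect_equal(tot$n_unique_source_records, 199165)
  expect_equal(tot$n_unique_cdm_records, 108657)
  empty <- aggregate_counts(list())
  expect_equal(empty$n_unique_source_records, 0)
  mixed <- list(mk(1, 1), qa_counts("drug", 1, 1, 0, 1, 1, 1))
  expect_error(aggregate_counts(mixed), "mixed")
})

test_that("demographics agree between SDTM and CDM sides on a mapped study", {
  gen <- generate_registry(registry_config(n_patients = 30, seed = 9))
  cdm <- map_study(gen$study, test_store(), gen$mapping_config)
  cc <- consistency_check(gen$study, cdm, gen$mapping_config)
  expect_length(cc$flags, 0)
  expect_lt(abs(cc$table["sdtm", "mean"] - cc$table["cdm", "mean"]), 0.01)
  expect_equal(cc$gender["sdtm", ], cc$gender["cdm", ])
  # an injected fault (deleted person row) is flagged
  cdm2 <- cdm
  cdm2$person <- cdm2$person[-1, ]
  cc2 <- consistency_check(gen$study, cdm2, gen$mapping_config)
  expect_gt(length(cc2$flags), 0)
})

test_that("QA counts recomputed from written CDM files match the in-memory report", {
  gen <- generate_registry(registry_config(n_patients = 25, seed = 13))
  cdm <- map_study(gen$study, test_store(), gen$mapping_config)
  dir <- withr::local_tempdir()
  write_cdm(cdm, dir)
  # distinct event rows per table, re-read from disk
  for (tb in names(cdm$tables)) {
    back <- utils::read.csv(file.path(dir, paste0(toupper(tb), ".csv")))
    expect_equal(nrow(back), nrow(cdm$tables[[tb]]), info = tb)
  }
  death <- utils::read.csv(file.path(dir, "DEATH.csv"))
  expect_equal(nrow(death), nrow(cdm$death))
  facts <- utils::read.csv(file.path(dir, "FACT_RELATIONSHIP.csv"))
  expect_equal(nrow(facts), nrow(cdm$fact_relationship))
})
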