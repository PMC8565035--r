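test_that("sample selection excludes violators, duplicates and data-missing patients", {
  dm <- rbind(dm_row("P1"), dm_row("P2", birth = ""), dm_row("P3"),
              dm_row("P3"), dm_row("P4"))
  ex <- data.frame(USUBJID = c("P1", "P2", "P3", "P4"), EXSEQ = 1,
                   EXPTCD = "000001", EXDECOD = "MACITENTAN",
                   EXSTDTC = c("2015-02-01", "2015-02-01", "2015-02-01", ""),
                   EXENDTC = c("2015-05-01", "2015-05-01", "2015-05-01", ""))
  st <- local_study(list(DM = dm, EX = ex), violators = "P1")
  sel <- select_sample(st)
  expect_setequal(sel$retained_ids, "P3")
  expect_equal(sel$report$n_in_database, 5)
  expect_equal(sel$report$n_violators, 1)
  # duplicate row + missing birth year + missing treatment dates
  expect_equal(sel$report$n_mapping_excluded, 3)
  expect_equal(sel$report$n_mapped, 1)
  expect_setequal(
    sel$log$reason[sel$log$patient_id == "P2"], "missing_birth_year")
  expect_setequal(
    sel$log$reason[sel$log$patient_id == "P4"], "missing_treatment_dates")
  expect_true("duplicate_record" %in%
                sel$log$reason[sel$log$patient_id == "P3"])
  # the accounting identity holds by construction
  expect_equal(sel$report$n_mapped,
               sel$report$n_in_database - sel$report$n_violators -
                 sel$report$n_mapping_excluded)
})

test_that("non-occurrence and not-done records are dropped with reasons", {
  recs <- data.frame(patient_id = "P1", domain = c("AE", "MH", "MH", "LB"),
                     seq = 1:4, occur_flag = c("Y", "N", "U", NA),
                     status_flag = c(NA, NA, NA, "NOT DONE"))
  fne <- filter_non_events(recs)
  expect_equal(nrow(fne$kept), 1)
  expect_equal(fne$kept$domain, "AE")
  expect_equal(fne$dropped$reason, c("not_occurred", "unknown", "not_done"))
})

test_that("routing fans out one event row per resolved concept", {
  store <- test_store()
  rec <- list(patient_id = "P1", domain = "AE", seq = 1L,
              value_chr = NA_character_, unit = NA_character_,
              source_value = "10057688")
  res <- resolve_source(store, "MedDRA", "10057688")
  rows <- route_record(rec, res, store, person_id = 1L,
                       start_date = as.Date("2015-06-11"))
  expect_equal(nrow(rows), length(res$concept_ids))
  expect_setequal(rows$concept_id, c(4249456, 4183956))
  expect_true(all(rows$table == "condition_occurrence"))
  # the MedDRA classification concept rides along only as source_concept_id
  expect_true(all(rows$source_concept_id == 35000001))
  # empty resolution emits nothing
  none <- route_record(rec, list(concept_ids = numeric(),
                                 source_concept_id = NA_real_),
                       store, 1L, as.Date("2015-06-11"))
  expect_equal(nrow(none), 0)
  # measurements carry numeric results
  mrec <- list(patient_id = "P1", domain = "XP", seq = 2L,
               value_chr = "48", unit = "mmHg", source_value = "MPAP")
  mres <- resolve_source(store, "SDTM-TEST", "MPAP")
  mrow <- route_record(mrec, mres, store, 1L, as.Date("2015-02-01"))
  expect_equal(mrow$table, "measurement")
  expect_equal(mrow$value_as_number, 48)
})

test_that("characteristics attach as observations with mirrored fact pairs", {
  store <- test_store()
  rec <- list(patient_id = "P1", domain = "AE", seq = 1L,
              value_chr = NA_character_, unit = NA_character_,
              source_value = "10038435")
  event <- route_record(rec, resolve_source(store, "MedDRA", "10038435"),
                        store, 1L, as.Date("2015-06-11"), uid_base = 0L)
  at <- attach_characteristic(event[1, ], 4022772, 4285732, uid_base = 1L)
  expect_equal(at$observation$concept_id, 4022772)
  expect_equal(at$observation$value_as_concept_id, 4285732)
  expect_equal(at$observation$start_date, event$start_date)
  expect_equal(nrow(at$facts), 2)
  # forward and inverse rows mirror each other
  expect_equal(at$facts$uid_1, rev(at$facts$uid_2))
  expect_equal(at$facts$table_1, rev(at$facts$table_2))
  expect_equal(unique(at$facts$relationship_concept_id), 1147900)
})

test_that("disposition records map to config-chosen observation concepts", {
  store <- test_store()
  cfg <- mapping_config(study_id = "OPUS")
  base <- list(patient_id = "P1", domain = "DS", seq = 1L,
               value_chr = NA_character_)
  enr <- map_disposition(c(base, term = "ENROLLMENT"), store, cfg, 1L,
                         as.Date("2015-01-10"))
  expect_equal(enr$concept_id, 44807982)
  expect_equal(enr$value_as_string, "OPUS")
  cons <- map_disposition(c(base, term = "INFORMED CONSENT"), store, cfg, 1L,
                          as.Date("2015-01-10"))
  expect_equal(cons$concept_id, 44811375)
  wd <- map_disposition(c(list(patient_id = "P1", domain = "DS", seq = 3L,
                               value_chr = "other reason"),
                          term = "WITHDRAWN"), store, cfg, 1L,
                        as.Date("2016-01-10"))
  expect_equal(wd$concept_id, 44810920)
  expect_equal(wd$value_as_concept_id, 45885208)
  # the alternative concept set is a config choice
  cfg2 <- mapping_config(disposition = list(enrollment = 4090379,
                                            consent = 4163733,
                                            completed = 40482840,
                                            withdrawn = 4087907))
  expect_equal(map_disposition(c(base, term = "ENROLLMENT"), store, cfg2, 1L,
                               as.Date("2015-01-10"))$concept_id, 4090379)
  expect_null(map_disposition(c(base, term = "SOMETHING ELSE"), store, cfg,
                              1L, as.Date("2015-01-10")))
})

test_that("outcomes become linked observations; fatal outcomes divert to death", {
  store <- test_store()
  event <- .event_row(1L, 1L, "condition_occurrence", 4000053,
                      as.Date("2016-03-15"), patient_id = "P1",
                      domain = "AE", seq = 1L)
  out <- map_outcome(event, "RECOVERED", store, uid_base = 1L)
  expect_equal(out$observation$concept_id, 4231813)
  expect_equal(out$observation$value_as_concept_id, 4000301)
  expect_equal(nrow(out$facts), 2)
  expect_identical(map_outcome(event, "FATAL", store), "fatal")
  expect_null(map_outcome(event, NA_character_, store))
})

test_that("observation periods span first to last event, extended by death", {
  ev <- rbind(
    .event_row(1L, 1L, "observation", 44807982, as.Date("2015-01-10"),
               patient_id = "P1", domain = "DS", seq = 1L),
    .event_row(2L, 1L, "condition_occurrence", 4000053,
               as.Date("2016-05-02"), patient_id = "P1", domain = "AE",
               seq = 1L),
    .event_row(3L, 2L, "observation", 44807982, as.Date("2015-03-01"),
               patient_id = "P2", domain = "DS", seq = 1L))
  per <- derive_observation_period(ev)
  expect_equal(per$observation_period_start_date,
               as.Date(c("2015-01-10", "2015-03-01")))
  expect_equal(per$observation_period_end_date,
               as.Date(c("2016-05-02", "2015-03-01")))  # zero-length allowed
  death <- data.frame(person_id = 1L, death_date = as.Date("2016-07-01"))
  per2 <- derive_observation_period(ev, death)
  expect_equal(per2$observation_period_end_date[per2$person_id == 1],
               as.Date("2016-07-01"))
})
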