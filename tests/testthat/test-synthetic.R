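test_that("identical config and seed produce byte-identical output files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_registry(registry_config(n_patients = 25, seed = 7), d1)
  generate_registry(registry_config(n_patients = 25, seed = 7), d2)
  expect_setequal(list.files(d1), list.files(d2))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})

test_that("retrospective registries capture only occurred conditions", {
  gen <- generate_registry(registry_config(n_patients = 60,
                                           design = "retrospective",
                                           rate_non_occurrence = 0.5,
                                           seed = 5))
  mh <- gen$study$tables$MH
  expect_false(any(mh$MHOCCUR %in% c("N", "U")))
  lb <- gen$study$tables$LB
  expect_false(any(lb$LBSTAT == "NOT DONE"))
  expect_equal(sum(gen$ledger$records$status == "non_event"), 0)
})

test_that("prospective non-occurrence rows appear at the configured rate", {
  gen <- generate_registry(registry_config(n_patients = 300, seed = 21,
                                           rate_non_occurrence = 0.4))
  mh <- gen$study$tables$MH
  checklist <- mh[mh$MHPTCD != "", ]
  p_hat <- mean(checklist$MHOCCUR %in% c("N", "U"))
  n <- nrow(checklist)
  # binomial tolerance: 4 standard errors around the configured rate
  expect_lt(abs(p_hat - 0.4), 4 * sqrt(0.4 * 0.6 / n))
})

test_that("the ledger is internally consistent with the emitted tables", {
  gen <- generate_registry(registry_config(n_patients = 80, seed = 3,
                                           death_rate = 0.15))
  recs <- gen$ledger$records
  pats <- gen$ledger$patients
  # death count: DD rows in the study match ledger death records for
  # retained patients
  dd <- gen$study$tables$DD
  retained <- pats$patient_id[pats$retained]
  expect_equal(nrow(recs[recs$domain == "DD", ]),
               sum(dd$USUBJID %in% retained))
  expect_setequal(unique(recs$patient_id), retained)
  # every ledger record exists in the study tables
  for (dom in unique(recs$domain)) {
    tab <- gen$study$tables[[dom]]
    keys_tab <- paste(tab$USUBJID, tab[[paste0(dom, "SEQ")]])
    sub <- recs[recs$domain == dom, ]
    expect_true(all(paste(sub$patient_id, sub$seq) %in% keys_tab),
                info = dom)
  }
  # violators are flagged in the study and carry no ledger rows
  expect_setequal(gen$study$violator_ids,
                  pats$patient_id[pats$violator])
})

test_that("every dictionary entry resolves to exactly its declared targets", {
  store <- test_store()
  dict <- mini_dictionary()
  check <- function(vocab, code, targets) {
    want <- as.numeric(strsplit(targets, ";")[[1]])
    got <- resolve_source(store, vocab, code)$concept_ids
    if (identical(want, 0)) expect_length(got, 0)
    else expect_equal(sort(got), sort(want), info = code)
  }
  for (i in seq_len(nrow(dict$conditions)))
    check("MedDRA", dict$conditions$code[i], dict$conditions$targets[i])
  for (i in seq_len(nrow(dict$condition_texts)))
    check("free-text", dict$condition_texts$text[i],
          dict$condition_texts$targets[i])
  for (i in seq_len(nrow(dict$drugs)))
    check("WHODrug", dict$drugs$code[i], dict$drugs$targets[i])
  for (i in seq_len(nrow(dict$drug_texts)))
    check("free-text", dict$drug_texts$text[i], dict$drug_texts$targets[i])
  for (i in seq_len(nrow(dict$tests)))
    check("SDTM-TEST", dict$tests$testcd[i], dict$tests$targets[i])
})
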