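#' @title Synthetic SDTM registry generator
#' @description
#' Emits a structurally realistic SDTM-style registry study together with a
#' ground-truth ledger that records, per generated record, its true date,
#' whether it is a non-occurrence row, a duplicate, a protocol violator's or
#' deliberately unmappable -- enabling exact expected-value computation for
#' every pipeline stage via [expected_qa()]. Content is clinically arbitrary
#' by design: the generator exercises data mechanics (partial dates,
#' free-text dates, conflicting death sources, checklist non-occurrence),
#' not disease epidemiology.
#'
#' Determinism: one seeded substream per (patient, domain), with a fixed
#' field draw order inside each, so identical config+seed give identical
#' output files.
#' @name synthetic_registry
NULL

#' Generator configuration
#'
#' Rates are per-record (or per-patient where noted) probabilities.
#' `rate_non_occurrence` applies to prospective checklist items and
#' not-done lab rows only; retrospective registries capture only occurred
#' conditions, so it is ignored there.
#'
#' @param n_patients number of patients.
#' @param design `"prospective"` or `"retrospective"`.
#' @param seed integer RNG seed.
#' @param rate_missing_day probability a written date lacks its day.
#' @param rate_missing_month_day probability it lacks day and month.
#' @param rate_fully_missing_date probability it is absent entirely (also
#'   drives missing birth years, hence mapping exclusions).
#' @param rate_non_occurrence probability a prospective checklist item is a
#'   non-occurrence/not-done row.
#' @param rate_duplicates probability a patient's DM record is duplicated.
#' @param rate_violators probability a patient is a flagged protocol
#'   violator.
#' @param death_rate probability a patient dies during the study.
#' @param rate_conflicting_death_sources probability a death is recorded in
#'   more than one source with conflicting dates.
#' @param rate_free_text probability a code or date is entered as free text.
#' @return object of class `registry_config`.
#' @export
registry_config <- function(n_patients = 500L,
                            design = c("prospective", "retrospective"),
                            seed = 1L,
                            rate_missing_day = 0.10,
                            rate_missing_month_day = 0.05,
                            rate_fully_missing_date = 0.02,
                            rate_non_occurrence = 0.50,
                            rate_duplicates = 0.01,
                            rate_violators = 0.02,
                            death_rate = 0.08,
                            rate_conflicting_death_sources = 0.30,
                            rate_free_text = 0.10) {
  design <- match.arg(design)
  rates <- c(rate_missing_day, rate_missing_month_day,
             rate_fully_missing_date, rate_non_occurrence, rate_duplicates,
             rate_violators, death_rate, rate_conflicting_death_sources,
             rate_free_text)
  stopifnot(all(rates >= 0 & rates <= 1), n_patients >= 1)
  structure(list(n_patients = as.integer(n_patients), design = design,
                 seed = as.integer(seed),
                 rate_missing_day = rate_missing_day,
                 rate_missing_month_day = rate_missing_month_day,
                 rate_fully_missing_date = rate_fully_missing_date,
                 rate_non_occurrence = rate_non_occurrence,
                 rate_duplicates = rate_duplicates,
                 rate_violators = rate_violators,
                 death_rate = death_rate,
                 rate_conflicting_death_sources =
                   rate_conflicting_death_sources,
                 rate_free_text = rate_free_text),
            class = "registry_config")
}

#' Miniature source-code dictionary
#'
#' The coded terms, free-text entries, test codes and timepoint labels the
#' generator draws from, each cross-referenced to its expected standard
#' target(s) in the bundled vocabulary (targets `0` mark deliberately
#' unmappable values). A test asserts that every entry resolves through the
#' bundled crosswalk to exactly these targets, so the ledger's expectations
#' and the vocabulary fixture cannot drift apart.
#' @return list of data frames: `conditions`, `condition_texts`, `drugs`,
#'   `drug_texts`, `tests`, plus `timepoints`.
#' @export
mini_dictionary <- function() {
  list(
    conditions = data.frame(
      code = c("10057688", "10038435", "10020772", "10003658",
               "10013968", "10012727", "10099991", "10099992"),
      name = c("Catheter site discharge", "Renal impairment",
               "Hypertension", "Atrial fibrillation", "Dyspnoea",
               "Diabetes mellitus", "Investigator text A",
               "Investigator text B"),
      targets = c("4249456;4183956", "4030518", "4000050", "4000051",
                  "4000052", "4000053", "0", "0"),
      stringsAsFactors = FALSE),
    condition_texts = data.frame(
      text = c("drug- and toxin-induced PAH",
               "PAH associated with connective tissue disease",
               "PAH associated with congenital heart disease",
               "pulmonary hypertension",
               "unclassifiable investigator narrative"),
      targets = c("2000000001", "4000010;4000030", "4000010;4000040",
                  "4322024", "0"),
      stringsAsFactors = FALSE),
    drugs = data.frame(
      code = c("000001", "000002", "000003", "000099"),
      name = c("MACITENTAN", "SELEXIPAG", "SILDENAFIL", "UNCODED COMPOUND"),
      targets = c("4000101", "4000102", "4000103", "0"),
      stringsAsFactors = FALSE),
    drug_texts = data.frame(
      text = c("macitentan tablets", "investigational prostacyclin analogue",
               "herbal supplement unspecified"),
      targets = c("4000101", "2000000005", "0"),
      stringsAsFactors = FALSE),
    tests = data.frame(
      domain = c("LB", "LB", "VS", "XP", "XP"),
      testcd = c("NTPROBNP", "CREAT", "SYSBP", "MPAP", "WHOFC"),
      unit = c("pg/mL", "mg/dL", "mmHg", "mmHg", ""),
      targets = c("3029435", "3016723", "3004249", "3028074", "2000000010"),
      stringsAsFactors = FALSE),
    timepoints = c("DRUG INITIATION", "LAST AVAILABLE")
  )
}

# seeded substream per (seed, key); fixed draw order inside a key
substream <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  set.seed(as.integer(h))
}

# write a true date under the missingness ladder; returns the string plus
# how many fields an imputation pass will have to complete (0 or 1)
.write_date <- function(true_date, cfg, allow_missing = TRUE) {
  u <- stats::runif(1)
  full <- cfg$rate_fully_missing_date
  md <- cfg$rate_missing_month_day
  d <- cfg$rate_missing_day
  if (allow_missing && u < full)
    return(list(text = "", n_imp = 1L, missing = TRUE))
  if (u < full + md)
    return(list(text = format(true_date, "%Y"), n_imp = 1L, missing = FALSE))
  if (u < full + md + d)
    return(list(text = format(true_date, "%Y-%m"), n_imp = 1L,
                missing = FALSE))
  list(text = format(true_date, "%Y-%m-%d"), n_imp = 0L, missing = FALSE)
}

# render a complete date as free text in one of the recognised dialects
.free_text_date <- function(true_date) {
  pick <- ceiling(stats::runif(1) * 3)
  body <- switch(pick,
    format(true_date, "%Y-%m-%d"),
    format(true_date, "%d %b %Y"),
    format(true_date, "%m/%d/%Y"))
  sprintf("noted %s in chart", body)
}

#' Generate a synthetic registry study
#'
#' @param config a [registry_config()].
#' @param dir_path optional; when given, the study (domain CSVs plus
#'   VIOLATORS.csv) and the ledger are also written there.
#' @return list with `study` (a `study_dataset`), `ledger` (list of data
#'   frames `records` and `patients`), `mapping_config` (the matching
#'   [mapping_config()]) and `config`.
#' @export
generate_registry <- function(config = registry_config(), dir_path = NULL) {
  stopifnot(inherits(config, "registry_config"))
  dict <- mini_dictionary()
  seed <- config$seed
  prospective <- config$design == "prospective"
  study_end <- as.Date("2019-12-31")

  tabs <- list(DM = list(), AE = list(), CM = list(), EX = list(),
               LB = list(), MH = list(), VS = list(), XP = list(),
               DS = list(), DD = list(), CE = list())
  led_rec <- list(); led_pat <- list()
  violators <- character(0)

  add_rec <- function(p, dom, seq, category, vocab, code, true_date,
                      non_event = FALSE, mappable = TRUE, targets = "0",
                      n_imp = 0L, undatable = FALSE, violator = FALSE,
                      status = NULL) {
    if (is.null(status))
      status <- if (violator) "excluded"
        else if (non_event) "non_event"
        else if (undatable) "undatable"
        else if (!mappable) "unmapped" else "mapped"
    led_rec[[length(led_rec) + 1L]] <<- data.frame(
      patient_id = p, domain = dom, seq = seq, category = category,
      vocab = vocab, code = code,
      true_date = if (is.null(true_date)) "" else format(true_date),
      status = status, targets = if (status == "mapped") targets else "0",
      n_targets = if (status == "mapped" && targets != "0")
        length(strsplit(targets, ";")[[1]]) else 0L,
      n_imputed_fields = if (status %in% c("mapped", "unmapped")) n_imp
        else 0L,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(config$n_patients)) {
    p <- sprintf("P%04d", i)

    ## -- patient-level draws (order: violator, duplicate, missing birth,
    ##    death, conflicting sources)
    substream(seed, paste0(p, ":patient"))
    is_viol <- stats::runif(1) < config$rate_violators
    is_dup <- stats::runif(1) < config$rate_duplicates
    birth_missing <- stats::runif(1) < config$rate_fully_missing_date
    dies <- stats::runif(1) < config$death_rate
    conflict <- dies &&
      stats::runif(1) < config$rate_conflicting_death_sources
    has_fatal_ae <- dies && stats::runif(1) < 0.5
    sex <- if (stats::runif(1) < 0.7) "F" else "M"
    birth_year <- 1935L + floor(stats::runif(1) * 50)
    enroll <- as.Date("2015-01-01") + floor(stats::runif(1) * 700)
    death_date <- if (dies) enroll + 300 + floor(stats::runif(1) * 300)
      else NULL
    if (!is.null(death_date) && death_date > study_end)
      death_date <- study_end

    if (is_viol) violators <- c(violators, p)
    retained <- !is_viol && !birth_missing
    led_pat[[length(led_pat) + 1L]] <- data.frame(
      patient_id = p, violator = is_viol, dup_rows = as.integer(is_dup),
      missing_birth = birth_missing, retained = retained, dies = dies,
      stringsAsFactors = FALSE)

    dm_row <- data.frame(
      USUBJID = p,
      BRTHDTC = if (birth_missing) "" else sprintf("%d", birth_year),
      SEX = sex, RFSTDTC = format(enroll), COUNTRY = "US",
      stringsAsFactors = FALSE)
    tabs$DM[[length(tabs$DM) + 1L]] <- dm_row
    if (is_dup) tabs$DM[[length(tabs$DM) + 1L]] <- dm_row

    track <- retained  # only retained patients' records enter the ledger

    ## -- EX: two intervals of the study drug ---------------------------------
    substream(seed, paste0(p, ":EX"))
    e1_end <- enroll + 90
    i2_partial <- stats::runif(1) < 2 * config$rate_missing_day
    e2_start <- e1_end + 20
    e2_end_w <- .write_date(min(e2_start + 180, study_end), config,
                            allow_missing = TRUE)
    tabs$EX[[length(tabs$EX) + 1L]] <- data.frame(
      USUBJID = p, EXSEQ = 1L, EXPTCD = "000001", EXDECOD = "MACITENTAN",
      EXSTDTC = format(enroll), EXENDTC = format(e1_end),
      stringsAsFactors = FALSE)
    tabs$EX[[length(tabs$EX) + 1L]] <- data.frame(
      USUBJID = p, EXSEQ = 2L, EXPTCD = "000001", EXDECOD = "MACITENTAN",
      EXSTDTC = if (i2_partial) format(e2_start, "%Y-%m")
                else format(e2_start),
      EXENDTC = e2_end_w$text, stringsAsFactors = FALSE)
    if (track) {
      add_rec(p, "EX", 1L, "drug", "WHODrug", "000001", enroll,
              targets = "4000101")
      add_rec(p, "EX", 2L, "drug", "WHODrug", "000001", e2_start,
              targets = "4000101",
              n_imp = as.integer(i2_partial) + e2_end_w$n_imp -
                as.integer(e2_end_w$missing))
    }

    ## -- AE ------------------------------------------------------------------
    substream(seed, paste0(p, ":AE"))
    n_ae <- floor(stats::runif(1) * 3)
    aeseq <- 0L
    for (j in seq_len(n_ae)) {
      aeseq <- aeseq + 1L
      k <- ceiling(stats::runif(1) * nrow(dict$conditions))
      cond <- dict$conditions[k, ]
      true_d <- enroll + 30 + floor(stats::runif(1) * 400)
      ft_date <- stats::runif(1) < config$rate_free_text
      w <- if (ft_date) list(text = .free_text_date(true_d), n_imp = 1L,
                             missing = FALSE)
           else .write_date(true_d, config)
      sev <- c("MILD", "MODERATE", "SEVERE")[ceiling(stats::runif(1) * 3)]
      rel <- c("YES", "NO", "POSSIBLE", "UNLIKELY")[
        ceiling(stats::runif(1) * 4)]
      ou <- stats::runif(1)
      outc <- if (ou < 1 / 3) "RECOVERED" else if (ou < 2 / 3)
        "NOT RECOVERED" else ""
      tabs$AE[[length(tabs$AE) + 1L]] <- data.frame(
        USUBJID = p, AESEQ = aeseq, AEPTCD = cond$code,
        AEDECOD = cond$name, AESTDTC = w$text, AEENDTC = "", AESEV = sev,
        AEREL = rel, AEOUT = outc, stringsAsFactors = FALSE)
      if (track)
        add_rec(p, "AE", aeseq, "condition", "MedDRA", cond$code, true_d,
                mappable = cond$targets != "0", targets = cond$targets,
                n_imp = w$n_imp, undatable = w$missing)
    }
    if (has_fatal_ae) {
      aeseq <- aeseq + 1L
      tabs$AE[[length(tabs$AE) + 1L]] <- data.frame(
        USUBJID = p, AESEQ = aeseq, AEPTCD = "10012727",
        AEDECOD = "Diabetes mellitus", AESTDTC = format(death_date),
        AEENDTC = "", AESEV = "SEVERE", AEREL = "NO", AEOUT = "FATAL",
        stringsAsFactors = FALSE)
      if (track)
        add_rec(p, "AE", aeseq, "condition", "MedDRA", "10012727",
                death_date, targets = "4000053")
    }

    ## -- CM ------------------------------------------------------------------
    substream(seed, paste0(p, ":CM"))
    n_cm <- floor(stats::runif(1) * 3)
    for (j in seq_len(n_cm)) {
      true_d <- enroll + floor(stats::runif(1) * 400)
      as_text <- stats::runif(1) < config$rate_free_text
      if (as_text) {
        k <- ceiling(stats::runif(1) * nrow(dict$drug_texts))
        dt <- dict$drug_texts[k, ]
        w <- .write_date(true_d, config)
        tabs$CM[[length(tabs$CM) + 1L]] <- data.frame(
          USUBJID = p, CMSEQ = j, CMPTCD = "", CMDECOD = dt$text,
          CMSTDTC = w$text, CMENDTC = "", stringsAsFactors = FALSE)
        if (track)
          add_rec(p, "CM", j, "drug", "free-text", normalize_text(dt$text),
                  true_d, mappable = dt$targets != "0", targets = dt$targets,
                  n_imp = w$n_imp, undatable = w$missing)
      } else {
        k <- ceiling(stats::runif(1) * nrow(dict$drugs))
        dg <- dict$drugs[k, ]
        w <- .write_date(true_d, config)
        tabs$CM[[length(tabs$CM) + 1L]] <- data.frame(
          USUBJID = p, CMSEQ = j, CMPTCD = dg$code, CMDECOD = dg$name,
          CMSTDTC = w$text, CMENDTC = "", stringsAsFactors = FALSE)
        if (track)
          add_rec(p, "CM", j, "drug", "WHODrug", dg$code, true_d,
                  mappable = dg$targets != "0", targets = dg$targets,
                  n_imp = w$n_imp, undatable = w$missing)
      }
    }

    ## -- MH: condition checklist (+ occasional free-text history) ------------
    substream(seed, paste0(p, ":MH"))
    checklist <- dict$conditions[2:5, ]
    mhseq <- 0L
    for (j in seq_len(nrow(checklist))) {
      cond <- checklist[j, ]
      true_d <- enroll - 200 - floor(stats::runif(1) * 1000)
      u_occ <- stats::runif(1)
      if (prospective) {
        non_occ <- u_occ < config$rate_non_occurrence
        occ <- if (!non_occ) "Y" else if (u_occ <
          config$rate_non_occurrence * 0.8) "N" else "U"
        mhseq <- mhseq + 1L
        w <- .write_date(true_d, config, allow_missing = FALSE)
        tabs$MH[[length(tabs$MH) + 1L]] <- data.frame(
          USUBJID = p, MHSEQ = mhseq, MHPTCD = cond$code,
          MHDECOD = cond$name, MHOCCUR = occ, MHSTDTC = w$text,
          stringsAsFactors = FALSE)
        if (track)
          add_rec(p, "MH", mhseq, "condition", "MedDRA", cond$code, true_d,
                  non_event = non_occ, mappable = cond$targets != "0",
                  targets = cond$targets,
                  n_imp = if (non_occ) 0L else w$n_imp)
      } else {
        # retrospective charts record only conditions that occurred
        occurred <- u_occ < 0.5
        if (occurred) {
          mhseq <- mhseq + 1L
          w <- .write_date(true_d, config, allow_missing = FALSE)
          tabs$MH[[length(tabs$MH) + 1L]] <- data.frame(
            USUBJID = p, MHSEQ = mhseq, MHPTCD = cond$code,
            MHDECOD = cond$name, MHOCCUR = "", MHSTDTC = w$text,
            stringsAsFactors = FALSE)
          if (track)
            add_rec(p, "MH", mhseq, "condition", "MedDRA", cond$code,
                    true_d, mappable = cond$targets != "0",
                    targets = cond$targets, n_imp = w$n_imp)
        }
      }
    }
    if (stats::runif(1) < config$rate_free_text) {
      k <- ceiling(stats::runif(1) * nrow(dict$condition_texts))
      ct <- dict$condition_texts[k, ]
      mhseq <- mhseq + 1L
      tabs$MH[[length(tabs$MH) + 1L]] <- data.frame(
        USUBJID = p, MHSEQ = mhseq, MHPTCD = "", MHDECOD = ct$text,
        MHOCCUR = if (prospective) "Y" else "", MHSTDTC = format(enroll),
        stringsAsFactors = FALSE)
      if (track)
        add_rec(p, "MH", mhseq, "condition", "free-text",
                normalize_text(ct$text), enroll,
                mappable = ct$targets != "0", targets = ct$targets)
    }

    ## -- LB ------------------------------------------------------------------
    substream(seed, paste0(p, ":LB"))
    lbseq <- 0L
    for (tst in c("NTPROBNP", "CREAT")) {
      trow <- dict$tests[dict$tests$testcd == tst, ]
      lbseq <- lbseq + 1L
      not_done <- prospective &&
        stats::runif(1) < config$rate_non_occurrence / 2
      tp <- if (tst == "NTPROBNP") "DRUG INITIATION" else "LAST AVAILABLE"
      true_d <- if (tst == "NTPROBNP") enroll else
        enroll + 200 + floor(stats::runif(1) * 100)
      w <- .write_date(true_d, config)
      val <- round(stats::runif(1) * 300 + 20, 1)
      tabs$LB[[length(tabs$LB) + 1L]] <- data.frame(
        USUBJID = p, LBSEQ = lbseq, LBTESTCD = tst,
        LBORRES = if (not_done) "" else format(val),
        LBORRESU = trow$unit,
        LBDTC = if (not_done) "" else w$text, LBTPT = tp,
        LBSTAT = if (not_done) "NOT DONE" else "",
        stringsAsFactors = FALSE)
      if (track)
        add_rec(p, "LB", lbseq, "finding", "SDTM-TEST", tst, true_d,
                non_event = not_done, targets = trow$targets,
                n_imp = if (not_done) 0L else w$n_imp)
    }

    ## -- VS ------------------------------------------------------------------
    substream(seed, paste0(p, ":VS"))
    tabs$VS[[length(tabs$VS) + 1L]] <- data.frame(
      USUBJID = p, VSSEQ = 1L, VSTESTCD = "SYSBP",
      VSORRES = format(round(stats::runif(1) * 60 + 100)),
      VSORRESU = "mmHg", VSDTC = format(enroll + 14),
      stringsAsFactors = FALSE)
    if (track)
      add_rec(p, "VS", 1L, "finding", "SDTM-TEST", "SYSBP", enroll + 14,
              targets = "3004249")

    ## -- XP: disease-specific haemodynamics and functional class -------------
    substream(seed, paste0(p, ":XP"))
    mpap <- round(stats::runif(1) * 40 + 25)
    fc <- c("I", "II", "III", "IV")[ceiling(stats::runif(1) * 4)]
    tabs$XP[[length(tabs$XP) + 1L]] <- data.frame(
      USUBJID = p, XPSEQ = 1L, XPTESTCD = "MPAP", XPORRES = format(mpap),
      XPMETHOD = "THERMODILUTION", XPDTC = format(enroll + 7),
      stringsAsFactors = FALSE)
    tabs$XP[[length(tabs$XP) + 1L]] <- data.frame(
      USUBJID = p, XPSEQ = 2L, XPTESTCD = "WHOFC", XPORRES = fc,
      XPMETHOD = "", XPDTC = format(enroll + 7), stringsAsFactors = FALSE)
    if (track) {
      add_rec(p, "XP", 1L, "finding", "SDTM-TEST", "MPAP", enroll + 7,
              targets = "3028074")
      add_rec(p, "XP", 2L, "finding", "SDTM-TEST", "WHOFC", enroll + 7,
              targets = "2000000010")
    }

    ## -- CE: hospitalizations ------------------------------------------------
    substream(seed, paste0(p, ":CE"))
    if (stats::runif(1) < 0.1) {
      hosp_d <- enroll + 60 + floor(stats::runif(1) * 200)
      tabs$CE[[length(tabs$CE) + 1L]] <- data.frame(
        USUBJID = p, CESEQ = 1L, CEDECOD = "hospitalization",
        CESTDTC = format(hosp_d), CEENDTC = format(hosp_d + 5),
        stringsAsFactors = FALSE)
      if (track)
        add_rec(p, "CE", 1L, "condition", "free-text", "hospitalization",
                hosp_d, targets = "9201")
    }

    ## -- DS ------------------------------------------------------------------
    substream(seed, paste0(p, ":DS"))
    withdrawn <- stats::runif(1) < 0.2
    final_d <- min(enroll + 540, study_end)
    if (dies) final_d <- min(final_d, death_date)
    tabs$DS[[length(tabs$DS) + 1L]] <- data.frame(
      USUBJID = p, DSSEQ = 1L, DSDECOD = "ENROLLMENT", DSORRES = "",
      DSSTDTC = format(enroll), stringsAsFactors = FALSE)
    tabs$DS[[length(tabs$DS) + 1L]] <- data.frame(
      USUBJID = p, DSSEQ = 2L, DSDECOD = "INFORMED CONSENT", DSORRES = "",
      DSSTDTC = format(enroll), stringsAsFactors = FALSE)
    tabs$DS[[length(tabs$DS) + 1L]] <- data.frame(
      USUBJID = p, DSSEQ = 3L,
      DSDECOD = if (withdrawn) "WITHDRAWN" else "COMPLETED",
      DSORRES = if (withdrawn) "other reason" else "",
      DSSTDTC = format(final_d), stringsAsFactors = FALSE)
    if (track) {
      add_rec(p, "DS", 1L, "disposition", "", "ENROLLMENT", enroll,
              targets = "1")
      add_rec(p, "DS", 2L, "disposition", "", "INFORMED CONSENT", enroll,
              targets = "1")
      add_rec(p, "DS", 3L, "disposition", "",
              if (withdrawn) "WITHDRAWN" else "COMPLETED", final_d,
              targets = "1")
    }

    ## -- DD ------------------------------------------------------------------
    if (dies) {
      substream(seed, paste0(p, ":DD"))
      w <- .write_date(death_date, config, allow_missing = FALSE)
      tabs$DD[[length(tabs$DD) + 1L]] <- data.frame(
        USUBJID = p, DDSEQ = 1L, DDDTC = w$text,
        DDORRES = "pulmonary hypertension", DDSRC = "CRF",
        stringsAsFactors = FALSE)
      if (track)
        add_rec(p, "DD", 1L, "death", "", "CRF", death_date,
                targets = "0", status = "death")
      if (conflict) {
        w2 <- .write_date(death_date + 7, config, allow_missing = FALSE)
        tabs$DD[[length(tabs$DD) + 1L]] <- data.frame(
          USUBJID = p, DDSEQ = 2L, DDDTC = w2$text,
          DDORRES = "pulmonary hypertension", DDSRC = "SAFETY",
          stringsAsFactors = FALSE)
        if (track)
          add_rec(p, "DD", 2L, "death", "", "SAFETY", death_date + 7,
                  targets = "0", status = "death")
      }
    }
  }

  tables <- lapply(tabs, function(rows)
    if (length(rows)) do.call(rbind, rows) else NULL)
  tables <- tables[!vapply(tables, is.null, logical(1))]

  mcfg <- mapping_config(study_id = sprintf("SYN-%s-%d",
                                            toupper(substr(config$design, 1,
                                                           4)),
                                            config$seed),
                         design = config$design,
                         study_end_date = format(study_end))
  study <- structure(list(study_id = mcfg$study_id, design = config$design,
                          study_end_date = mcfg$study_end_date,
                          tables = tables, violator_ids = violators),
                     class = "study_dataset")
  ledger <- list(records = do.call(rbind, led_rec),
                 patients = do.call(rbind, led_pat))
  rownames(ledger$records) <- rownames(ledger$patients) <- NULL

  if (!is.null(dir_path)) {
    write_study(study, dir_path)
    utils::write.csv(ledger$records, file.path(dir_path, "ledger_records.csv"),
                     row.names = FALSE)
    utils::write.csv(ledger$patients, file.path(dir_path,
                                                "ledger_patients.csv"),
                     row.names = FALSE)
  }
  list(study = study, ledger = ledger, mapping_config = mcfg,
       config = config)
}

#' Expected quality-assessment figures from a generator ledger
#'
#' Recomputes, from the ground truth alone, every count the pipeline's
#' [qa_report()] must reproduce on the generated study: the exclusion
#' accounting, the record-fate tallies, and the per-category unique source
#' value / concept / record counts. This is pure ledger arithmetic,
#' independent of the transformation code.
#'
#' @param gen the list returned by [generate_registry()].
#' @return list with `exclusion`, `records`, `condition`, `drug` and
#'   `n_date_imputations` (death-date audits excluded: they are counted by
#'   the pipeline separately).
#' @export
expected_qa <- function(gen) {
  pats <- gen$ledger$patients
  recs <- gen$ledger$records

  n_db <- nrow(pats) + sum(pats$dup_rows)
  n_viol <- sum(pats$violator * (1L + pats$dup_rows))
  n_dup_nonviol <- sum(pats$dup_rows[!pats$violator])
  n_missing <- sum(!pats$violator & pats$missing_birth)
  exclusion <- list(
    n_in_database = n_db,
    n_violators = n_viol,
    n_mapping_excluded = n_dup_nonviol + n_missing,
    n_mapped = sum(pats$retained))

  records <- list(
    n_records = nrow(recs),
    n_mapped = sum(recs$status %in% c("mapped", "death")),
    n_non_event = sum(recs$status == "non_event"),
    n_unmapped = sum(recs$status == "unmapped"),
    n_undatable = sum(recs$status == "undatable"))

  per_cat <- function(domains) {
    sub <- recs[recs$domain %in% domains, , drop = FALSE]
    coded <- sub[sub$code != "", , drop = FALSE]
    src_vals <- unique(paste(coded$vocab, coded$code))
    mapped <- sub[sub$status == "mapped", , drop = FALSE]
    targets <- unique(unlist(strsplit(mapped$targets[mapped$targets != "0"],
                                      ";")))
    targets <- as.numeric(targets)
    list(n_unique_source_values = length(src_vals),
         n_unique_concept_ids = length(targets),
         n_unique_custom_concept_ids = sum(targets >= CUSTOM_ID_BASE),
         n_unique_source_records = nrow(sub),
         n_unique_cdm_records = sum(mapped$n_targets),
         n_unique_source_records_mapped = nrow(mapped))
  }

  list(exclusion = exclusion, records = records,
       condition = per_cat(.qa_condition_domains),
       drug = per_cat(.qa_drug_domains),
       n_date_imputations = sum(recs$n_imputed_fields))
}
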