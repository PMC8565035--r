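#' @title Study-level transformation pipeline
#' @description
#' [map_study()] runs the whole transformation for one study: sample
#' selection, reference-timeline construction, non-event filtering, date
#' completion, source-to-standard resolution, domain routing, fact linking,
#' death-date reconciliation and observation-period derivation. The result
#' is a `cdm_result` holding the OMOP tables, the four logs and the
#' exclusion report. Identical inputs and config produce identical output.
#' @name pipeline
NULL

rec_key <- function(p, d, s) paste(p, d, s, sep = "\r")

first_non_na <- function(...) {
  for (x in list(...)) if (!is.null(x) && !is.na(x)) return(x)
  NA_character_
}

#' Transform a study dataset into OMOP CDM tables
#'
#' @param study a `study_dataset` from [read_study()].
#' @param store a `vocabulary_store` from [load_vocabulary()].
#' @param config a [mapping_config()].
#' @return An object of class `cdm_result`: list with `person`,
#'   `observation_period`, `events` (internal all-event frame with
#'   provenance), `tables` (OMOP-format frames), `death`,
#'   `fact_relationship`, `logs` (exclusion, non_event, unmapped, undatable,
#'   imputation), `exclusion_report` and `record_status` (one row per source
#'   record with its fate).
#' @export
map_study <- function(study, store, config = mapping_config()) {
  stopifnot(inherits(study, "study_dataset"),
            inherits(store, "vocabulary_store"))
  lint_vocabulary(store)
  rel_to_drug <- register_custom_concept(store, "Relationship to study drug",
                                         "Observation")
  if (store$closure_stale) refresh_closure(store)

  sel <- select_sample(study, config)

  ## ---- PERSON -------------------------------------------------------------
  dm <- study$tables$DM
  dm <- dm[!duplicated(dm), , drop = FALSE]
  dm <- dm[dm$USUBJID %in% sel$retained_ids, , drop = FALSE]
  dm <- dm[order(dm$USUBJID), , drop = FALSE]
  sex <- toupper(dm[[dm_var("sex", config)]] %||% rep("", nrow(dm)))
  birth <- parse_partial_date(dm[[dm_var("birth", config)]] %||%
                              rep("", nrow(dm)))
  gc <- .gender_concepts[sex]
  gc[is.na(gc)] <- 0
  person <- data.frame(person_id = seq_len(nrow(dm)),
                       gender_concept_id = unname(gc),
                       year_of_birth = birth$year,
                       gender_source_value = sex,
                       person_source_value = dm$USUBJID,
                       stringsAsFactors = FALSE)
  pid_of <- stats::setNames(person$person_id, person$person_source_value)

  enroll_pd <- parse_partial_date(dm[[dm_var("enroll", config)]] %||%
                                  rep("", nrow(dm)))
  enroll_date <- as.Date(enroll_pd)
  names(enroll_date) <- dm$USUBJID

  study_end <- NULL
  if (!is.null(config$study_end_date))
    study_end <- impute_generic(config$study_end_date)

  records <- as_sdtm_records(study, config)
  records <- records[records$patient_id %in% sel$retained_ids, , drop = FALSE]

  ## ---- audit / log accumulators -------------------------------------------
  audit <- list(); undatable <- list(); unmapped <- list()
  add_audit <- function(p, d, s, field, orig, imp, strategy, note) {
    audit[[length(audit) + 1L]] <<- data.frame(
      patient_id = p, domain = d, seq = s, field = field,
      original = ifelse(is.na(orig), "", orig), imputed = format(imp),
      strategy = strategy, note = note, stringsAsFactors = FALSE)
  }
  add_undatable <- function(p, d, s, reason) {
    undatable[[length(undatable) + 1L]] <<- data.frame(
      patient_id = p, domain = d, seq = s, reason = reason,
      stringsAsFactors = FALSE)
  }
  add_unmapped <- function(p, d, s, vocab, code) {
    unmapped[[length(unmapped) + 1L]] <<- data.frame(
      patient_id = p, domain = d, seq = s,
      vocab = ifelse(is.na(vocab), "", vocab),
      source_value = ifelse(is.na(code), "", code), stringsAsFactors = FALSE)
  }

  ## ---- EX drug intervals (previous-interval rule) -------------------------
  ex_dates <- new.env(parent = emptyenv())
  ex_recs <- records[records$domain == "EX", , drop = FALSE]
  for (p in unique(ex_recs$patient_id)) {
    prow <- ex_recs[ex_recs$patient_id == p, , drop = FALSE]
    for (code in unique(prow$code)) {
      grp <- prow[is.na(prow$code) == is.na(code) &
                  (is.na(code) | prow$code %in% code), , drop = FALSE]
      grp <- grp[order(grp$seq), , drop = FALSE]
      prev_end <- NULL
      for (i in seq_len(nrow(grp))) {
        r <- grp[i, ]
        st_pd <- parse_partial_date(r$start_raw %||% "")
        if (attr(st_pd, "failed")[1])
          st_pd <- extract_date_from_text(r$start_raw)
        start <- as.Date(NA)
        if (!is.na(st_pd$year)) {
          if (pd_complete(st_pd)) {
            start <- as.Date(st_pd)
          } else {
            res <- impute_drug_start(st_pd[1], prev_end)
            start <- res$imputed
            add_audit(p, "EX", r$seq, "start", format(st_pd), start,
                      res$strategy, res$note)
          }
        }
        en_pd <- parse_partial_date(r$end_raw %||% "")
        end <- as.Date(NA)
        if (!is.na(en_pd$year)) {
          if (pd_complete(en_pd)) {
            end <- as.Date(en_pd)
          } else {
            end <- impute_generic(en_pd[1])
            add_audit(p, "EX", r$seq, "end", format(en_pd), end, "generic",
                      "first-day completion")
          }
        }
        ex_dates[[rec_key(p, "EX", r$seq)]] <- list(start = start, end = end)
        if (!is.na(end)) prev_end <- end
        else if (!is.na(start)) prev_end <- start
      }
    }
  }

  ## ---- reference timelines ------------------------------------------------
  pr_start <- parse_partial_date(records$start_raw)
  pr_end <- parse_partial_date(records$end_raw)
  raw_dates <- c(as.Date(pr_start), as.Date(pr_end))
  raw_pid <- c(records$patient_id, records$patient_id)
  not_dd <- rep(records$domain != "DD", 2)
  ok <- !is.na(raw_dates) & not_dd
  lai_tab <- tapply(raw_dates[ok], raw_pid[ok], max)

  timelines <- new.env(parent = emptyenv())
  for (p in sel$retained_ids) {
    di <- de <- NULL
    keys <- ls(ex_dates)
    pk <- keys[startsWith(keys, paste0(p, "\r"))]
    if (length(pk)) {
      starts <- Reduce(c, lapply(pk, function(k) ex_dates[[k]]$start))
      ends <- Reduce(c, lapply(pk, function(k) ex_dates[[k]]$end))
      if (any(!is.na(starts))) di <- min(starts, na.rm = TRUE)
      if (any(!is.na(ends))) de <- max(ends, na.rm = TRUE)
      else if (!is.null(di) && any(!is.na(starts)))
        de <- max(starts, na.rm = TRUE)
    }
    lai <- c(if (p %in% names(lai_tab))
               as.Date(as.vector(lai_tab[[p]]), origin = "1970-01-01"),
             if (!is.na(enroll_date[p] %||% NA)) enroll_date[[p]])
    lai <- if (length(lai)) max(lai) else NULL
    if (!is.null(lai) && !is.null(study_end) && lai > study_end)
      lai <- study_end
    timelines[[p]] <- reference_timeline(
      patient_id = p, drug_initiation = di, drug_end = de,
      last_available_info = lai, study_end = study_end,
      enrollment = if (!is.na(enroll_date[p] %||% NA)) enroll_date[[p]]
                   else NULL)
  }

  ## ---- non-event filtering ------------------------------------------------
  fne <- filter_non_events(records)
  kept <- fne$kept
  non_event_log <- fne$dropped[, c("patient_id", "domain", "seq", "reason")]

  ## ---- death reconciliation -----------------------------------------------
  death_rows <- list()
  dd_recs <- kept[kept$domain == "DD", , drop = FALSE]
  fatal_ae <- kept[kept$domain == "AE" &
                   toupper(kept$outcome %||% "") %in% "FATAL", , drop = FALSE]
  death_patients <- sort(unique(c(dd_recs$patient_id, fatal_ae$patient_id)))
  dd_status <- character(0)
  for (p in death_patients) {
    src <- character(0); y <- m <- d <- integer(0)
    pdd <- dd_recs[dd_recs$patient_id == p, , drop = FALSE]
    for (i in seq_len(nrow(pdd))) {
      pd_i <- parse_partial_date(pdd$start_raw[i] %||% "")
      src <- c(src, if (toupper(pdd$source[i] %||% "CRF") == "SAFETY")
                      "safety_db" else "crf_death_details")
      y <- c(y, pd_i$year); m <- c(m, pd_i$month); d <- c(d, pd_i$day)
    }
    pfa <- fatal_ae[fatal_ae$patient_id == p, , drop = FALSE]
    for (i in seq_len(nrow(pfa))) {
      pd_i <- parse_partial_date(pfa$start_raw[i] %||% "")
      src <- c(src, "crf_fatal_ae")
      y <- c(y, pd_i$year); m <- c(m, pd_i$month); d <- c(d, pd_i$day)
    }
    cand <- data.frame(source = factor(src, levels = c(
      "crf_death_details", "crf_fatal_ae", "safety_db")),
      year = y, month = m, day = d)
    tl <- timelines[[p]]
    res <- tryCatch(impute_death_date(cand, tl$last_available_info),
                    error = function(e) NULL)
    if (is.null(res)) {
      for (i in seq_len(nrow(pdd)))
        add_undatable(p, "DD", pdd$seq[i], "death_unplaceable")
      dd_status[rec_key(p, "DD", pdd$seq)] <- "undatable"
      next
    }
    add_audit(p, "DD", if (nrow(pdd)) pdd$seq[1] else NA_integer_, "death",
              res$original, res$imputed, res$strategy, res$note)
    cause_cid <- NA_real_; cause_src <- NA_character_
    if (nrow(pdd) && !is.na(pdd$value_chr[1])) {
      cause_src <- pdd$value_chr[1]
      cres <- resolve_source(store, "free-text", cause_src)
      if (length(cres$concept_ids)) cause_cid <- cres$concept_ids[1]
    }
    death_rows[[p]] <- data.frame(person_id = unname(pid_of[p]),
                                  death_date = res$imputed,
                                  cause_concept_id = cause_cid,
                                  cause_source_value = cause_src %||%
                                    NA_character_,
                                  stringsAsFactors = FALSE)
    if (nrow(pdd)) dd_status[rec_key(p, "DD", pdd$seq)] <- "death"
  }
  death <- if (length(death_rows)) do.call(rbind, death_rows) else
    data.frame(person_id = integer(), death_date = as.Date(character()),
               cause_concept_id = numeric(), cause_source_value = character())
  rownames(death) <- NULL

  ## ---- date completion + resolution + routing -----------------------------
  uid_n <- 0L
  next_uid <- function(k = 1L) {
    uid_n <<- uid_n + k
    uid_n - k
  }
  ev_list <- list(); fact_list <- list()
  res_cache <- new.env(parent = emptyenv())
  resolve_cached <- function(vocab, code) {
    key <- paste(vocab, code, sep = "\r")
    if (is.null(res_cache[[key]]))
      res_cache[[key]] <- resolve_source(store, vocab, code)
    res_cache[[key]]
  }
  status <- list()
  add_status <- function(p, d, s, st, n_rows = 0L) {
    status[[length(status) + 1L]] <<- data.frame(
      patient_id = p, domain = d, seq = s, status = st, n_rows = n_rows,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(non_event_log)))
    add_status(non_event_log$patient_id[i], non_event_log$domain[i],
               non_event_log$seq[i], "non_event")

  work <- kept[kept$domain != "DD", , drop = FALSE]
  for (i in seq_len(nrow(work))) {
    rec <- as.list(work[i, ])
    p <- rec$patient_id; dom <- rec$domain; s <- rec$seq
    tl <- timelines[[p]]
    is_finding <- dom %in% .finding_domains

    ## -- complete the record date
    start <- end <- as.Date(NA)
    if (dom == "EX") {
      ed <- ex_dates[[rec_key(p, "EX", s)]]
      if (!is.null(ed)) { start <- ed$start; end <- ed$end }
      if (is.na(start)) {
        add_undatable(p, dom, s, "undatable"); add_status(p, dom, s, "undatable")
        next
      }
    } else if (is_finding) {
      pd_s <- parse_partial_date(rec$start_raw %||% "")
      part <- if (!is.na(pd_s$year)) pd_s[1] else NULL
      res <- impute_lab_date(part, rec$timepoint %||% NA_character_, tl,
                             config$timepoints)
      if (is.na(res$imputed)) {
        add_undatable(p, dom, s, "undatable"); add_status(p, dom, s, "undatable")
        next
      }
      start <- res$imputed
      if (res$strategy != "none")
        add_audit(p, dom, s, "date", res$original, start, res$strategy,
                  res$note)
    } else {
      pd_s <- parse_partial_date(rec$start_raw %||% "")
      strategy <- NULL
      if (attr(pd_s, "failed")[1]) {
        pd_s <- extract_date_from_text(rec$start_raw)
        if (!is.na(pd_s$year)) strategy <- "free_text"
      }
      if (!is.na(pd_s$year)) {
        start <- impute_generic(pd_s[1])
        if (!pd_complete(pd_s)[1] || !is.null(strategy))
          add_audit(p, dom, s, "start", rec$start_raw, start,
                    strategy %||% "generic",
                    if (is.null(strategy)) "first-day completion"
                    else "date extracted from text")
      } else {
        tp_date <- impute_by_timepoint(rec$timepoint %||% NA_character_, tl,
                                       config$timepoints)
        if (!is.null(tp_date)) {
          start <- tp_date
          add_audit(p, dom, s, "start", rec$start_raw, start, "timepoint",
                    paste("anchored at timepoint", rec$timepoint))
        } else {
          add_undatable(p, dom, s, "undatable"); add_status(p, dom, s, "undatable")
          next
        }
      }
      pd_e <- parse_partial_date(rec$end_raw %||% "")
      if (attr(pd_e, "failed")[1]) pd_e <- extract_date_from_text(rec$end_raw)
      if (!is.na(pd_e$year)) {
        end <- impute_generic(pd_e[1])
        if (!pd_complete(pd_e)[1])
          add_audit(p, dom, s, "end", rec$end_raw, end, "generic",
                    "first-day completion")
      }
    }

    ## -- disposition records
    if (dom == "DS") {
      row <- map_disposition(rec, store, config, unname(pid_of[p]), start,
                             uid_base = uid_n)
      if (is.null(row)) {
        add_unmapped(p, dom, s, "disposition", rec$term %||% "")
        add_status(p, dom, s, "unmapped")
      } else {
        next_uid()
        ev_list[[length(ev_list) + 1L]] <- row
        add_status(p, dom, s, "mapped", 1L)
      }
      next
    }

    ## -- resolve and route
    res <- resolve_cached(rec$vocab %||% NA_character_,
                          first_non_na(rec$code, rec$testcd, rec$term))
    if (!length(res$concept_ids)) {
      add_unmapped(p, dom, s, rec$vocab %||% "", rec$source_value)
      add_status(p, dom, s, "unmapped")
      next
    }
    rows <- route_record(rec, res, store, unname(pid_of[p]), start, end,
                         uid_base = uid_n)
    next_uid(nrow(rows))

    ## value-level concept for coded finding results (e.g. functional class)
    if (is_finding && !is.na(rec$value_chr %||% NA) &&
        !is.na(rec$testcd %||% NA)) {
      vres <- resolve_cached(paste0("VAL-", rec$testcd), rec$value_chr)
      if (length(vres$concept_ids)) {
        obs_rows <- rows$table == "observation"
        rows$value_as_concept_id[obs_rows] <- vres$concept_ids[1]
        rows$value_as_string[obs_rows] <- NA_character_
      }
    }
    ev_list[[length(ev_list) + 1L]] <- rows
    n_emitted <- nrow(rows)
    primary <- rows[1, ]

    ## combination recipe: custom crosswalk fan-out rows are linked facts
    if (nrow(rows) > 1) {
      xw <- store$crosswalk
      hits_code <- first_non_na(rec$code, rec$testcd, rec$term)
      if (identical(rec$vocab, "free-text"))
        hits_code <- normalize_text(hits_code)
      hits <- xw[xw$source_vocabulary == (rec$vocab %||% "") &
                 xw$source_code == hits_code, , drop = FALSE]
      if (nrow(hits) > 1 && any(hits$provenance == "custom")) {
        for (j in 2:nrow(rows))
          fact_list[[length(fact_list) + 1L]] <-
            fact_pair(primary$uid, primary$table, rows$uid[j], rows$table[j],
                      .combination_rel)
      }
    }

    ## -- characteristics and outcomes
    if (!is.na(rec$severity %||% NA)) {
      sres <- resolve_cached("free-text", rec$severity)
      if (length(sres$concept_ids)) {
        at <- attach_characteristic(primary, 4022772, sres$concept_ids[1],
                                    uid_base = uid_n)
        next_uid()
        ev_list[[length(ev_list) + 1L]] <- at$observation
        fact_list[[length(fact_list) + 1L]] <- at$facts
        n_emitted <- n_emitted + 1L
      }
    }
    if (!is.na(rec$causality %||% NA)) {
      cres <- resolve_cached("free-text", rec$causality)
      if (length(cres$concept_ids)) {
        at <- attach_characteristic(primary, rel_to_drug,
                                    cres$concept_ids[1], uid_base = uid_n)
        next_uid()
        ev_list[[length(ev_list) + 1L]] <- at$observation
        fact_list[[length(fact_list) + 1L]] <- at$facts
        n_emitted <- n_emitted + 1L
      }
    }
    if (!is.na(rec$method %||% NA)) {
      mres <- resolve_cached("free-text", rec$method)
      if (length(mres$concept_ids)) {
        at <- attach_characteristic(primary, mres$concept_ids[1], NA_real_,
                                    relationship_concept_id = 4152892,
                                    uid_base = uid_n)
        next_uid()
        ev_list[[length(ev_list) + 1L]] <- at$observation
        fact_list[[length(fact_list) + 1L]] <- at$facts
        n_emitted <- n_emitted + 1L
      }
    }
    out <- map_outcome(primary, rec$outcome %||% NA_character_, store,
                       uid_base = uid_n)
    if (is.list(out)) {
      next_uid()
      ev_list[[length(ev_list) + 1L]] <- out$observation
      fact_list[[length(fact_list) + 1L]] <- out$facts
      n_emitted <- n_emitted + 1L
    }
    add_status(p, dom, s, "mapped", n_emitted)
  }

  ## DD record statuses (consumed by the death pathway or undatable)
  if (length(dd_status)) {
    parts <- strsplit(names(dd_status), "\r", fixed = TRUE)
    for (i in seq_along(dd_status))
      add_status(parts[[i]][1], "DD", as.integer(parts[[i]][3]),
                 dd_status[i], 0L)
  }

  ## ---- assemble ------------------------------------------------------------
  events <- if (length(ev_list)) do.call(rbind, ev_list) else .empty_events()
  rownames(events) <- NULL
  events$event_id <- NA_integer_
  for (tb in unique(events$table)) {
    idx <- which(events$table == tb)
    events$event_id[idx] <- seq_along(idx)
  }

  facts <- if (length(fact_list)) do.call(rbind, fact_list) else
    data.frame(uid_1 = integer(), table_1 = character(), uid_2 = integer(),
               table_2 = character(), relationship_concept_id = numeric())
  if (nrow(facts)) {
    m1 <- match(facts$uid_1, events$uid); m2 <- match(facts$uid_2, events$uid)
    fact_relationship <- data.frame(
      domain_concept_id_1 = unname(.cdm_table_concepts[facts$table_1]),
      fact_id_1 = events$event_id[m1],
      domain_concept_id_2 = unname(.cdm_table_concepts[facts$table_2]),
      fact_id_2 = events$event_id[m2],
      relationship_concept_id = facts$relationship_concept_id)
  } else {
    fact_relationship <- data.frame(
      domain_concept_id_1 = numeric(), fact_id_1 = integer(),
      domain_concept_id_2 = numeric(), fact_id_2 = integer(),
      relationship_concept_id = numeric())
  }

  observation_period <- derive_observation_period(events, death)

  logs <- list(
    exclusion = sel$log,
    non_event = non_event_log,
    unmapped = if (length(unmapped)) do.call(rbind, unmapped) else
      data.frame(patient_id = character(), domain = character(),
                 seq = integer(), vocab = character(),
                 source_value = character()),
    undatable = if (length(undatable)) do.call(rbind, undatable) else
      data.frame(patient_id = character(), domain = character(),
                 seq = integer(), reason = character()),
    imputation = if (length(audit)) do.call(rbind, audit) else
      data.frame(patient_id = character(), domain = character(),
                 seq = integer(), field = character(), original = character(),
                 imputed = character(), strategy = character(),
                 note = character()))
  for (nm in names(logs)) rownames(logs[[nm]]) <- NULL

  record_status <- if (length(status)) do.call(rbind, status) else
    data.frame(patient_id = character(), domain = character(),
               seq = integer(), status = character(), n_rows = integer())
  rownames(record_status) <- NULL

  structure(list(study_id = config$study_id,
                 person = person,
                 observation_period = observation_period,
                 events = events,
                 tables = cdm_tables(events),
                 death = death,
                 fact_relationship = fact_relationship,
                 logs = logs,
                 exclusion_report = sel$report,
                 record_status = record_status,
                 config = config),
            class = "cdm_result")
}

# split the internal event frame into OMOP-format per-table frames
cdm_tables <- function(events) {
  out <- list()
  spec <- list(
    condition_occurrence = c(id = "condition_occurrence_id",
                             concept_id = "condition_concept_id",
                             start_date = "condition_start_date",
                             end_date = "condition_end_date",
                             source_value = "condition_source_value",
                             source_concept_id = "condition_source_concept_id"),
    drug_exposure = c(id = "drug_exposure_id",
                      concept_id = "drug_concept_id",
                      start_date = "drug_exposure_start_date",
                      end_date = "drug_exposure_end_date",
                      source_value = "drug_source_value",
                      source_concept_id = "drug_source_concept_id"),
    measurement = c(id = "measurement_id", concept_id = "measurement_concept_id",
                    start_date = "measurement_date",
                    value_as_number = "value_as_number",
                    unit_source_value = "unit_source_value",
                    source_value = "measurement_source_value",
                    source_concept_id = "measurement_source_concept_id"),
    observation = c(id = "observation_id", concept_id = "observation_concept_id",
                    start_date = "observation_date",
                    value_as_concept_id = "value_as_concept_id",
                    value_as_number = "value_as_number",
                    value_as_string = "value_as_string",
                    source_value = "observation_source_value",
                    source_concept_id = "observation_source_concept_id"),
    procedure_occurrence = c(id = "procedure_occurrence_id",
                             concept_id = "procedure_concept_id",
                             start_date = "procedure_date",
                             source_value = "procedure_source_value",
                             source_concept_id = "procedure_source_concept_id"),
    visit_occurrence = c(id = "visit_occurrence_id",
                         concept_id = "visit_concept_id",
                         start_date = "visit_start_date",
                         end_date = "visit_end_date",
                         source_value = "visit_source_value"))
  for (tb in names(spec)) {
    sub <- events[events$table == tb, , drop = FALSE]
    cols <- spec[[tb]]
    df <- data.frame(sub$event_id, sub$person_id, stringsAsFactors = FALSE)
    names(df) <- c(cols[["id"]], "person_id")
    for (src in setdiff(names(cols), "id")) {
      val <- if (src %in% names(sub)) sub[[src]] else NA
      df[[cols[[src]]]] <- val
    }
    rownames(df) <- NULL
    out[[tb]] <- df
  }
  out
}

#' @export
print.cdm_result <- function(x, ...) {
  cat("OMOP CDM transformation result:", x$study_id, "\n")
  cat(sprintf("  persons: %d, events: %d, deaths: %d, fact links: %d\n",
              nrow(x$person), nrow(x$events), nrow(x$death),
              nrow(x$fact_relationship)))
  n <- vapply(x$tables, nrow, integer(1))
  for (tb in names(n)) cat(sprintf("    %-21s %6d rows\n", tb, n[tb]))
  cat(sprintf("  logs: %d excluded, %d non-event, %d unmapped, %d undatable, %d imputations\n",
              nrow(x$logs$exclusion), nrow(x$logs$non_event),
              nrow(x$logs$unmapped), nrow(x$logs$undatable),
              nrow(x$logs$imputation)))
  invisible(x)
}

#' Write a `cdm_result` to a directory of delimited files
#'
#' Emits the CDM tables in standard column layout (PERSON,
#' OBSERVATION_PERIOD, the six event tables, DEATH, FACT_RELATIONSHIP) plus
#' the machine-readable logs and the exclusion report.
#' @param cdm a `cdm_result`.
#' @param dir_path output directory (created if absent).
#' @return `dir_path`, invisibly.
#' @export
write_cdm <- function(cdm, dir_path) {
  stopifnot(inherits(cdm, "cdm_result"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) utils::write.csv(x, file.path(dir_path, f),
                                        row.names = FALSE, na = "")
  wr(cdm$person, "PERSON.csv")
  wr(cdm$observation_period, "OBSERVATION_PERIOD.csv")
  for (tb in names(cdm$tables)) wr(cdm$tables[[tb]], paste0(toupper(tb), ".csv"))
  wr(cdm$death, "DEATH.csv")
  wr(cdm$fact_relationship, "FACT_RELATIONSHIP.csv")
  for (lg in names(cdm$logs))
    wr(cdm$logs[[lg]], paste0(lg, "_log.csv"))
  rep <- cdm$exclusion_report
  wr(data.frame(n_in_database = rep$n_in_database,
                n_violators = rep$n_violators,
                n_mapping_excluded = rep$n_mapping_excluded,
                n_mapped = rep$n_mapped,
                pct_violators = rep$pct_violators,
                pct_mapping_excluded = rep$pct_mapping_excluded,
                pct_mapped = rep$pct_mapped),
     "exclusion_report.csv")
  invisible(dir_path)
}
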