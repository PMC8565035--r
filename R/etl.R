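#' @title ETL engine: sample selection, routing, FACT_RELATIONSHIP
#' @description
#' Transforms a [read_study()] dataset into OMOP CDM v5.3.1 tables: selects
#' the analysable sample with a full exclusion ledger, drops non-occurrence
#' records per CDM convention, completes dates through the imputation
#' strategies, resolves source codes to standard concepts, routes each record
#' to the event table its concept's domain dictates, and links related facts
#' (severity, causality, measurement method, outcomes) through mirrored
#' FACT_RELATIONSHIP pairs. Every input record ends up in exactly one of:
#' the CDM output, the non-event log, the unmapped log, the undatable log or
#' the exclusion log -- nothing is lost silently.
#' @name etl_engine
NULL

# Fixture metadata concept: generic characteristic-of-event link used where
# the CDM has no specific relationship concept (method links use 4152892).
.fact_characteristic_rel <- 1147900
.combination_rel <- 1147901

.gender_concepts <- c(F = 8532, M = 8507)

#' Exclusion accounting report
#'
#' The patient-level accounting of the mapping process: patients (records) in
#' the database, protocol violators, records excluded during mapping, and the
#' mapped remainder, with percentages of the database total to one decimal.
#' @param n_in_database DM records in the database.
#' @param n_violators records of flagged protocol violators.
#' @param n_mapping_excluded records excluded during mapping (missing birth
#'   year, missing treatment dates, duplicate records).
#' @return object of class `exclusion_report`.
#' @export
exclusion_report <- function(n_in_database, n_violators, n_mapping_excluded) {
  n_mapped <- n_in_database - n_violators - n_mapping_excluded
  if (n_mapped < 0)
    stop("exclusion accounting is negative: ledger corruption", call. = FALSE)
  pct <- function(n) if (n_in_database > 0) round1(n / n_in_database * 100) else NA_real_
  structure(list(n_in_database = n_in_database,
                 n_violators = n_violators,
                 n_mapping_excluded = n_mapping_excluded,
                 n_mapped = n_mapped,
                 pct_violators = pct(n_violators),
                 pct_mapping_excluded = pct(n_mapping_excluded),
                 pct_mapped = pct(n_mapped)),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Data exclusion in the mapping process\n")
  cat(sprintf("  Patients in database, N              %6d\n", x$n_in_database))
  cat(sprintf("  Violating inclusion criteria, n (%%)  %6d (%.1f)\n",
              x$n_violators, x$pct_violators))
  cat(sprintf("  Excluded during mapping, n (%%)       %6d (%.1f)\n",
              x$n_mapping_excluded, x$pct_mapping_excluded))
  cat(sprintf("  Total mapped, n (%%)                  %6d (%.1f)\n",
              x$n_mapped, x$pct_mapped))
  invisible(x)
}

# round half up, one decimal (printed-table convention)
round1 <- function(x) floor(x * 10 + 0.5) / 10

#' Select the mappable sample
#'
#' Excludes, in order: (a) DM records of flagged protocol violators; (b)
#' exact-duplicate DM records (the first occurrence, in file order, is kept
#' and the patient remains mapped); (c) patients whose birth year is missing
#' or whose treatment (EX) start and end dates are both completely missing.
#' Category (a) and categories (b)+(c) form the two exclusion rows of the
#' accounting report; the identity
#' `n_mapped = n_in_database - n_violators - n_mapping_excluded` holds by
#' construction because every DM record lands in exactly one category.
#'
#' @param study a `study_dataset`.
#' @param config a [mapping_config()].
#' @return list with `retained_ids`, `report` (an [exclusion_report()]) and
#'   `log` (data frame patient_id, reason).
#' @export
select_sample <- function(study, config = mapping_config()) {
  dm <- study$tables$DM
  n_db <- nrow(dm)
  log <- list()
  is_violator <- dm$USUBJID %in% study$violator_ids
  if (any(is_violator))
    log$viol <- data.frame(patient_id = dm$USUBJID[is_violator],
                           reason = "protocol_violator")
  dm2 <- dm[!is_violator, , drop = FALSE]
  dup <- duplicated(dm2)
  if (any(dup))
    log$dup <- data.frame(patient_id = dm2$USUBJID[dup],
                          reason = "duplicate_record")
  dm3 <- dm2[!dup, , drop = FALSE]

  birth <- parse_partial_date(dm3[[dm_var("birth", config)]] %||%
                              rep("", nrow(dm3)))
  no_birth <- is.na(birth$year)

  no_trt <- rep(FALSE, nrow(dm3))
  ex <- study$tables$EX
  if (!is.null(ex) && nrow(ex)) {
    st <- parse_partial_date(ex[[domain_var("EX", "start", config)]] %||%
                             rep("", nrow(ex)))
    en <- parse_partial_date(ex[[domain_var("EX", "end", config)]] %||%
                             rep("", nrow(ex)))
    usable <- !is.na(st$year) | !is.na(en$year)
    has_trt <- unique(ex$USUBJID[usable])
    no_trt <- !(dm3$USUBJID %in% has_trt)
  }
  excl <- no_birth | no_trt
  if (any(excl))
    log$map <- data.frame(
      patient_id = dm3$USUBJID[excl],
      reason = ifelse(no_birth[excl], "missing_birth_year",
                      "missing_treatment_dates"))
  retained <- dm3$USUBJID[!excl]
  report <- exclusion_report(
    n_in_database = n_db,
    n_violators = sum(is_violator),
    n_mapping_excluded = sum(dup) + sum(excl))
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(patient_id = character(), reason = character())
  rownames(log) <- NULL
  list(retained_ids = retained, report = report, log = log)
}

#' Drop non-occurrence and not-done records
#'
#' Per the CDM convention only events that actually occurred are mapped:
#' records stating that an event did not occur (`--OCCUR` of N), is unknown
#' (U), or that an assessment was not done (`--STAT` of NOT DONE) are
#' dropped, each counted under its reason for the quality-assessment
#' accounting.
#'
#' @param records normalised record frame from [as_sdtm_records()].
#' @return list with `kept` and `dropped` (the latter with a `reason`
#'   column: `not_occurred`, `unknown`, `not_done`).
#' @export
filter_non_events <- function(records) {
  occ <- toupper(records$occur_flag %||% rep(NA_character_, nrow(records)))
  stat <- toupper(records$status_flag %||% rep(NA_character_, nrow(records)))
  reason <- rep(NA_character_, nrow(records))
  reason[!is.na(occ) & occ == "N"] <- "not_occurred"
  reason[!is.na(occ) & occ == "U"] <- "unknown"
  reason[is.na(reason) & !is.na(stat) & stat == "NOT DONE"] <- "not_done"
  drop <- !is.na(reason)
  dropped <- records[drop, , drop = FALSE]
  dropped$reason <- reason[drop]
  list(kept = records[!drop, , drop = FALSE], dropped = dropped)
}

# internal: zero-row event frame with the full column set
.empty_events <- function() {
  data.frame(uid = integer(0), person_id = integer(0), table = character(0),
             concept_id = numeric(0), start_date = as.Date(character(0)),
             end_date = as.Date(character(0)),
             value_as_concept_id = numeric(0), value_as_number = numeric(0),
             value_as_string = character(0),
             unit_source_value = character(0), source_value = character(0),
             source_concept_id = numeric(0), patient_id = character(0),
             domain = character(0), seq = integer(0), role = character(0),
             stringsAsFactors = FALSE)
}

# internal: blank event-row template (uid links facts before ids exist)
.event_row <- function(uid, person_id, table, concept_id, start_date,
                       end_date = as.Date(NA), value_as_concept_id = NA_real_,
                       value_as_number = NA_real_,
                       value_as_string = NA_character_,
                       unit_source_value = NA_character_,
                       source_value = "", source_concept_id = NA_real_,
                       patient_id = NA_character_, domain = NA_character_,
                       seq = NA_integer_, role = "primary") {
  data.frame(uid = uid, person_id = person_id, table = table,
             concept_id = concept_id, start_date = start_date,
             end_date = end_date, value_as_concept_id = value_as_concept_id,
             value_as_number = value_as_number,
             value_as_string = value_as_string,
             unit_source_value = unit_source_value,
             source_value = source_value,
             source_concept_id = source_concept_id,
             patient_id = patient_id, domain = domain, seq = seq,
             role = role, stringsAsFactors = FALSE)
}

#' Route one source record into CDM event rows
#'
#' Emits one event row per resolved concept (one-to-many fan-out); the
#' target table is dictated by each concept's domain. Classification
#' concepts never appear as the event concept -- resolution only returns
#' standard or custom targets, and the source concept id is kept in
#' `source_concept_id`. An empty resolution emits nothing (the caller logs
#' the record as unmapped).
#'
#' @param rec one row of the normalised record frame (as a list or
#'   single-row data frame).
#' @param resolution result of [resolve_source()] for the record.
#' @param store a `vocabulary_store`.
#' @param person_id the person surrogate key.
#' @param start_date,end_date complete dates (end may be NA).
#' @param uid_base integer; uids are allocated from `uid_base + 1`.
#' @return data frame of event rows (possibly 0 rows).
#' @export
route_record <- function(rec, resolution, store, person_id, start_date,
                         end_date = as.Date(NA), uid_base = 0L) {
  ids <- resolution$concept_ids
  if (!length(ids)) return(.empty_events())
  info <- concept_info(store, ids)
  tabs <- .domain_to_table[info$domain_id]
  if (anyNA(tabs))
    stop("concept(s) with unroutable domain: ",
         paste(sprintf("%s (%s)", info$concept_id[is.na(tabs)],
                       info$domain_id[is.na(tabs)]), collapse = ", "),
         call. = FALSE)
  val_num <- suppressWarnings(as.numeric(rec$value_chr))
  rows <- lapply(seq_along(ids), function(i) {
    .event_row(uid = uid_base + i, person_id = person_id,
               table = unname(tabs[i]), concept_id = ids[i],
               start_date = start_date, end_date = end_date,
               value_as_number = if (tabs[i] == "measurement") val_num
                                 else NA_real_,
               value_as_string = if (tabs[i] == "measurement" && is.na(val_num))
                                 rec$value_chr else NA_character_,
               unit_source_value = rec$unit %||% NA_character_,
               source_value = rec$source_value,
               source_concept_id = resolution$source_concept_id,
               patient_id = rec$patient_id, domain = rec$domain,
               seq = rec$seq)
  })
  do.call(rbind, rows)
}

# mirrored FACT_RELATIONSHIP pair over uids; resolved to table-scoped ids at
# assembly time
fact_pair <- function(uid_1, table_1, uid_2, table_2, relationship_id) {
  data.frame(uid_1 = c(uid_1, uid_2), table_1 = c(table_1, table_2),
             uid_2 = c(uid_2, uid_1), table_2 = c(table_2, table_1),
             relationship_concept_id = relationship_id)
}

#' Attach a characteristic to an emitted event
#'
#' Creates an observation row holding the characteristic (severity,
#' causality, measurement method, ...) as its concept and the assessment as
#' `value_as_concept_id`, dated and keyed like the event, plus the mirrored
#' FACT_RELATIONSHIP pair linking observation and event.
#'
#' @param event a single event row (as produced by [route_record()]).
#' @param characteristic_concept_id observation concept (e.g. condition
#'   severity).
#' @param value_concept_id the assessed value concept (e.g. moderate).
#' @param relationship_concept_id link concept; defaults to the generic
#'   characteristic link, use 4152892 for measurement methods.
#' @param uid_base uid allocation base.
#' @return list with `observation` (event row) and `facts` (two mirrored
#'   rows).
#' @export
attach_characteristic <- function(event, characteristic_concept_id,
                                  value_concept_id,
                                  relationship_concept_id =
                                    .fact_characteristic_rel,
                                  uid_base = 0L) {
  obs <- .event_row(uid = uid_base + 1L, person_id = event$person_id,
                    table = "observation",
                    concept_id = characteristic_concept_id,
                    start_date = event$start_date,
                    value_as_concept_id = value_concept_id,
                    source_value = event$source_value,
                    patient_id = event$patient_id, domain = event$domain,
                    seq = event$seq, role = "attachment")
  facts <- fact_pair(obs$uid, "observation", event$uid, event$table,
                     relationship_concept_id)
  list(observation = obs, facts = facts)
}

#' Map a disposition record to an observation
#'
#' Enrollment and consent facts carry the study name in `value_as_string`;
#' discontinuation facts carry the reason in `value_as_concept_id` (resolved
#' through the free-text crosswalk). The observation concept per category is
#' a config choice among the CDM alternatives.
#'
#' @param rec normalised DS record (list / single-row data frame); the
#'   disposition category is its `term` (--DECOD) and the discontinuation
#'   reason its `value_chr`.
#' @param store a `vocabulary_store`.
#' @param config a [mapping_config()].
#' @param person_id,date surrogate key and completed record date.
#' @param uid_base uid allocation base.
#' @return an event row, or NULL for an unknown disposition category (caller
#'   logs it as unmapped).
#' @export
map_disposition <- function(rec, store, config, person_id, date,
                            uid_base = 0L) {
  cat_ <- toupper(rec$term %||% "")
  dc <- config$disposition
  concept <- switch(cat_,
    "ENROLLMENT" = , "ENROLLED" = dc$enrollment,
    "INFORMED CONSENT" = , "CONSENT" = dc$consent,
    "COMPLETED" = dc$completed,
    "WITHDRAWN" = , "WITHDRAWAL" = dc$withdrawn,
    NULL)
  if (is.null(concept)) return(NULL)
  val_str <- if (cat_ %in% c("ENROLLMENT", "ENROLLED", "INFORMED CONSENT",
                             "CONSENT")) config$study_id else NA_character_
  val_cid <- NA_real_
  if (cat_ %in% c("WITHDRAWN", "WITHDRAWAL") && !is.na(rec$value_chr %||% NA)) {
    res <- resolve_source(store, "free-text", rec$value_chr)
    if (length(res$concept_ids)) val_cid <- res$concept_ids[1]
  }
  .event_row(uid = uid_base + 1L, person_id = person_id,
             table = "observation", concept_id = as.numeric(concept),
             start_date = date, value_as_concept_id = val_cid,
             value_as_string = val_str, source_value = rec$term,
             patient_id = rec$patient_id, domain = rec$domain, seq = rec$seq)
}

#' Map an adverse event outcome
#'
#' A fatal outcome is not an event row: it becomes a death-date candidate
#' forwarded to [impute_death_date()]. Any other recorded outcome becomes an
#' observation with the adverse-incident-outcome-categories concept
#' (4231813) holding the outcome as `value_as_concept_id`, linked to the
#' event via a mirrored FACT_RELATIONSHIP pair.
#'
#' @param event the emitted event row.
#' @param outcome the source outcome string (e.g. "RECOVERED", "FATAL").
#' @param store a `vocabulary_store`.
#' @param uid_base uid allocation base.
#' @return NULL for missing outcomes, the string `"fatal"` for fatal ones,
#'   else a list with `observation` and `facts`.
#' @export
map_outcome <- function(event, outcome, store, uid_base = 0L) {
  if (is.na(outcome %||% NA)) return(NULL)
  if (toupper(outcome) == "FATAL") return("fatal")
  res <- resolve_source(store, "free-text", outcome)
  val <- if (length(res$concept_ids)) res$concept_ids[1] else NA_real_
  obs <- .event_row(uid = uid_base + 1L, person_id = event$person_id,
                    table = "observation", concept_id = 4231813,
                    start_date = event$start_date,
                    value_as_concept_id = val, source_value = outcome,
                    patient_id = event$patient_id, domain = event$domain,
                    seq = event$seq, role = "attachment")
  list(observation = obs,
       facts = fact_pair(obs$uid, "observation", event$uid, event$table,
                         .fact_characteristic_rel))
}

#' Derive one observation period per person
#'
#' Start is the earliest event or enrollment date, end the latest of the
#' last event date and the death date. Events never fall outside the period
#' by construction; the period is zero-length for a single dated event.
#'
#' @param events assembled event frame (internal representation).
#' @param death DEATH rows (person_id, death_date).
#' @return data frame person_id, observation_period_start_date,
#'   observation_period_end_date.
#' @export
derive_observation_period <- function(events, death = NULL) {
  if (!nrow(events)) {
    return(data.frame(person_id = integer(),
                      observation_period_start_date = as.Date(character()),
                      observation_period_end_date = as.Date(character())))
  }
  dates <- c(events$start_date, events$end_date)
  pid <- c(events$person_id, events$person_id)
  ok <- !is.na(dates)
  agg_min <- tapply(dates[ok], pid[ok], min)
  agg_max <- tapply(dates[ok], pid[ok], max)
  per <- data.frame(person_id = as.integer(names(agg_min)),
                    observation_period_start_date =
                      as.Date(as.vector(agg_min), origin = "1970-01-01"),
                    observation_period_end_date =
                      as.Date(as.vector(agg_max), origin = "1970-01-01"))
  if (!is.null(death) && nrow(death)) {
    m <- match(per$person_id, death$person_id)
    dd <- death$death_date[m]
    later <- !is.na(dd) & dd > per$observation_period_end_date
    per$observation_period_end_date[later] <- dd[later]
  }
  per[order(per$person_id), , drop = FALSE]
}
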