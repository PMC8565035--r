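#' @title Deterministic date imputation
#' @description
#' OMOP event rows require complete dates, while registry SDTM data carry
#' partial ("2015", "2015-06") or missing dates. Four deterministic
#' strategies complete them: extraction from free text, timepoint anchors,
#' the previous drug interval, and comparison against reference timepoints
#' (drug initiation/end, last available information, last follow-up visit,
#' study end, death). Every imputation returns an `imputation_result`
#' carrying the original value, the completed date, the strategy used and a
#' note, so the audit log can reconstruct each decision.
#' @name imputation
NULL

#' Reference timeline for one patient
#'
#' The pre-defined reference timepoints the comparison strategy draws on.
#' @param patient_id patient identifier.
#' @param drug_initiation,drug_end complete `Date`s (or NULL) of the first
#'   study-drug interval.
#' @param last_available_info complete `Date` of the last available
#'   information for the patient.
#' @param last_followup_visit complete `Date` of the last follow-up visit.
#' @param study_end complete `Date` the study ended (NULL while ongoing).
#' @param enrollment complete `Date` of registry enrollment.
#' @param death_candidates data frame of death-date candidates, see
#'   [death_candidates()].
#' @return object of class `reference_timeline`.
#' @export
reference_timeline <- function(patient_id = NA_character_,
                               drug_initiation = NULL, drug_end = NULL,
                               last_available_info = NULL,
                               last_followup_visit = NULL,
                               study_end = NULL, enrollment = NULL,
                               death_candidates = NULL) {
  if (!is.null(last_available_info) && !is.null(study_end) &&
      last_available_info > study_end)
    stop("last_available_info after study_end", call. = FALSE)
  structure(list(patient_id = patient_id,
                 drug_initiation = drug_initiation,
                 drug_end = drug_end,
                 last_available_info = last_available_info,
                 last_followup_visit = last_followup_visit,
                 study_end = study_end,
                 enrollment = enrollment,
                 death_candidates = death_candidates),
            class = "reference_timeline")
}

#' Death-date candidates from the three recording sources
#'
#' The same death may be recorded in the study CRF death details, as an
#' adverse event with fatal outcome, and in the drug safety database, with
#' conflicting and differently complete dates. The source factor level order
#' encodes the tie-break hierarchy.
#' @param source character vector, each one of `"crf_death_details"`,
#'   `"crf_fatal_ae"`, `"safety_db"`.
#' @param date a `partial_date` of the same length.
#' @return data frame with `source` (ordered factor) and date components.
#' @export
death_candidates <- function(source, date) {
  lv <- c("crf_death_details", "crf_fatal_ae", "safety_db")
  stopifnot(all(source %in% lv), inherits(date, "partial_date"))
  data.frame(source = factor(source, levels = lv),
             year = date$year, month = date$month, day = date$day)
}

imputation_result <- function(original, imputed, strategy, note = "",
                              conflict = FALSE) {
  structure(list(original = original, imputed = imputed,
                 strategy = strategy, note = note, conflict = conflict),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("imputed %s -> %s [%s]%s\n",
              if (is.null(x$original) || all(is.na(x$original))) "(missing)"
              else paste(x$original, collapse = ","),
              format(x$imputed), x$strategy,
              if (x$conflict) " CONFLICT" else ""))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Complete a partial date generically
#'
#' A missing day becomes the first day of that month; a missing day and
#' month becomes 1 January of that year. A complete date passes through
#' unchanged. The year must be present -- a fully missing date needs one of
#' the reference strategies instead.
#'
#' @param partial a `partial_date` (vectorised).
#' @return `Date` vector.
#' @examples
#' impute_generic(partial_date(2015, 6))   # 2015-06-01
#' impute_generic(partial_date(2015))      # 2015-01-01
#' @export
impute_generic <- function(partial) {
  stopifnot(inherits(partial, "partial_date"))
  if (anyNA(partial$year))
    stop("impute_generic requires a year; use a reference strategy",
         call. = FALSE)
  m <- ifelse(is.na(partial$month), 1L, partial$month)
  d <- ifelse(is.na(partial$day), 1L, partial$day)
  as.Date(sprintf("%04d-%02d-%02d", partial$year, m, d))
}

#' Impute a drug initiation date
#'
#' The partial start is completed generically (first day / 1 January); when
#' the completed candidate does not fall after the end of the previous
#' interval of the same drug, the start becomes that end date plus one day,
#' so consecutive intervals never overlap. If the shifted date contradicts
#' the recorded components (lands in a different year, or month when one was
#' recorded), the contradiction is flagged and the generic candidate kept.
#'
#' @param partial a length-1 `partial_date` with year present.
#' @param prev_interval_end complete `Date` of the previous interval's end,
#'   or NULL when this is the first interval.
#' @return an `imputation_result`.
#' @examples
#' impute_drug_start(partial_date(2015, 6), as.Date("2015-06-10"))
#' @export
impute_drug_start <- function(partial, prev_interval_end = NULL) {
  stopifnot(inherits(partial, "partial_date"), length(partial) == 1L)
  candidate <- impute_generic(partial)
  if (pd_complete(partial))
    return(imputation_result(format(partial), candidate, "none",
                             "already complete"))
  if (!is.null(prev_interval_end) && candidate <= prev_interval_end) {
    shifted <- prev_interval_end + 1L
    sy <- as.integer(format(shifted, "%Y"))
    sm <- as.integer(format(shifted, "%m"))
    conflict <- sy != partial$year ||
      (!is.na(partial$month) && sm != partial$month)
    if (conflict)
      return(imputation_result(
        format(partial), candidate, "prev_interval",
        sprintf("previous-interval shift to %s contradicts recorded parts; generic candidate retained",
                format(shifted)), conflict = TRUE))
    return(imputation_result(format(partial), shifted, "prev_interval",
                             "previous interval end + 1 day"))
  }
  imputation_result(format(partial), candidate, "generic",
                    "first-day completion")
}

#' Impute a laboratory test date
#'
#' When the test's timepoint anchors at drug initiation and the recorded
#' components agree with the drug initiation date, that date is used. When
#' the timepoint marks the last available information before study end, the
#' earlier of the drug end date and the study end date is used. Otherwise a
#' recorded year falls through to generic completion; with no year at all
#' the record is undatable (imputed is NA and the caller drops it with a
#' logged reason).
#'
#' @param partial a length-1 `partial_date`, or NULL for a fully missing
#'   date.
#' @param timepoint the record's timepoint label.
#' @param timeline a [reference_timeline()].
#' @param timepoints timepoint-to-anchor table, see [default_timepoints()].
#' @return an `imputation_result` (`imputed` is NA when unresolvable).
#' @export
impute_lab_date <- function(partial, timepoint, timeline,
                            timepoints = default_timepoints()) {
  orig <- if (is.null(partial)) NA_character_ else format(partial)
  if (!is.null(partial) && pd_complete(partial))
    return(imputation_result(orig, impute_generic(partial), "none",
                             "already complete"))
  anchor <- NULL
  if (!is.na(timepoint) && toupper(timepoint) %in% names(timepoints))
    anchor <- timepoints[[toupper(timepoint)]]$anchor

  if (identical(anchor, "drug_initiation") &&
      !is.null(timeline$drug_initiation)) {
    di <- timeline$drug_initiation
    agree <- is.null(partial) ||
      ((is.na(partial$year) || partial$year == as.integer(format(di, "%Y"))) &&
       (is.na(partial$month) || partial$month == as.integer(format(di, "%m"))))
    if (agree)
      return(imputation_result(orig, di, "reference_comparison",
                               "drug initiation date"))
  }
  if (identical(anchor, "min_drug_end_study_end")) {
    cand <- c(timeline$drug_end, timeline$study_end)
    if (length(cand))
      return(imputation_result(orig, min(cand), "reference_comparison",
                               "earlier of drug end and study end"))
  }
  if (!is.null(partial) && !is.na(partial$year))
    return(imputation_result(orig, impute_generic(partial), "generic",
                             "first-day completion"))
  imputation_result(orig, as.Date(NA), "none", "undatable: no year and no applicable reference")
}

#' Impute a death date from conflicting sources
#'
#' Selects the candidate with the fewest missing components; ties are broken
#' by the source hierarchy (CRF death details, then fatal adverse events
#' from the CRF, then the drug safety database). With no candidate carrying
#' a year, the date of last available information is used. A selected
#' partial candidate is completed generically, and if that completed date
#' falls before the last available information it is replaced by it (the
#' floor applies only to imputed, not recorded-complete, dates). The result
#' is invariant under reordering of the candidate list.
#'
#' @param candidates a data frame from [death_candidates()] (may have zero
#'   rows).
#' @param last_available_info complete `Date`; required when no candidate
#'   has a usable year.
#' @return an `imputation_result` with strategy `"death_hierarchy"`.
#' @export
impute_death_date <- function(candidates, last_available_info = NULL) {
  usable <- candidates[!is.na(candidates$year), , drop = FALSE]
  if (!nrow(usable)) {
    if (is.null(last_available_info))
      stop("no death-date candidate with a year and no last available information: cannot place death",
           call. = FALSE)
    return(imputation_result(NA_character_, last_available_info,
                             "death_hierarchy",
                             "no usable candidate; last available information"))
  }
  pd <- partial_date(usable$year, usable$month, usable$day)
  nmiss <- pd_n_missing(pd)
  completed <- impute_generic(pd)
  ord <- order(nmiss, as.integer(usable$source), completed)
  pick <- ord[1]
  chosen <- pd[pick]
  date <- completed[pick]
  note <- sprintf("source %s, %d missing part(s)",
                  as.character(usable$source[pick]), nmiss[pick])
  if (nmiss[pick] > 0L && !is.null(last_available_info) &&
      date < last_available_info) {
    date <- last_available_info
    note <- paste0(note, "; floored at last available information")
  }
  imputation_result(format(chosen), date, "death_hierarchy", note)
}

#' Resolve a timepoint label to a reference date
#'
#' Strategy (ii): SDTM timepoint labels such as "before patient
#' discontinuation" anchor a record to a reference date. The label-to-anchor
#' table is configuration, since each registry's timepoint vocabulary is its
#' own.
#'
#' @param timepoint the label.
#' @param timeline a [reference_timeline()].
#' @param timepoints the label-to-anchor table ([default_timepoints()]).
#' @return a complete `Date`, or NULL when the label is unmapped or its
#'   anchor is absent from the timeline.
#' @export
impute_by_timepoint <- function(timepoint, timeline,
                                timepoints = default_timepoints()) {
  if (is.na(timepoint)) return(NULL)
  entry <- timepoints[[toupper(timepoint)]]
  if (is.null(entry)) return(NULL)
  anchor <- switch(entry$anchor,
    drug_initiation = timeline$drug_initiation,
    drug_end = timeline$drug_end,
    last_available_info = timeline$last_available_info,
    last_followup_visit = timeline$last_followup_visit,
    study_end = timeline$study_end,
    enrollment = timeline$enrollment,
    min_drug_end_study_end = {
      cand <- c(timeline$drug_end, timeline$study_end)
      if (length(cand)) min(cand) else NULL
    },
    NULL)
  if (is.null(anchor)) return(NULL)
  anchor + as.integer(entry$offset_days %||% 0L)
}
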