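#' @title Mapping quality assessment
#' @description
#' Reproduces the accounting used to judge a registry transformation:
#' patient-level exclusion arithmetic, consolidation (redundancy) of source
#' values into standard concepts, record-level counts before and after
#' mapping, and a demographic consistency check between the SDTM source and
#' the CDM output. Keys are documented explicitly because the accounting is
#' meaningless without them: a "unique source record" is a distinct
#' (patient, domain, sequence) triple, a "unique CDM record" a distinct
#' event row (counted after one-to-many fan-out), and a "unique source
#' value" a distinct (vocabulary, code-or-normalised-text) pair.
#' @name qa
NULL

#' Redundancy of source values after consolidation
#'
#' The share of distinct source values that collapsed onto an already-used
#' standard concept during mapping, as a whole percent:
#' `round((n_source_values - n_concept_ids) / n_source_values * 100)`.
#' Scale-invariant in its two arguments.
#'
#' @param n_source_values distinct source values in the SDTM data.
#' @param n_concept_ids distinct standard concept ids they mapped to.
#' @return integer percent; `NA` when there are no source values.
#' @examples
#' redundancy_pct(10659, 3698)  # 65
#' @export
redundancy_pct <- function(n_source_values, n_concept_ids) {
  if (n_source_values == 0) return(NA_integer_)
  stopifnot(n_source_values >= n_concept_ids, n_concept_ids > 0)
  as.integer(floor((n_source_values - n_concept_ids) / n_source_values * 100
                   + 0.5))
}

#' Patient-level exclusion accounting
#'
#' @param n_db patients (DM records) in the database.
#' @param n_violators protocol violators excluded.
#' @param n_excluded records excluded during mapping.
#' @return list with `n_mapped` and `pct_mapped` (one decimal, half-up).
#' @examples
#' exclusion_accounting(2722, 46, 2)  # 2674 mapped, 98.2%
#' @export
exclusion_accounting <- function(n_db, n_violators, n_excluded) {
  if (n_db < n_violators + n_excluded)
    stop("exclusions exceed the database count: ledger corruption",
         call. = FALSE)
  n_mapped <- n_db - n_violators - n_excluded
  list(n_mapped = n_mapped, pct_mapped = round1(n_mapped / n_db * 100))
}

#' Per-category quality-assessment counts
#'
#' @param category `"condition"` or `"drug"`.
#' @param n_unique_source_values,n_unique_concept_ids,n_unique_custom_concept_ids,n_unique_source_records,n_unique_cdm_records,n_unique_source_records_mapped
#'   the six Table-style tallies.
#' @return object of class `qa_counts`.
#' @export
qa_counts <- function(category, n_unique_source_values, n_unique_concept_ids,
                      n_unique_custom_concept_ids, n_unique_source_records,
                      n_unique_cdm_records, n_unique_source_records_mapped) {
  stopifnot(category %in% c("condition", "drug"),
            n_unique_custom_concept_ids <= n_unique_concept_ids)
  vals <- c(n_unique_source_values = n_unique_source_values,
            n_unique_concept_ids = n_unique_concept_ids,
            n_unique_custom_concept_ids = n_unique_custom_concept_ids,
            n_unique_source_records = n_unique_source_records,
            n_unique_cdm_records = n_unique_cdm_records,
            n_unique_source_records_mapped = n_unique_source_records_mapped)
  if (any(vals < 0)) stop("negative QA count", call. = FALSE)
  structure(c(list(category = category), as.list(vals)), class = "qa_counts")
}

#' Aggregate QA counts across registries
#'
#' Element-wise sums of per-registry tallies; all reports must share one
#' category.
#' @param reports list of [qa_counts()] objects.
#' @return a `qa_counts` with the summed fields (all zero for an empty
#'   list, category `"condition"`).
#' @export
aggregate_counts <- function(reports) {
  if (!length(reports))
    return(qa_counts("condition", 0, 0, 0, 0, 0, 0))
  cats <- unique(vapply(reports, function(r) r$category, character(1)))
  if (length(cats) > 1)
    stop("cannot aggregate mixed categories: ",
         paste(cats, collapse = ", "), call. = FALSE)
  fields <- setdiff(names(reports[[1]]), "category")
  sums <- lapply(fields, function(f)
    sum(vapply(reports, function(r) as.numeric(r[[f]]), numeric(1))))
  names(sums) <- fields
  do.call(qa_counts, c(list(category = cats), sums))
}

#' @export
print.qa_counts <- function(x, ...) {
  cat("QA counts (", x$category, " codes)\n", sep = "")
  cat(sprintf("  unique source values            %8d\n",
              x$n_unique_source_values))
  cat(sprintf("  unique concept ids              %8d (%d custom)\n",
              x$n_unique_concept_ids, x$n_unique_custom_concept_ids))
  cat(sprintf("  unique source records           %8d (%d mapped)\n",
              x$n_unique_source_records, x$n_unique_source_records_mapped))
  cat(sprintf("  unique CDM records              %8d\n",
              x$n_unique_cdm_records))
  invisible(x)
}

# consolidation can be negative on tiny studies when one-to-many fan-out
# outweighs redundancy; the report shows not-applicable there
safe_redundancy <- function(qc) {
  if (qc$n_unique_concept_ids == 0 ||
      qc$n_unique_source_values < qc$n_unique_concept_ids)
    return(NA_integer_)
  redundancy_pct(qc$n_unique_source_values, qc$n_unique_concept_ids)
}

# the record categories the QA tallies are computed over
.qa_condition_domains <- c("AE", "MH", "CE")
.qa_drug_domains <- c("CM", "EX")

# distinct (vocabulary, code-or-normalised-text) source values
.n_source_values <- function(recs) {
  code <- ifelse(!is.na(recs$code), recs$code,
                 ifelse(!is.na(recs$term), normalize_text(recs$term), NA))
  length(unique(stats::na.omit(paste(recs$vocab, code)[!is.na(code)])))
}

#' Compute QA counts for one category from a transformation result
#'
#' @param study the source `study_dataset`.
#' @param cdm the [map_study()] result.
#' @param category `"condition"` (AE/MH/CE records) or `"drug"` (CM/EX).
#' @param config the [mapping_config()] used.
#' @return a [qa_counts()].
#' @export
compute_qa_counts <- function(study, cdm, category = c("condition", "drug"),
                              config = mapping_config()) {
  category <- match.arg(category)
  doms <- if (category == "condition") .qa_condition_domains else
    .qa_drug_domains
  recs <- as_sdtm_records(study, config)
  recs <- recs[recs$domain %in% doms &
               recs$patient_id %in% cdm$person$person_source_value, ,
               drop = FALSE]
  ev <- cdm$events[cdm$events$domain %in% doms &
                   cdm$events$role == "primary", , drop = FALSE]
  st <- cdm$record_status[cdm$record_status$domain %in% doms, , drop = FALSE]
  concept_ids <- unique(ev$concept_id)
  qa_counts(category,
            n_unique_source_values = .n_source_values(recs),
            n_unique_concept_ids = length(concept_ids),
            n_unique_custom_concept_ids =
              sum(concept_ids >= CUSTOM_ID_BASE),
            n_unique_source_records =
              length(unique(rec_key(recs$patient_id, recs$domain,
                                    recs$seq))),
            n_unique_cdm_records = nrow(ev),
            n_unique_source_records_mapped =
              sum(st$status == "mapped"))
}

#' Demographic consistency between source and CDM
#'
#' Recomputes mean (SD) age at enrollment and the gender distribution on
#' both sides over the mapped patients and flags discrepancies (exact for
#' counts, 0.01 for means). Age at enrollment is enrollment year minus birth
#' year on both sides; the CDM side reads the enrollment observation rows
#' and PERSON.
#'
#' @param study the source `study_dataset`.
#' @param cdm the [map_study()] result.
#' @param config the [mapping_config()] used.
#' @return list with `table` (side-by-side statistics) and `flags`
#'   (character vector of discrepancies, empty when consistent).
#' @export
consistency_check <- function(study, cdm, config = mapping_config()) {
  dm <- study$tables$DM
  dm <- dm[!duplicated(dm), , drop = FALSE]
  dm <- dm[dm$USUBJID %in% cdm$person$person_source_value, , drop = FALSE]
  birth <- parse_partial_date(dm[[dm_var("birth", config)]] %||%
                              rep("", nrow(dm)))
  enroll <- parse_partial_date(dm[[dm_var("enroll", config)]] %||%
                               rep("", nrow(dm)))
  sdtm_age <- enroll$year - birth$year
  sdtm_sex <- toupper(dm[[dm_var("sex", config)]] %||% rep("", nrow(dm)))

  obs <- cdm$tables$observation
  enr <- obs[obs$observation_concept_id == config$disposition$enrollment, ,
             drop = FALSE]
  m <- match(enr$person_id, cdm$person$person_id)
  cdm_age <- as.integer(format(as.Date(enr$observation_date), "%Y")) -
    cdm$person$year_of_birth[m]
  cdm_sex <- c(`8532` = "F", `8507` = "M")[
    as.character(cdm$person$gender_concept_id)]
  cdm_sex[is.na(cdm_sex)] <- ""

  stat <- function(x) c(n = sum(!is.na(x)),
                        mean = mean(x, na.rm = TRUE),
                        sd = stats::sd(x, na.rm = TRUE))
  tab <- rbind(sdtm = stat(sdtm_age), cdm = stat(cdm_age))
  flags <- character(0)
  if (nrow(cdm$person) != cdm$exclusion_report$n_mapped)
    flags <- c(flags, sprintf(
      "person count mismatch: %d PERSON rows vs %d mapped patients",
      nrow(cdm$person), cdm$exclusion_report$n_mapped))
  if (nrow(dm) != nrow(cdm$person))
    flags <- c(flags, sprintf("patient count mismatch: %d SDTM vs %d CDM",
                              nrow(dm), nrow(cdm$person)))
  if (tab["sdtm", "n"] != tab["cdm", "n"])
    flags <- c(flags, "age denominator mismatch")
  if (isTRUE(abs(tab["sdtm", "mean"] - tab["cdm", "mean"]) > 0.01))
    flags <- c(flags, "mean age differs beyond 0.01")
  if (isTRUE(abs(tab["sdtm", "sd"] - tab["cdm", "sd"]) > 0.01))
    flags <- c(flags, "age SD differs beyond 0.01")
  for (g in c("F", "M")) {
    if (sum(sdtm_sex == g) != sum(cdm_sex == g))
      flags <- c(flags, sprintf("gender count mismatch for %s", g))
  }
  gender <- rbind(
    sdtm = c(F = sum(sdtm_sex == "F"), M = sum(sdtm_sex == "M"),
             missing = sum(!sdtm_sex %in% c("F", "M"))),
    cdm = c(F = sum(cdm_sex == "F"), M = sum(cdm_sex == "M"),
            missing = sum(!cdm_sex %in% c("F", "M"))))
  list(table = tab, gender = gender, flags = flags)
}

#' Full quality-assessment report for a transformation
#'
#' Bundles the exclusion report, per-category QA counts, redundancy
#' percentages, record-level mapping rates with and without non-event
#' records, and the demographic consistency check.
#'
#' @param study the source `study_dataset`.
#' @param cdm the [map_study()] result.
#' @param config the [mapping_config()] used.
#' @return object of class `qa_report`.
#' @export
qa_report <- function(study, cdm, config = mapping_config()) {
  cond <- compute_qa_counts(study, cdm, "condition", config)
  drug <- compute_qa_counts(study, cdm, "drug", config)
  st <- cdm$record_status
  n_rec <- nrow(st)
  n_mapped <- sum(st$status %in% c("mapped", "death"))
  n_nonev <- sum(st$status == "non_event")
  pct_unmapped_all <- if (n_rec > 0)
    round1((n_rec - n_mapped) / n_rec * 100) else NA_real_
  denom_ex_nonev <- n_rec - n_nonev
  pct_unmapped_ex_nonev <- if (denom_ex_nonev > 0)
    round1((denom_ex_nonev - n_mapped) / denom_ex_nonev * 100) else NA_real_
  structure(list(
    study_id = cdm$study_id,
    exclusion = cdm$exclusion_report,
    condition = cond,
    drug = drug,
    redundancy = c(condition = safe_redundancy(cond),
                   drug = safe_redundancy(drug)),
    records = list(n_records = n_rec, n_mapped = n_mapped,
                   n_non_event = n_nonev,
                   n_unmapped = sum(st$status == "unmapped"),
                   n_undatable = sum(st$status == "undatable"),
                   pct_unmapped_all = pct_unmapped_all,
                   pct_unmapped_excl_non_events = pct_unmapped_ex_nonev),
    consistency = consistency_check(study, cdm, config)),
    class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat("=== Quality assessment:", x$study_id, "===\n")
  print(x$exclusion)
  print(x$condition)
  print(x$drug)
  cat(sprintf("Redundancy: condition %s%%, drug %s%%\n",
              x$redundancy[["condition"]], x$redundancy[["drug"]]))
  r <- x$records
  cat(sprintf("Records: %d total; %d mapped, %d non-event, %d unmapped, %d undatable\n",
              r$n_records, r$n_mapped, r$n_non_event, r$n_unmapped,
              r$n_undatable))
  cat(sprintf("Unmapped: %.1f%% of all records, %.1f%% excluding non-events\n",
              r$pct_unmapped_all, r$pct_unmapped_excl_non_events))
  fl <- x$consistency$flags
  cat("Consistency:", if (length(fl)) paste(fl, collapse = "; ")
      else "no discrepancies", "\n")
  invisible(x)
}

#' Write a QA report to a delimited file
#' @param report a [qa_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qa_report <- function(report, path) {
  rows <- list()
  add <- function(section, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(section = section,
                                             metric = metric, value = value)
  ex <- report$exclusion
  for (f in c("n_in_database", "n_violators", "n_mapping_excluded",
              "n_mapped", "pct_violators", "pct_mapping_excluded",
              "pct_mapped"))
    add("exclusion", f, ex[[f]])
  for (cat_ in c("condition", "drug")) {
    qc <- report[[cat_]]
    for (f in setdiff(names(qc), "category")) add(cat_, f, qc[[f]])
    add(cat_, "redundancy_pct", report$redundancy[[cat_]])
  }
  for (f in names(report$records)) add("records", f, report$records[[f]])
  add("consistency", "n_flags", length(report$consistency$flags))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Compare two QA reports (refresh workflow)
#'
#' A vocabulary or data refresh re-runs the transformation; this diff makes
#' the movement between two QA reports explicit.
#' @param old,new two [qa_report()] objects.
#' @return data frame of metrics with old, new and delta columns.
#' @export
diff_qa <- function(old, new) {
  pick <- function(r) c(
    n_mapped_patients = r$exclusion$n_mapped,
    n_records = r$records$n_records,
    n_records_mapped = r$records$n_mapped,
    n_unmapped = r$records$n_unmapped,
    condition_concepts = r$condition$n_unique_concept_ids,
    drug_concepts = r$drug$n_unique_concept_ids)
  a <- pick(old); b <- pick(new)
  data.frame(metric = names(a), old = unname(a), new = unname(b),
             delta = unname(b - a))
}
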