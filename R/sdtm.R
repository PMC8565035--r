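#' @title SDTM study datasets
#' @description
#' A `study_dataset` holds one registry study as read from disk: one verbatim
#' data frame per SDTM domain (DM, AE, CM, EX, LB, MH, VS, DD, DS, XP, ...),
#' the study design, the study end date and the set of flagged protocol
#' violators. Reading never mutates or imputes; every transformation happens
#' downstream and is logged.
#' @name study_dataset
NULL

# Variable-name conventions per SDTM general-observation-class practice.
# Roles resolve to <DOMAIN><SUFFIX>; config var_overrides take precedence.
.role_suffix <- c(seq = "SEQ", start = "STDTC", end = "ENDTC", date = "DTC",
                  occur = "OCCUR", stat = "STAT", tpt = "TPT",
                  decod = "DECOD", code = "PTCD", testcd = "TESTCD",
                  orres = "ORRES", unit = "ORRESU", method = "METHOD",
                  sev = "SEV", rel = "REL", out = "OUT", cat = "CAT",
                  src = "SRC")

#' Resolve the column name carrying a given role for a domain
#' @param domain SDTM domain code.
#' @param role one of names(.role_suffix).
#' @param config a [mapping_config()].
#' @return column name string.
#' @keywords internal
domain_var <- function(domain, role, config = mapping_config()) {
  ov <- config$var_overrides[[domain]]
  if (!is.null(ov) && !is.null(ov[[role]])) return(ov[[role]])
  paste0(domain, .role_suffix[[role]])
}

# DM is a special-purpose domain whose variables are not domain-prefixed
.dm_defaults <- c(birth = "BRTHDTC", sex = "SEX", enroll = "RFSTDTC")

#' @rdname domain_var
#' @keywords internal
dm_var <- function(role, config = mapping_config()) {
  ov <- config$var_overrides[["DM"]]
  if (!is.null(ov) && !is.null(ov[[role]])) return(ov[[role]])
  .dm_defaults[[role]]
}

#' Read an SDTM-style study from a directory of delimited files
#'
#' Expects one RFC-4180 comma-delimited UTF-8 file per domain, named
#' `<DOMAIN>.csv` with a header row. A `VIOLATORS.csv` file (column
#' `USUBJID`), when present, supplies the flagged protocol violators.
#' All values are kept verbatim as character; date strings that fail ISO-8601
#' prefix parsing stay in place and are flagged via attributes, never dropped.
#'
#' @param dir_path directory containing the domain files.
#' @param config a [mapping_config()].
#' @return A `study_dataset`: list with `study_id`, `design`,
#'   `study_end_date`, `tables` (named list of data frames) and
#'   `violator_ids`.
#' @export
read_study <- function(dir_path, config = mapping_config()) {
  if (!dir.exists(dir_path))
    stop("study directory not found: ", dir_path, call. = FALSE)
  files <- list.files(dir_path, pattern = "^[A-Z]{2,3}\\.csv$",
                      full.names = TRUE)
  domains <- sub("\\.csv$", "", basename(files))
  if (!"DM" %in% domains)
    stop("no DM.csv in ", dir_path, ": the demographics domain is required",
         call. = FALSE)
  known <- c("DM", "AE", "CM", "EX", "LB", "MH", "VS", "DD", "DS", "XP", "CE")
  unknown <- setdiff(domains, known)
  if (length(unknown))
    warning("unknown domain file(s) loaded as generic domains: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  tables <- stats::setNames(lapply(files, function(f)
    utils::read.csv(f, colClasses = "character", check.names = FALSE,
                    na.strings = NULL, fileEncoding = "UTF-8")), domains)

  vfile <- file.path(dir_path, "VIOLATORS.csv")
  violators <- character()
  if (file.exists(vfile))
    violators <- utils::read.csv(vfile, colClasses = "character")$USUBJID

  all_ids <- unique(unlist(lapply(tables, function(t) t[["USUBJID"]]),
                           use.names = FALSE))
  dm_ids <- tables$DM$USUBJID
  orphans <- setdiff(all_ids, dm_ids)
  if (length(orphans))
    warning("patients referenced outside DM only: ",
            paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)

  structure(list(study_id = config$study_id,
                 design = config$design,
                 study_end_date = config$study_end_date,
                 tables = tables,
                 violator_ids = violators),
            class = "study_dataset")
}

#' Write a study dataset back to a directory of delimited files
#'
#' Inverse of [read_study()]: every field value round-trips byte-identically
#' for conforming files.
#' @param study a `study_dataset`.
#' @param dir_path output directory (created if absent).
#' @return `dir_path`, invisibly.
#' @export
write_study <- function(study, dir_path) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  for (dom in names(study$tables))
    utils::write.csv(study$tables[[dom]],
                     file.path(dir_path, paste0(dom, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (length(study$violator_ids))
    utils::write.csv(data.frame(USUBJID = study$violator_ids),
                     file.path(dir_path, "VIOLATORS.csv"), row.names = FALSE)
  invisible(dir_path)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("SDTM study dataset:", x$study_id, sprintf("(%s)\n", x$design))
  n <- vapply(x$tables, nrow, integer(1))
  cat(sprintf("  %-4s %6d rows\n", names(n), n), sep = "")
  cat("  violators flagged:", length(x$violator_ids), "\n")
  invisible(x)
}

# Domains handled as checklists/events (coded with MedDRA), as drug
# interventions (WHODrug), and as findings (test-code keyed).
.event_domains <- c("AE", "MH", "CE")
.drug_domains <- c("CM", "EX")
.finding_domains <- c("LB", "VS", "XP")

#' Normalise SDTM tables to one record frame
#'
#' Flattens every non-DM domain into a single data frame with one row per
#' source record and standardised columns, keyed by
#' `(patient_id, domain, seq)`. Verbatim source values are preserved in
#' `source_value`; nothing is imputed or dropped here.
#'
#' @param study a `study_dataset`.
#' @param config a [mapping_config()].
#' @return data frame with columns patient_id, domain, seq, vocab, code,
#'   term, free_text, occur_flag, status_flag, timepoint, start_raw, end_raw,
#'   testcd, value_chr, unit, method, severity, causality, outcome, category,
#'   source, source_value.
#' @export
as_sdtm_records <- function(study, config = mapping_config()) {
  stopifnot(inherits(study, "study_dataset"))
  out <- list()
  for (dom in setdiff(names(study$tables), "DM")) {
    tab <- study$tables[[dom]]
    if (!nrow(tab)) next
    g <- function(role) {
      col <- domain_var(dom, role, config)
      if (col %in% names(tab) && !(col %in% config$drop_vars))
        tab[[col]] else rep(NA_character_, nrow(tab))
    }
    blank_na <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)
    seq_raw <- g("seq")
    rec <- data.frame(
      patient_id = tab[["USUBJID"]],
      domain = dom,
      seq = as.integer(ifelse(seq_raw == "" | is.na(seq_raw),
                              seq_len(nrow(tab)), seq_raw)),
      code = blank_na(g("code")),
      term = blank_na(g("decod")),
      occur_flag = blank_na(g("occur")),
      status_flag = blank_na(g("stat")),
      timepoint = blank_na(g("tpt")),
      start_raw = blank_na(g("start")),
      end_raw = blank_na(g("end")),
      date_raw = blank_na(g("date")),
      testcd = blank_na(g("testcd")),
      value_chr = blank_na(g("orres")),
      unit = blank_na(g("unit")),
      method = blank_na(g("method")),
      severity = blank_na(g("sev")),
      causality = blank_na(g("rel")),
      outcome = blank_na(g("out")),
      category = blank_na(g("cat")),
      source = blank_na(g("src")),
      stringsAsFactors = FALSE
    )
    # findings domains record a single --DTC; events use --STDTC/--ENDTC
    rec$start_raw <- ifelse(is.na(rec$start_raw), rec$date_raw, rec$start_raw)
    rec$date_raw <- NULL
    rec$vocab <- if (dom %in% .event_domains) {
      ifelse(!is.na(rec$code), "MedDRA",
             ifelse(!is.na(rec$term), "free-text", NA_character_))
    } else if (dom %in% .drug_domains) {
      ifelse(!is.na(rec$code), "WHODrug",
             ifelse(!is.na(rec$term), "free-text", NA_character_))
    } else if (dom %in% .finding_domains) {
      ifelse(!is.na(rec$testcd), "SDTM-TEST", NA_character_)
    } else if (dom %in% c("DS", "DD")) {
      NA_character_
    } else {
      ifelse(!is.na(rec$term), "free-text", NA_character_)
    }
    rec$source_value <- ifelse(!is.na(rec$code), rec$code,
                        ifelse(!is.na(rec$testcd), rec$testcd,
                        ifelse(!is.na(rec$term), rec$term, "")))
    out[[dom]] <- rec
  }
  if (!length(out)) {
    return(data.frame(patient_id = character(), domain = character(),
                      seq = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  key <- paste(res$patient_id, res$domain, res$seq)
  if (anyDuplicated(key))
    warning("duplicate (patient, domain, seq) keys present", call. = FALSE)
  res[order(res$patient_id, res$domain, res$seq), , drop = FALSE]
}
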