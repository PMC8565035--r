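#' Mapping configuration
#'
#' A `mapping_config` gathers everything about a transformation run that is
#' study-specific rather than algorithmic: the study design, the study end
#' date, how timepoint labels anchor to the patient reference timeline, which
#' of the alternative disposition concepts to emit, variable-name overrides
#' for non-standard SDTM column names, and a drop-list of variables judged
#' irrelevant to analyses (empty by default).
#'
#' @param study_id study label written into enrollment observations.
#' @param design `"prospective"` or `"retrospective"`.
#' @param study_end_date ISO-8601 date string or NULL (ongoing study).
#' @param timepoints named list mapping timepoint labels (upper-cased) to a
#'   list with `anchor` (one of `"drug_initiation"`, `"drug_end"`,
#'   `"last_available_info"`, `"last_followup_visit"`, `"study_end"`,
#'   `"min_drug_end_study_end"`, `"enrollment"`) and integer `offset_days`.
#' @param disposition named list choosing the observation concept per
#'   disposition category (`enrollment`, `consent`, `completed`, `withdrawn`).
#' @param var_overrides named list `domain -> (role -> column name)`
#'   overriding the SDTM naming conventions.
#' @param drop_vars character vector of variable names excluded from mapping.
#' @return An object of class `mapping_config`.
#' @export
mapping_config <- function(study_id = "STUDY",
                           design = c("prospective", "retrospective"),
                           study_end_date = NULL,
                           timepoints = default_timepoints(),
                           disposition = default_disposition_concepts(),
                           var_overrides = list(),
                           drop_vars = character()) {
  design <- match.arg(design)
  end <- NULL
  if (!is.null(study_end_date)) {
    end <- parse_partial_date(study_end_date)
    if (attr(end, "failed")[1])
      stop("study_end_date is not an ISO-8601 date prefix: ", study_end_date,
           call. = FALSE)
  }
  structure(list(study_id = study_id,
                 design = design,
                 study_end_date = end,
                 timepoints = timepoints,
                 disposition = disposition,
                 var_overrides = var_overrides,
                 drop_vars = toupper(drop_vars)),
            class = "mapping_config")
}

#' Default timepoint-to-anchor table
#'
#' Timepoint labels are study vocabulary, not standard SDTM, so the mapping
#' from label to reference anchor is configuration. The defaults cover the
#' labels the synthetic generator emits.
#' @return named list of `(anchor, offset_days)` entries.
#' @export
default_timepoints <- function() {
  list(
    "DRUG INITIATION" = list(anchor = "drug_initiation", offset_days = 0L),
    "LAST AVAILABLE" = list(anchor = "min_drug_end_study_end",
                            offset_days = 0L),
    "BEFORE DISCONTINUATION" = list(anchor = "last_available_info",
                                    offset_days = 0L),
    "WITHIN 3 MONTHS OF BASELINE" = list(anchor = "enrollment",
                                         offset_days = 0L)
  )
}

#' Default disposition concept choices
#'
#' The CDM offers more than one plausible observation concept per disposition
#' category; the choice is fixed per run in the config.
#' @return named list of concept ids.
#' @export
default_disposition_concepts <- function() {
  list(enrollment = 44807982L,   # Participant in research study
       consent = 44811375L,      # Consent given to participate in research
       completed = 44810922L,    # Participation in research study completed
       withdrawn = 44810920L)    # Withdrawn from research study
}

#' Read a mapping configuration from a YAML file
#'
#' @param path path to a YAML file; recognised keys mirror the arguments of
#'   [mapping_config()].
#' @return A `mapping_config`.
#' @export
read_mapping_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  args <- list()
  for (key in c("study_id", "design", "study_end_date", "drop_vars"))
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  if (!is.null(raw$timepoints)) {
    tp <- lapply(raw$timepoints, function(x)
      list(anchor = x$anchor,
           offset_days = as.integer(x$offset_days %||% 0L)))
    names(tp) <- toupper(names(raw$timepoints))
    args$timepoints <- tp
  }
  if (!is.null(raw$disposition)) {
    d <- default_disposition_concepts()
    for (nm in names(raw$disposition)) d[[nm]] <- as.integer(raw$disposition[[nm]])
    args$disposition <- d
  }
  if (!is.null(raw$var_overrides)) args$var_overrides <- raw$var_overrides
  do.call(mapping_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mapping_config <- function(x, ...) {
  cat("Mapping configuration\n")
  cat("  study:         ", x$study_id, "\n")
  cat("  design:        ", x$design, "\n")
  cat("  study end:     ",
      if (is.null(x$study_end_date)) "(ongoing)" else format(x$study_end_date),
      "\n")
  cat("  timepoints:    ", length(x$timepoints), "labels\n")
  cat("  drop-list:     ", length(x$drop_vars), "variables\n")
  invisible(x)
}
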