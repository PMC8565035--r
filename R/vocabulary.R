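#' @title OMOP vocabulary store
#' @description
#' A `vocabulary_store` holds the four vocabulary collections the ETL needs:
#' CONCEPT, CONCEPT_RELATIONSHIP, CONCEPT_ANCESTOR and a source-to-standard
#' crosswalk. It is an environment so that custom-concept registration during
#' a run updates the store in place, mirroring how a CDM instance accretes
#' local concepts. Standard concepts carry `standard_concept == "S"`,
#' classification concepts (e.g. MedDRA) `"C"`; custom concepts live in the
#' id range from 2,000,000,000 upwards and exist only in this instance.
#' @name vocabulary_store
NULL

CUSTOM_ID_BASE <- 2000000000L

#' Construct a vocabulary store from in-memory tables
#'
#' @param concepts data frame with Athena-style columns `concept_id`,
#'   `concept_name`, `domain_id`, `vocabulary_id`, `concept_class_id`,
#'   `standard_concept`, `concept_code`.
#' @param relationships data frame `concept_id_1`, `concept_id_2`,
#'   `relationship_id` (`"Maps to"`, `"Is a"`, or custom labels).
#' @param crosswalk data frame `source_vocabulary`, `source_code`,
#'   `target_concept_id`, `priority`, `provenance`.
#' @param ancestors optional precomputed CONCEPT_ANCESTOR data frame; when
#'   NULL the transitive closure is built with [build_ancestor_closure()].
#' @return An environment of class `vocabulary_store`.
#' @export
vocabulary_store <- function(concepts, relationships, crosswalk,
                             ancestors = NULL) {
  store <- new.env(parent = emptyenv())
  concepts$concept_id <- as.numeric(concepts$concept_id)
  concepts$is_custom <- concepts$concept_id >= CUSTOM_ID_BASE
  relationships$concept_id_1 <- as.numeric(relationships$concept_id_1)
  relationships$concept_id_2 <- as.numeric(relationships$concept_id_2)
  crosswalk$target_concept_id <- as.numeric(crosswalk$target_concept_id)
  if (is.null(crosswalk$priority)) crosswalk$priority <- 1L
  store$concepts <- concepts
  store$relationships <- relationships
  store$crosswalk <- crosswalk
  store$ancestors <- ancestors
  store$closure_stale <- is.null(ancestors)
  class(store) <- "vocabulary_store"
  validate_store(store)
  if (store$closure_stale) refresh_closure(store)
  store
}

#' Load a vocabulary store from tab-delimited Athena-style files
#'
#' Reads `CONCEPT.csv`, `CONCEPT_RELATIONSHIP.csv` and optionally
#' `CONCEPT_ANCESTOR.csv` (all tab-delimited, the Athena distribution
#' layout) plus `crosswalk.tsv` from a directory.
#' @param dir_path directory with the vocabulary files.
#' @return A `vocabulary_store`.
#' @export
load_vocabulary <- function(dir_path) {
  if (!dir.exists(dir_path))
    stop("vocabulary directory not found: ", dir_path, call. = FALSE)
  rd <- function(f) utils::read.delim(file.path(dir_path, f),
                                      colClasses = "character",
                                      na.strings = NULL, quote = "")
  concepts <- rd("CONCEPT.csv")
  rel <- rd("CONCEPT_RELATIONSHIP.csv")
  xw <- rd("crosswalk.tsv")
  anc <- NULL
  if (file.exists(file.path(dir_path, "CONCEPT_ANCESTOR.csv"))) {
    anc <- rd("CONCEPT_ANCESTOR.csv")
    for (col in names(anc)) anc[[col]] <- as.numeric(anc[[col]])
  }
  vocabulary_store(concepts, rel, xw, anc)
}

#' Write a store's collections to a directory
#' @param store a `vocabulary_store`.
#' @param dir_path output directory.
#' @return `dir_path`, invisibly.
#' @export
write_vocabulary <- function(store, dir_path) {
  stopifnot(inherits(store, "vocabulary_store"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) utils::write.table(
    x, file.path(dir_path, f), sep = "\t", quote = FALSE, row.names = FALSE)
  cols <- setdiff(names(store$concepts), "is_custom")
  wr(store$concepts[, cols], "CONCEPT.csv")
  wr(store$relationships, "CONCEPT_RELATIONSHIP.csv")
  wr(store$ancestors, "CONCEPT_ANCESTOR.csv")
  wr(store$crosswalk, "crosswalk.tsv")
  invisible(dir_path)
}

#' Validate referential integrity of a vocabulary store
#'
#' Checks that relationship endpoints and crosswalk targets exist, that every
#' crosswalk target is standard or custom, and that every 'Maps to' target is
#' a standard concept. Fatal on violation: a broken store would corrupt every
#' downstream event row.
#' @param store a `vocabulary_store`.
#' @return TRUE, invisibly.
#' @export
validate_store <- function(store) {
  ids <- store$concepts$concept_id
  if (anyDuplicated(ids))
    stop("duplicate concept ids in store", call. = FALSE)
  rel <- store$relationships
  missing_ep <- setdiff(c(rel$concept_id_1, rel$concept_id_2), ids)
  if (length(missing_ep))
    stop("relationship endpoints missing from CONCEPT: ",
         paste(utils::head(missing_ep, 5), collapse = ", "), call. = FALSE)
  xw_missing <- setdiff(store$crosswalk$target_concept_id, ids)
  if (length(xw_missing))
    stop("crosswalk targets missing from CONCEPT: ",
         paste(utils::head(xw_missing, 5), collapse = ", "), call. = FALSE)
  tgt <- concept_info(store, store$crosswalk$target_concept_id)
  bad <- !(tgt$standard_concept == "S" | tgt$is_custom)
  if (any(bad))
    stop("crosswalk targets neither standard nor custom: ",
         paste(utils::head(tgt$concept_id[bad], 5), collapse = ", "),
         call. = FALSE)
  mt <- rel[rel$relationship_id == "Maps to", ]
  if (nrow(mt)) {
    mtt <- concept_info(store, mt$concept_id_2)
    badm <- !(mtt$standard_concept == "S" | mtt$is_custom)
    if (any(badm))
      stop("'Maps to' targets must be standard concepts: ",
           paste(utils::head(mtt$concept_id[badm], 5), collapse = ", "),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Look up concept rows by id
#' @param store a `vocabulary_store`.
#' @param ids concept ids.
#' @return data frame of concept rows in the order of `ids`.
#' @export
concept_info <- function(store, ids) {
  idx <- match(as.numeric(ids), store$concepts$concept_id)
  store$concepts[idx, , drop = FALSE]
}

#' @export
print.vocabulary_store <- function(x, ...) {
  cat("OMOP vocabulary store\n")
  cat("  concepts:     ", nrow(x$concepts),
      sprintf("(%d custom)\n", sum(x$concepts$is_custom)))
  cat("  relationships:", nrow(x$relationships), "\n")
  cat("  ancestors:    ", if (is.null(x$ancestors)) 0 else nrow(x$ancestors),
      if (x$closure_stale) "(stale)\n" else "\n")
  cat("  crosswalk:    ", nrow(x$crosswalk), "entries\n")
  invisible(x)
}

#' Normalise free text for crosswalk lookup
#' @param x character vector.
#' @return lower-cased, whitespace-squashed text.
#' @export
normalize_text <- function(x) {
  tolower(trimws(gsub("\\s+", " ", x)))
}

#' Resolve a source code or text to standard concept ids
#'
#' Lookup order: (1) exact crosswalk entry for `(vocab, code)` -- free text is
#' normalised first; (2) a direct `Maps to` relationship from a source concept
#' carrying that vocabulary and code; (3) empty, signalling an unmapped source
#' value for the unmapped log. One source value may resolve to several
#' standard concepts (one-to-many mapping); all targets are returned, in
#' crosswalk priority order.
#'
#' @param store a `vocabulary_store`.
#' @param vocab source vocabulary (`"MedDRA"`, `"WHODrug"`, `"free-text"`,
#'   `"SDTM-TEST"`, ...).
#' @param code_or_text the source code or verbatim text.
#' @return list with `concept_ids` (numeric, possibly empty), `provenance`
#'   (`"crosswalk"`, `"maps_to"` or `"unmapped"`) and `source_concept_id`
#'   (the non-standard source concept when one exists, else NA).
#' @export
resolve_source <- function(store, vocab, code_or_text) {
  stopifnot(inherits(store, "vocabulary_store"))
  code <- as.character(code_or_text)
  if (is.na(code) || code == "")
    return(list(concept_ids = numeric(), provenance = "unmapped",
                source_concept_id = NA_real_))
  if (vocab == "free-text") code <- normalize_text(code)
  src_row <- store$concepts[store$concepts$vocabulary_id == vocab &
                            store$concepts$concept_code == code, ]
  src_id <- if (nrow(src_row)) src_row$concept_id[1] else NA_real_

  xw <- store$crosswalk
  hit <- xw[xw$source_vocabulary == vocab & xw$source_code == code, ]
  if (nrow(hit)) {
    hit <- hit[order(as.integer(hit$priority)), ]
    return(list(concept_ids = hit$target_concept_id,
                provenance = "crosswalk", source_concept_id = src_id))
  }
  if (!is.na(src_id)) {
    rel <- store$relationships
    mt <- rel[rel$relationship_id == "Maps to" &
              rel$concept_id_1 == src_id, ]
    if (nrow(mt))
      return(list(concept_ids = sort(mt$concept_id_2),
                  provenance = "maps_to", source_concept_id = src_id))
  }
  list(concept_ids = numeric(), provenance = "unmapped",
       source_concept_id = src_id)
}

#' Register a custom concept
#'
#' Allocates the next id at or above 2,000,000,000, records an `Is a`
#' relationship to each parent, and marks the ancestor closure stale.
#' Idempotent on `(name, domain_id)`: re-registering returns the existing id
#' and changes nothing, so a concept introduced for one registry can be
#' reused when mapping the next. Registration never removes or alters any
#' pre-existing concept, relationship or closure row.
#'
#' @param store a `vocabulary_store` (modified in place).
#' @param name concept name.
#' @param domain_id CDM domain (`"Condition"`, `"Observation"`, ...).
#' @param parent_ids concept ids the new concept is a descendant of; may be
#'   empty (an orphan custom concept, e.g. a new observable with no standard
#'   parent). Parents must exist and be standard or custom.
#' @return the concept id (numeric).
#' @export
register_custom_concept <- function(store, name, domain_id,
                                    parent_ids = numeric()) {
  stopifnot(inherits(store, "vocabulary_store"))
  existing <- store$concepts[store$concepts$concept_name == name &
                             store$concepts$domain_id == domain_id &
                             store$concepts$is_custom, ]
  if (nrow(existing)) return(existing$concept_id[1])
  parent_ids <- as.numeric(parent_ids)
  if (length(parent_ids)) {
    pr <- concept_info(store, parent_ids)
    if (anyNA(pr$concept_id))
      stop("unknown parent concept(s): ",
           paste(parent_ids[is.na(pr$concept_id)], collapse = ", "),
           call. = FALSE)
    if (any(!(pr$standard_concept == "S" | pr$is_custom)))
      stop("parents must be standard or custom concepts", call. = FALSE)
  }
  cur_max <- suppressWarnings(
    max(store$concepts$concept_id[store$concepts$is_custom]))
  new_id <- if (is.finite(cur_max)) cur_max + 1 else CUSTOM_ID_BASE
  row <- store$concepts[0, ]
  row[1, "concept_id"] <- new_id
  row[1, "concept_name"] <- name
  row[1, "domain_id"] <- domain_id
  row[1, "vocabulary_id"] <- "Custom"
  if ("concept_class_id" %in% names(row)) row[1, "concept_class_id"] <- "Custom"
  row[1, "standard_concept"] <- "S"
  if ("concept_code" %in% names(row))
    row[1, "concept_code"] <- normalize_text(name)
  row[1, "is_custom"] <- TRUE
  store$concepts <- rbind(store$concepts, row)
  if (length(parent_ids)) {
    rel <- store$relationships[rep(1L, length(parent_ids)), , drop = FALSE]
    if (!nrow(store$relationships)) {
      rel <- data.frame(concept_id_1 = parent_ids, concept_id_2 = parent_ids,
                        relationship_id = "Is a")
    }
    rel[] <- NA
    rel$concept_id_1 <- new_id
    rel$concept_id_2 <- parent_ids
    rel$relationship_id <- "Is a"
    rownames(rel) <- NULL
    store$relationships <- rbind(store$relationships, rel)
  }
  store$closure_stale <- TRUE
  new_id
}

#' Declare a combination of concepts for a granular clinical entity
#'
#' Disease subgroups absent from the standard vocabulary can sometimes be
#' expressed as a combination of existing standard concepts (e.g. pulmonary
#' arterial hypertension plus an aetiology qualifier) rather than a new
#' custom concept. The combination is a declarative recipe: the ETL emits one
#' event row per member and links the qualifiers to the primary row via
#' FACT_RELATIONSHIP.
#'
#' @param store a `vocabulary_store`.
#' @param primary_id concept id of the primary condition.
#' @param qualifier_ids concept ids of qualifier conditions; empty gives the
#'   trivial one-row recipe.
#' @return object of class `concept_combination` with `primary`,
#'   `qualifiers` and `n_rows`.
#' @export
combine_concepts <- function(store, primary_id, qualifier_ids = numeric()) {
  ids <- c(primary_id, qualifier_ids)
  info <- concept_info(store, ids)
  if (anyNA(info$concept_id))
    stop("unknown concept id(s) in combination: ",
         paste(ids[is.na(info$concept_id)], collapse = ", "), call. = FALSE)
  structure(list(primary = as.numeric(primary_id),
                 qualifiers = as.numeric(qualifier_ids),
                 n_rows = 1L + length(qualifier_ids)),
            class = "concept_combination")
}

#' @export
print.concept_combination <- function(x, ...) {
  cat("Concept combination:", x$n_rows, "row recipe\n")
  cat("  primary:   ", x$primary, "\n")
  if (length(x$qualifiers))
    cat("  qualifiers:", paste(x$qualifiers, collapse = ", "), "\n")
  invisible(x)
}

#' Build the CONCEPT_ANCESTOR transitive closure
#'
#' Computes, for every ordered pair (ancestor, descendant) connected through
#' `Is a` edges, the shortest and longest path lengths over the hierarchy
#' DAG, plus a `(c, c, 0, 0)` self row for every hierarchy member (OMOP
#' convention). `max_levels` is well-defined because the graph is required
#' acyclic; a cycle aborts with the offending concept ids.
#'
#' @param x a `vocabulary_store` (members = all concepts in the store) or a
#'   relationship data frame with columns `concept_id_1` (descendant),
#'   `concept_id_2` (ancestor) and `relationship_id` (only `"Is a"` rows are
#'   used); members are then the nodes of the edge set.
#' @return data frame `ancestor_concept_id`, `descendant_concept_id`,
#'   `min_levels_of_separation`, `max_levels_of_separation`, sorted.
#' @export
build_ancestor_closure <- function(x) {
  if (inherits(x, "vocabulary_store")) {
    rel <- x$relationships
    members <- x$concepts$concept_id
  } else {
    rel <- x
    members <- numeric()
  }
  isa <- rel[rel$relationship_id == "Is a", , drop = FALSE]
  child <- as.numeric(isa$concept_id_1)
  parent <- as.numeric(isa$concept_id_2)
  members <- sort(unique(c(members, child, parent)))
  n <- length(members)
  idx <- function(id) match(id, members)
  ch <- idx(child); pa <- idx(parent)

  # Kahn's algorithm over parent -> child direction for a topological order
  # in which every parent precedes its children.
  kids <- split(ch, pa)
  indeg <- tabulate(ch, nbins = n)  # number of parents per node
  queue <- which(indeg == 0L)
  topo <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    topo <- c(topo, v)
    for (w in kids[[as.character(v)]] %||% integer(0)) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(topo) < n) {
    cyc <- members[setdiff(seq_len(n), topo)]
    stop("'Is a' hierarchy contains a cycle involving concepts: ",
         paste(cyc, collapse = ", "), call. = FALSE)
  }

  parents_of <- split(pa, ch)
  anc_min <- vector("list", n)
  anc_max <- vector("list", n)
  for (v in topo) {
    ps <- parents_of[[as.character(v)]] %||% integer(0)
    if (!length(ps)) {
      anc_min[[v]] <- numeric(0); anc_max[[v]] <- numeric(0)
      next
    }
    mn <- list(); mx <- list()
    for (p in ps) {
      cand_mn <- c(stats::setNames(1, p), anc_min[[p]] + 1)
      cand_mx <- c(stats::setNames(1, p), anc_max[[p]] + 1)
      mn[[length(mn) + 1]] <- cand_mn
      mx[[length(mx) + 1]] <- cand_mx
    }
    mn <- unlist(mn); mx <- unlist(mx)
    anc_min[[v]] <- tapply(mn, names(mn), min)
    anc_max[[v]] <- tapply(mx, names(mx), max)
  }

  rows <- vector("list", n + 1)
  rows[[1]] <- data.frame(ancestor_concept_id = members,
                          descendant_concept_id = members,
                          min_levels_of_separation = numeric(n),
                          max_levels_of_separation = numeric(n))
  for (v in seq_len(n)) {
    a <- anc_min[[v]]
    if (is.null(a) || !length(a)) next
    ord <- order(as.numeric(names(a)))
    rows[[v + 1]] <- data.frame(
      ancestor_concept_id = members[as.integer(names(a))[ord]],
      descendant_concept_id = members[v],
      min_levels_of_separation = as.numeric(a)[ord],
      max_levels_of_separation = as.numeric(anc_max[[v]])[
        order(as.numeric(names(anc_max[[v]])))])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(out$ancestor_concept_id, out$descendant_concept_id), ]
  rownames(out) <- NULL
  out
}

#' Rebuild a store's ancestor closure in place
#' @param store a `vocabulary_store`.
#' @return the store, invisibly.
#' @export
refresh_closure <- function(store) {
  stopifnot(inherits(store, "vocabulary_store"))
  store$ancestors <- build_ancestor_closure(store)
  store$closure_stale <- FALSE
  invisible(store)
}

# CDM table metadata concept ids used in FACT_RELATIONSHIP domain columns.
# The observation (1147304) and measurement (1147330) ids follow the CDM
# vocabulary; the remaining tables use fixture metadata ids in the same range.
.cdm_table_concepts <- c(condition_occurrence = 1147333,
                         drug_exposure = 1147339,
                         measurement = 1147330,
                         observation = 1147304,
                         procedure_occurrence = 1147301,
                         visit_occurrence = 1147332)

.domain_to_table <- c(Condition = "condition_occurrence",
                      Drug = "drug_exposure",
                      Measurement = "measurement",
                      Observation = "observation",
                      Procedure = "procedure_occurrence",
                      Visit = "visit_occurrence")

#' Lint the store against the CDM routing map
#'
#' Every crosswalk target's domain must determine a unique CDM event table;
#' a target outside the routable domains is a vocabulary bug that would make
#' [route_record()] fail mid-run, so it is caught up front.
#' @param store a `vocabulary_store`.
#' @return TRUE, invisibly; fatal otherwise.
#' @export
lint_vocabulary <- function(store) {
  tgt <- concept_info(store, unique(store$crosswalk$target_concept_id))
  routable <- names(.domain_to_table)
  bad <- !(tgt$domain_id %in% c(routable, "Meas Value"))
  if (any(bad))
    stop("crosswalk targets with unroutable domain: ",
         paste(sprintf("%s (%s)", tgt$concept_id[bad], tgt$domain_id[bad]),
               collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
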