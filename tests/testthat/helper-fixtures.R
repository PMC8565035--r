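# Shared fixtures: built in code at test time, nothing stored on disk.

# the bundled miniature vocabulary, loaded once per test run
test_store <- local({
  store <- NULL
  function() {
    if (is.null(store)) store <<- load_vocabulary(example_vocabulary())
    store
  }
})

# write a study to a temp dir and read it back through the package I/O
local_study <- function(tables, violators = character(),
                        config = mapping_config(), env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  for (dom in names(tables))
    utils::write.csv(tables[[dom]], file.path(dir, paste0(dom, ".csv")),
                     row.names = FALSE)
  if (length(violators))
    utils::write.csv(data.frame(USUBJID = violators),
                     file.path(dir, "VIOLATORS.csv"), row.names = FALSE)
  read_study(dir, config)
}

dm_row <- function(id, birth = "1950", sex = "F", enroll = "2015-01-10") {
  data.frame(USUBJID = id, BRTHDTC = birth, SEX = sex, RFSTDTC = enroll,
             COUNTRY = "US", stringsAsFactors = FALSE)
}

# independent brute-force ancestor-closure oracle: exhaustive DFS path
# enumeration over 'Is a' edges (child -> parent), min/max path lengths
oracle_closure <- function(edges) {
  nodes <- sort(unique(c(edges$child, edges$parent)))
  all_paths <- function(v) {
    out <- list()
    for (p in edges$parent[edges$child == v]) {
      key <- as.character(p)
      out[[key]] <- c(out[[key]], 1)
      sub <- all_paths(p)
      for (a in names(sub)) out[[a]] <- c(out[[a]], sub[[a]] + 1)
    }
    out
  }
  rows <- data.frame(ancestor_concept_id = nodes,
                     descendant_concept_id = nodes,
                     min_levels_of_separation = 0,
                     max_levels_of_separation = 0)
  for (v in nodes) {
    ap <- all_paths(v)
    for (a in names(ap))
      rows <- rbind(rows, data.frame(
        ancestor_concept_id = as.numeric(a), descendant_concept_id = v,
        min_levels_of_separation = min(ap[[a]]),
        max_levels_of_separation = max(ap[[a]])))
  }
  rows <- rows[order(rows$ancestor_concept_id, rows$descendant_concept_id), ]
  rownames(rows) <- NULL
  rows
}

# random DAG with edges from higher-numbered child to lower-numbered parent
random_dag <- function(n, p_edge = 0.1) {
  child <- integer(0); parent <- integer(0)
  for (c_ in 2:n) for (p_ in 1:(c_ - 1))
    if (stats::runif(1) < p_edge) {
      child <- c(child, c_); parent <- c(parent, p_)
    }
  data.frame(child = child, parent = parent)
}
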