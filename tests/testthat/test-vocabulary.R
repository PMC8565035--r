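test_that("source resolution follows crosswalk, then 'Maps to', then unmapped", {
  store <- test_store()
  # one-to-many crosswalk entry, priority order preserved
  res <- resolve_source(store, "MedDRA", "10057688")
  expect_equal(res$concept_ids, c(4249456, 4183956))
  expect_equal(res$provenance, "crosswalk")
  expect_equal(res$source_concept_id, 35000001)
  # free text resolves through normalisation to a custom concept
  res <- resolve_source(store, "free-text", "Drug- and Toxin-induced PAH")
  expect_equal(res$concept_ids, 2000000001)
  # unmapped values come back empty, not as an error
  expect_length(resolve_source(store, "free-text", "zzz-nonsense")$concept_ids,
                0)
  expect_equal(resolve_source(store, "free-text", "zzz")$provenance,
               "unmapped")

  # 'Maps to' is the fallback when no crosswalk entry exists
  concepts <- data.frame(
    concept_id = c(1, 2), concept_name = c("src", "std"),
    domain_id = "Condition", vocabulary_id = c("MedDRA", "SNOMED"),
    concept_class_id = "PT", standard_concept = c("C", "S"),
    concept_code = c("123", "s1"))
  rel <- data.frame(concept_id_1 = 1, concept_id_2 = 2,
                    relationship_id = "Maps to")
  xw <- data.frame(source_vocabulary = character(), source_code = character(),
                   target_concept_id = numeric(), priority = integer(),
                   provenance = character())
  st2 <- vocabulary_store(concepts, rel, xw)
  res <- resolve_source(st2, "MedDRA", "123")
  expect_equal(res$concept_ids, 2)
  expect_equal(res$provenance, "maps_to")
})

test_that("resolution is a pure function of (vocab, code, store)", {
  store <- test_store()
  a <- resolve_source(store, "MedDRA", "10038435")
  b <- resolve_source(store, "MedDRA", "10038435")
  expect_identical(a, b)
})

test_that("custom concept registration allocates >= 2e9 ids, is idempotent and monotone", {
  store <- load_vocabulary(example_vocabulary())  # fresh: registration mutates
  before_concepts <- store$concepts
  before_closure <- store$ancestors
  pah <- 4000010
  id1 <- register_custom_concept(store, "Severe drug- and toxin-induced PAH",
                                 "Condition", pah)
  expect_gte(id1, 2000000000)
  expect_true(any(store$relationships$concept_id_1 == id1 &
                  store$relationships$concept_id_2 == pah &
                  store$relationships$relationship_id == "Is a"))
  id2 <- register_custom_concept(store, "Severe drug- and toxin-induced PAH",
                                 "Condition", pah)
  expect_identical(id1, id2)
  # orphan custom concepts (no standard parent) are permitted
  orphan <- register_custom_concept(store, "Registry-specific scale",
                                    "Observation")
  expect_gte(orphan, 2000000000)
  expect_error(register_custom_concept(store, "bad", "Condition", 999999999),
               "unknown parent")
  # monotonicity: nothing pre-existing was removed or altered
  expect_identical(
    store$concepts[seq_len(nrow(before_concepts)), names(before_concepts)],
    before_concepts)
  refresh_closure(store)
  merged <- merge(before_closure, store$ancestors,
                  by = c("ancestor_concept_id", "descendant_concept_id"))
  expect_equal(merged$min_levels_of_separation.x,
               merged$min_levels_of_separation.y)
  expect_equal(nrow(merged), nrow(before_closure))
  # new custom concept sits under the full chain PAH -> PH
  expect_true(any(store$ancestors$ancestor_concept_id == 4322024 &
                  store$ancestors$descendant_concept_id == id1 &
                  store$ancestors$min_levels_of_separation == 2))
})

test_that("concept combinations are declarative multi-row recipes", {
  store <- test_store()
  two <- combine_concepts(store, 4000010, 4000030)
  expect_equal(two$n_rows, 2L)
  expect_equal(two$primary, 4000010)
  chd <- combine_concepts(store, 4000010, 4000040)
  expect_equal(chd$n_rows, 2L)
  one <- combine_concepts(store, 4000010)
  expect_equal(one$n_rows, 1L)
  expect_error(combine_concepts(store, 4000010, 12345678901), "unknown")
})

test_that("ancestor closure matches hand-enumerated chains and diamonds", {
  isa <- function(child, parent)
    data.frame(concept_id_1 = child, concept_id_2 = parent,
               relationship_id = rep("Is a", length(child)))
  # chain D -> B -> A
  chain <- build_ancestor_closure(rbind(isa(4, 2), isa(2, 1)))
  expect_equal(chain, data.frame(
    ancestor_concept_id = c(1, 1, 1, 2, 2, 4),
    descendant_concept_id = c(1, 2, 4, 2, 4, 4),
    min_levels_of_separation = c(0, 1, 2, 0, 1, 0),
    max_levels_of_separation = c(0, 1, 2, 0, 1, 0)))
  # diamond D->B->A, D->C->A: two equal-length paths
  diamond <- rbind(isa(4, 2), isa(4, 3), isa(2, 1), isa(3, 1))
  cl <- build_ancestor_closure(diamond)
  ad <- cl[cl$ancestor_concept_id == 1 & cl$descendant_concept_id == 4, ]
  expect_equal(ad$min_levels_of_separation, 2)
  expect_equal(ad$max_levels_of_separation, 2)
  # an extra direct edge D->A splits min and max
  cl2 <- build_ancestor_closure(rbind(diamond, isa(4, 1)))
  ad2 <- cl2[cl2$ancestor_concept_id == 1 & cl2$descendant_concept_id == 4, ]
  expect_equal(ad2$min_levels_of_separation, 1)
  expect_equal(ad2$max_levels_of_separation, 2)
  # no edges: self rows only
  none <- build_ancestor_closure(isa(numeric(0), numeric(0)))
  expect_equal(nrow(none), 0)
})

test_that("closure equals the brute-force path-enumeration oracle on random DAGs", {
  set.seed(2024)
  for (rep in 1:12) {
    n <- sample(5:50, 1)
    edges <- random_dag(n, p_edge = runif(1, 0.03, 0.12))
    if (!nrow(edges)) next
    got <- build_ancestor_closure(
      data.frame(concept_id_1 = edges$child, concept_id_2 = edges$parent,
                 relationship_id = "Is a"))
    want <- oracle_closure(edges)
    rownames(got) <- NULL
    expect_equal(got, want, info = paste("rep", rep))
  }
})

test_that("a cycle in the hierarchy is fatal and names the cycle", {
  bad <- data.frame(concept_id_1 = c(1, 2, 3), concept_id_2 = c(2, 3, 1),
                    relationship_id = "Is a")
  expect_error(build_ancestor_closure(bad), "cycle")
})

test_that("the store validates referential integrity and 'Maps to' targets", {
  concepts <- data.frame(
    concept_id = c(1, 2), concept_name = c("a", "b"),
    domain_id = "Condition", vocabulary_id = "SNOMED",
    concept_class_id = "X", standard_concept = c("C", "S"),
    concept_code = c("1", "2"))
  empty_xw <- data.frame(source_vocabulary = character(),
                         source_code = character(),
                         target_concept_id = numeric(),
                         priority = integer(), provenance = character())
  expect_error(vocabulary_store(
    concepts,
    data.frame(concept_id_1 = 1, concept_id_2 = 99,
               relationship_id = "Is a"), empty_xw), "missing")
  # 'Maps to' into a classification concept is invalid
  expect_error(vocabulary_store(
    concepts,
    data.frame(concept_id_1 = 2, concept_id_2 = 1,
               relationship_id = "Maps to"), empty_xw), "Maps to")
  # crosswalk target must be standard or custom
  expect_error(vocabulary_store(
    concepts,
    data.frame(concept_id_1 = numeric(), concept_id_2 = numeric(),
               relationship_id = character()),
    data.frame(source_vocabulary = "MedDRA", source_code = "x",
               target_concept_id = 1, priority = 1,
               provenance = "manual")), "neither standard nor custom")
  expect_silent(lint_vocabulary(test_store()))
})
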