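test_that("parse_obo reads terms, names, synonyms and is_a links", {
  ont <- parse_obo(mini_obo)
  expect_length(ont$concepts, 3)
  expect_equal(ont$roots, "X:1")
  expect_equal(ont$concepts[["X:3"]]$parents, "X:2")
  expect_equal(ont$concepts[["X:3"]]$synonyms, "leafy")

  # fixture: medial meniscus sits under meniscus
  expect_equal(toy_ont$concepts[["TRAK:0001090"]]$name, "medial meniscus")
  expect_equal(toy_ont$concepts[["TRAK:0001090"]]$parents, "TRAK:0000045")

  expect_length(parse_obo("")$concepts, 0)
})

test_that("parse_obo rejects malformed stanzas and is_a cycles", {
  expect_error(parse_obo("[Term]\nid: A:1\nthis is not a tag line"),
               "malformed")
  cyc <- "[Term]\nid: A:1\nname: a\nis_a: A:2\n\n[Term]\nid: A:2\nname: b\nis_a: A:1"
  expect_error(parse_obo(cyc), "cyclic")
  expect_error(parse_obo("[Term]\nid: A:1\nname: a\nis_a: A:9"),
               "unresolved")
})

test_that("obsolete terms are dropped", {
  obo <- paste(mini_obo,
               "\n[Term]\nid: X:4\nname: gone\nis_obsolete: true\n")
  expect_length(parse_obo(obo)$concepts, 3)
})

test_that("descendants is the reflexive-transitive closure", {
  expect_equal(descendants(parse_obo(mini_obo), "X:3"), "X:3")
  expect_true(all(c("TRAK:0000051", "TOY:0000013", "TRAK:0000049") %in%
                    descendants(toy_ont, "TRAK:0001027")))
  expect_error(descendants(toy_ont, "TRAK:9999999"), "unknown")
})

test_that("descendants agrees with brute-force reachability on a random DAG", {
  set.seed(42)
  n <- 10
  ids <- sprintf("N:%d", 1:n)
  stanzas <- character()
  edges <- list()
  for (i in seq_len(n)) {
    parents <- if (i == 1) integer() else
      sample(seq_len(i - 1), sample(0:min(2, i - 1), 1))
    edges[[i]] <- parents
    stanzas <- c(stanzas, "[Term]", sprintf("id: %s", ids[i]),
                 sprintf("name: node %d", i),
                 sprintf("is_a: %s", ids[parents]), "")
  }
  ont <- parse_obo(paste(stanzas, collapse = "\n"))
  # independent reachability: children adjacency + loop to fixpoint
  reach <- function(start) {
    kids <- function(x) ids[vapply(seq_len(n), function(j)
      x %in% ids[edges[[j]]], logical(1))]
    seen <- start
    repeat {
      nxt <- setdiff(unlist(lapply(seen, kids)), seen)
      if (!length(nxt)) return(sort(seen))
      seen <- c(seen, nxt)
    }
  }
  for (id in ids) {
    expect_setequal(descendants(ont, id), reach(id))
  }
  # monotonicity along is-a edges: child closure inside parent closure
  for (i in seq_len(n)) {
    for (p in edges[[i]]) {
      expect_true(all(descendants(ont, ids[i]) %in% descendants(ont, ids[p])))
    }
  }
})

test_that("semantic_slot types concepts by their ancestry", {
  expect_equal(semantic_slot(toy_ont, "TOY:0000101"), "finding_qualifier")
  expect_equal(semantic_slot(toy_ont, "TRAK:0001090"), "anatomy")
  expect_equal(semantic_slot(toy_ont, "TOY:0000157"), "finding")
  expect_equal(semantic_slot(toy_ont, "TOY:0000119"), "certainty")
  # outside every type root
  expect_true(is.na(semantic_slot(toy_ont, "TRAK:0000133")))
  # an id under the roots of two different slots is a configuration error
  bad_map <- c("TRAK:0000045" = "anatomy", "TRAK:0001089" = "finding")
  expect_error(semantic_slot(toy_ont, "TRAK:0001089", bad_map), "several")
  # two roots mapping to the SAME slot are fine
  ok_map <- c("TRAK:0000045" = "anatomy", "TRAK:0001089" = "anatomy")
  expect_equal(semantic_slot(toy_ont, "TRAK:0001089", ok_map), "anatomy")
})

test_that("compile_dictionary applies remaps, ignores and informal additions", {
  dict <- toy_dict
  # remapped surface points at the child concept; the parent is not exported
  je <- dict$entries[dict$entries$surface == "joint effusion", ]
  expect_equal(je$concept_id, "TRAK:0001411")
  expect_false("TRAK:0001410" %in% dict$entries$concept_id)
  # composite branch not exported; its components are
  expect_false("TRAK:0000513" %in% dict$entries$concept_id)
  expect_true(any(dict$entries$surface == "acl" &
                    dict$entries$concept_id == "TRAK:0000049"))
  expect_true(any(dict$entries$surface == "rupture" &
                    dict$entries$concept_id == "TRAK:0000211"))
  # informal verb form present and flagged
  rupt <- dict$entries[dict$entries$surface == "ruptured", ]
  expect_equal(rupt$concept_id, "TRAK:0000211")
  expect_false(rupt$official)
  # idf defined for every entry token
  expect_true(all(unlist(dict$tokens) %in% names(dict$idf)))
})

test_that("compile_dictionary is deterministic and honours the ignore set", {
  d1 <- compile_dictionary(toy_ont, toy_cfg$overrides)
  d2 <- compile_dictionary(toy_ont, toy_cfg$overrides)
  expect_identical(d1$entries, d2$entries)
  ignored <- c("TRAK:0001410",
               descendants(toy_ont, "TRAK:0000513"))
  expect_length(intersect(d1$entries$concept_id, ignored), 0)
})

test_that("override validation rejects unknown ids and ignore/remap clashes", {
  expect_error(
    compile_dictionary(toy_ont, dict_overrides(
      ignored_concepts = "TRAK:4242424")), "unknown")
  expect_error(
    compile_dictionary(toy_ont, dict_overrides(
      ignored_concepts = "TRAK:0001411",
      remaps = data.frame(surface = "joint effusion",
                          from = "TRAK:0001410", to = "TRAK:0001411"))),
    "remap target")
})
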