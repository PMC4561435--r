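test_that("slot candidates follow semantic typing with the cartilage override", {
  doc <- "There is early fissuring of the hyaline cartilage of the lateral patellar facet."
  tk <- tokenize(doc)
  m <- match_dictionary(tk, 1, nrow(tk), toy_dict, toy_cfg$match, doc)
  m$uid <- seq_len(nrow(m))
  lab <- assign_slot_candidates(m, toy_ont, cartilage_id = "TOY:0000017")
  expect_equal(lab$slot[lab$text == "hyaline cartilage"], "anatomy")
  expect_equal(lab$slot[lab$text == "lateral patellar facet"],
               "anatomy_qualifier")

  # without a co-occurring cartilage mention, anatomy keeps its slot
  doc2 <- "There is oedema in the lateral patellar facet."
  tk2 <- tokenize(doc2)
  m2 <- match_dictionary(tk2, 1, nrow(tk2), toy_dict, toy_cfg$match, doc2)
  m2$uid <- seq_len(nrow(m2))
  lab2 <- assign_slot_candidates(m2, toy_ont, cartilage_id = "TOY:0000017")
  expect_equal(lab2$slot[lab2$text == "lateral patellar facet"], "anatomy")

  # certainty descriptors are certainty candidates
  doc3 <- "This raises the possibility of a patella dislocation."
  tk3 <- tokenize(doc3)
  m3 <- match_dictionary(tk3, 1, nrow(tk3), toy_dict, toy_cfg$match, doc3)
  m3$uid <- seq_len(nrow(m3))
  lab3 <- assign_slot_candidates(m3, toy_ont)
  expect_equal(lab3$slot[lab3$text == "possibility"], "certainty")

  expect_equal(nrow(assign_slot_candidates(m3[0, ], toy_ont)), 0)
})

test_that("compatibility rules require soft tissue for tears", {
  expect_true(check_compatibility("TOY:0000158", "TRAK:0001027", toy_ont))
  expect_true(check_compatibility("TOY:0000157", "TRAK:0000053", toy_ont))
  expect_false(check_compatibility("TOY:0000157", "TOY:0000022", toy_ont))
  expect_false(check_compatibility("TRAK:0000211", "TOY:0000019", toy_ont))
  # a finding with no applicable rule accepts anything
  expect_true(check_compatibility("TOY:0000150", "TOY:0000022", toy_ont))
})

test_that("single-finding filling attaches all within-segment fillers", {
  res <- process_report("There is a small undisplaced vertical radial tear of the posterior horn of the lateral meniscus.", toy_cfg)
  expect_length(res$records, 1)
  r <- res$records[[1]]
  expect_equal(r$finding$id, "TOY:0000158")
  expect_null(r$negation)
  expect_equal(r$anatomy$id, "TRAK:0001089")
  expect_setequal(vapply(r$finding_qualifiers, `[[`, "", "id"),
                  c("TOY:0000101", "TOY:0000112", "TRAK:0001388"))
  expect_equal(vapply(r$anatomy_qualifiers, `[[`, "", "id"), "TOY:0000172")
  # offsets index into the document
  doc <- "There is a small undisplaced vertical radial tear of the posterior horn of the lateral meniscus."
  expect_equal(substr(doc, r$anatomy$start + 1,
                      r$anatomy$start + r$anatomy$offset), r$anatomy$text)
})

test_that("anatomy is backtracked from preceding segments when compatible", {
  res <- process_report("There is a vertical longitudinal tear of the peripheral aspect of the posterior third of the medial meniscus. The tear does not appear significant.", toy_cfg)
  expect_length(res$records, 2)
  r2 <- res$records[[2]]
  expect_equal(r2$finding$id, "TOY:0000157")
  expect_equal(r2$anatomy$id, "TRAK:0001090")
  expect_null(r2$negation)  # "not" follows the finding, so no attachment
})

test_that("noun-phrase structure links anatomy qualifiers to their anatomy", {
  res <- process_report("There is marrow oedema at the medial aspect of the patella and the lateral aspect of the lateral femoral condyle.", toy_cfg)
  expect_length(res$records, 2)
  expect_true(record_matching(res$records,
                              list(finding_id = "TOY:0000150",
                                   anatomy_id = "TOY:0000022",
                                   aq_ids = "TRAK:0000031")))
  expect_true(record_matching(res$records,
                              list(finding_id = "TOY:0000150",
                                   anatomy_id = "TRAK:0001037",
                                   aq_ids = "TOY:0000135")))
})

test_that("two findings divide fillers at the first finding's end", {
  res <- process_report("HISTORY Lateral joint line tenderness meniscal tear.", toy_cfg)
  expect_true(record_matching(res$records,
                              list(finding_id = "TOY:0000151",
                                   anatomy_id = "TOY:0000028")))
  expect_true(record_matching(res$records,
                              list(finding_id = "TOY:0000157",
                                   anatomy_id = "TRAK:0000045")))
})

test_that("'or' shares the non-finding fillers between both records", {
  res <- process_report("There is bone bruising or subchondral marrow oedema at the inferior patella.", toy_cfg)
  expect_length(res$records, 2)
  for (spec in list(list(finding_id = "TOY:0000154"),
                    list(finding_id = "TOY:0000150"))) {
    spec$anatomy_id <- "TOY:0000022"
    spec$aq_ids <- "TOY:0000137"
    expect_true(record_matching(res$records, spec))
  }
})

test_that("negation attaches only when the cue precedes the finding", {
  for (res in list(
    process_report("No bone marrow lesion identified.", toy_cfg),
    process_report("There is general attenuation of the body of the medial meniscus without a discrete tear.", toy_cfg))) {
    for (r in res$records) {
      if (!is.null(r$negation)) {
        expect_lt(r$negation$start, r$finding$start)
      }
    }
  }
})

test_that("self-contained findings skip the anatomy search", {
  res <- process_report("The patella is normal. There is Osgood-Schlatter disease.", toy_cfg)
  osd <- Filter(function(r) r$finding$id == "TOY:0000167", res$records)
  expect_length(osd, 1)
  expect_null(osd[[1]]$anatomy)
})

test_that("equivalent zone phrases map to the same concept id", {
  r1 <- process_report("There is a tear of the posterior horn of the lateral meniscus.", toy_cfg)$records[[1]]
  r2 <- process_report("There is a tear of the posterior third of the lateral meniscus.", toy_cfg)$records[[1]]
  expect_equal(r1$anatomy_qualifiers[[1]]$id, r2$anatomy_qualifiers[[1]]$id)
})

test_that("JSON serialisation is schema-stable and round-trips", {
  expect_equal(to_json(list()), "[]")
  res <- process_report("There is a small undisplaced vertical radial tear of the posterior horn of the lateral meniscus.", toy_cfg)
  js <- to_json(res$records)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(names(parsed[[1]]),
               c("finding", "finding_qualifiers", "negation", "certainty",
                 "anatomy", "anatomy_qualifiers"))
  expect_equal(names(parsed[[1]]$finding),
               c("text", "start", "offset", "id", "name"))
  expect_equal(parsed[[1]]$anatomy$id, "TRAK:0001089")
  expect_equal(parsed[[1]]$anatomy$name, "lateral meniscus")
  # round trip
  expect_equal(from_json(js), res$records)
  # wrapped form
  js2 <- to_json(res$records, report_id = "r1")
  expect_equal(from_json(js2), res$records)
})
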