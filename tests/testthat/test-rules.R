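run_rules <- function(doc, allow_or = TRUE) {
  tk <- tokenize(doc)
  m <- match_dictionary(tk, 1, nrow(tk), toy_dict, toy_cfg$match, doc)
  if (nrow(m)) m$uid <- seq_len(nrow(m))
  list(tokens = tk, before = m,
       after = apply_rules(tk, 1, nrow(tk), m, toy_ont, toy_dict, doc,
                           allow_or = allow_or))
}

test_that("coordination adds the combined sibling concept", {
  r <- run_rules("There is some signal in both the medial and lateral meniscus posteriorly.")
  added <- r$after[r$after$source == "rule:coordination", ]
  expect_equal(added$text, "medial")
  expect_equal(added$concept_id, "TRAK:0001090")

  r2 <- run_rules("The cruciate and collateral ligaments are intact.")
  added2 <- r2$after[r2$after$source == "rule:coordination", ]
  expect_equal(added2$concept_id, "TOY:0000013")

  r3 <- run_rules("The lateral meniscus is intact.")
  expect_equal(nrow(r3$after), nrow(r3$before))
})

test_that("coordination over 'or' is controlled by allow_or", {
  doc <- "There is signal in the medial or lateral meniscus."
  with_or <- run_rules(doc, allow_or = TRUE)
  without <- run_rules(doc, allow_or = FALSE)
  expect_true("TRAK:0001090" %in% with_or$after$concept_id)
  expect_false("TRAK:0001090" %in% without$after$concept_id)
})

test_that("enumeration expands stacked modifiers of a matched compound", {
  r <- run_rules("This possibly represents a tiny peripheral vertical longitudinal tear.")
  added <- r$after[r$after$source == "rule:enumeration", ]
  expect_setequal(added$concept_id, c("TRAK:0001388", "TRAK:0001389"))
  expect_setequal(added$text, c("vertical", "peripheral"))
  # satellites link back to the base compound mention
  base_uid <- r$after$uid[r$after$text == "longitudinal tear"]
  expect_true(all(added$base == base_uid))

  r2 <- run_rules("There is a small undisplaced vertical radial tear of the posterior horn.")
  added2 <- r2$after[r2$after$source == "rule:enumeration", ]
  expect_equal(added2$concept_id, "TRAK:0001388")  # small/undisplaced untouched

  r3 <- run_rules("There is a longitudinal tear.")
  expect_equal(nrow(r3$after), nrow(r3$before))
})

test_that("implicit anatomy is derived from finding morphology", {
  r <- run_rules("He has previously undergone medial meniscectomy.")
  added <- r$after[r$after$source == "rule:implicit_anatomy", ]
  expect_equal(added$concept_id, "TRAK:0001090")

  r2 <- run_rules("There is prepatellar bursitis.")
  expect_true("TRAK:0001054" %in% r2$after$concept_id)

  r3 <- run_rules("Appearances are consistent with patellar tendinitis.")
  expect_true("TRAK:0000053" %in% r3$after$concept_id)

  r4 <- run_rules("There is bursitis.")
  expect_false("TRAK:0001054" %in% r4$after$concept_id)
})

test_that("negation cues are detected with the no-further exception", {
  mark <- function(doc) {
    tk <- tokenize(doc)
    detect_negation(tk, 1, nrow(tk), doc)
  }
  expect_equal(mark("No bone marrow lesion identified.")$cue, "no")
  expect_equal(mark("It has not subluxed.")$cue, "not")
  expect_equal(mark("There is attenuation without a discrete tear.")$cue,
               "without")
  m <- mark("This represents residual vascularity rather than a tear.")
  expect_equal(m$cue, "rather than")
  expect_equal(m$text, "rather than")
  expect_equal(nrow(mark("There is no further cartilage defect.")), 0)
  # order: the cue span precedes the finding it will negate
  m2 <- mark("There is no discrete tear.")
  expect_lt(m2$start, regexpr("tear", "There is no discrete tear.") - 1)
})

test_that("the rule layer is additive and idempotent", {
  docs <- c(
    "There is signal in both the medial and lateral meniscus.",
    "This possibly represents a tiny peripheral vertical longitudinal tear.",
    "He has previously undergone medial meniscectomy.",
    "The cruciate and collateral ligaments are intact.")
  for (doc in docs) {
    r <- run_rules(doc)
    # additive: every original mention survives unchanged
    expect_true(nrow(r$after) >= nrow(r$before))
    expect_identical(r$after[seq_len(nrow(r$before)), names(r$before)],
                     r$before)
    # idempotent: a second application adds nothing
    again <- apply_rules(r$tokens, 1, nrow(r$tokens), r$after, toy_ont,
                         toy_dict, doc)
    expect_identical(again, r$after)
  }
})
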