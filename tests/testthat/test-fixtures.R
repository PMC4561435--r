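test_that("the toy ontology parses and contains the published identifiers", {
  ont <- toy_ont
  published <- c(
    "TRAK:0000031", "TRAK:0000045", "TRAK:0000046", "TRAK:0000049",
    "TRAK:0000051", "TRAK:0000053", "TRAK:0000077", "TRAK:0000091",
    "TRAK:0000092", "TRAK:0000133", "TRAK:0000204", "TRAK:0000211",
    "TRAK:0000222", "TRAK:0000225", "TRAK:0000229", "TRAK:0000236",
    "TRAK:0000323", "TRAK:0000362", "TRAK:0000513", "TRAK:0000656",
    "TRAK:0001027", "TRAK:0001037", "TRAK:0001054", "TRAK:0001089",
    "TRAK:0001090", "TRAK:0001322", "TRAK:0001337", "TRAK:0001345",
    "TRAK:0001346", "TRAK:0001388", "TRAK:0001389", "TRAK:0001390",
    "TRAK:0001396", "TRAK:0001410", "TRAK:0001411", "TRAK:0001422",
    "TRAK:0001441", "TRAK:0001447", "TRAK:0001456", "TRAK:0001461",
    "TRAK:0001467", "TRAK:0001468", "TRAK:0001478", "TRAK:0001482",
    "TRAK:0001485", "TRAK:0001488", "TRAK:0001495", "TRAK:0001502",
    "TRAK:0001511", "TRAK:0001529", "TRAK:0001531", "TRAK:0001561",
    "TRAK:0001581", "TRAK:0001598")
  expect_true(all(published %in% names(ont$concepts)))
  expect_gte(length(ont$concepts), 60)

  expect_equal(ont$concepts[["TRAK:0001090"]]$name, "medial meniscus")
  expect_equal(ont$concepts[["TRAK:0001090"]]$parents, "TRAK:0000045")
  expect_true("lateral femoral condyle" %in%
                ont$concepts[["TRAK:0001037"]]$synonyms)
  expect_equal(ont$concepts[["TRAK:0001037"]]$name,
               "lateral condyle of femur")
})

test_that("the worked-example corpus covers the documented constructions", {
  wx <- worked_examples()
  expect_gte(length(wx), 15)
  expect_true(all(vapply(wx, function(w) nzchar(w$text), logical(1))))
  # the negation quartet plus the exception are all present
  neg_cues <- unlist(lapply(wx, function(w) w$expect$negation_cues))
  expect_true(all(c("No", "not", "without", "rather than") %in% neg_cues))
  has_nofurther <- any(vapply(wx, function(w)
    grepl("no further", w$text) &&
      identical(w$expect$negation_cues, character()), logical(1)))
  expect_true(has_nofurther)
  # Table-style enumeration sentence with its anatomy id
  tab1 <- Filter(function(w) grepl("small undisplaced vertical radial", w$text),
                 wx)
  expect_length(tab1, 1)
  expect_equal(tab1[[1]]$expect$records[[1]]$anatomy_id, "TRAK:0001089")
})

test_that("generate_corpus is deterministic and honours n_reports", {
  expect_length(generate_corpus(corpus_config(n_reports = 0))$reports, 0)
  g1 <- generate_corpus(corpus_config(n_reports = 5, seed = 77))
  g2 <- generate_corpus(corpus_config(n_reports = 5, seed = 77))
  expect_identical(corpus_texts(g1), corpus_texts(g2))
  expect_identical(corpus_gold(g1), corpus_gold(g2))
  g3 <- generate_corpus(corpus_config(n_reports = 5, seed = 78))
  expect_false(identical(corpus_texts(g1), corpus_texts(g3)))
})

test_that("gold spans index into their report text", {
  gc <- generate_corpus(corpus_config(n_reports = 8, seed = 3))
  ids <- names(toy_ont$concepts)
  for (rep in gc$reports) {
    for (rec in rep$records) {
      fl <- c(list(rec$finding, rec$negation, rec$certainty, rec$anatomy),
              rec$finding_qualifiers, rec$anatomy_qualifiers)
      for (s in Filter(Negate(is.null), fl)) {
        expect_identical(substr(rep$text, s$start + 1, s$start + s$offset),
                         s$text)
        if (nzchar(s$id)) expect_true(s$id %in% ids)
      }
    }
  }
})

test_that("corpus statistics approach the configured report shape", {
  cfg <- corpus_config(n_reports = 120, seed = 19)
  gc <- generate_corpus(cfg)
  txts <- corpus_texts(gc)
  ns <- vapply(txts, function(t) nrow(split_sentences(tokenize(t))), 0L)
  nt <- vapply(txts, function(t) nrow(tokenize(t)), 0L)
  # sample means land within two standard errors of the configured targets
  expect_lt(abs(mean(ns) - cfg$mean_sentences),
            2 * cfg$sd_sentences / sqrt(length(ns)) + 0.5)
  expect_lt(abs(mean(nt) - cfg$mean_tokens),
            2 * cfg$sd_tokens / sqrt(length(nt)))
})

test_that("typos respect gold spans and the configured rate", {
  cfg <- corpus_config(n_reports = 60, seed = 31)
  gc <- generate_corpus(cfg)
  clean <- generate_corpus(corpus_config(n_reports = 60, seed = 31,
                                         typo_rate = 0))
  n_edits <- 0
  for (id in names(gc$reports)) {
    a <- gc$reports[[id]]$text
    b <- clean$reports[[id]]$text
    expect_equal(nchar(a), nchar(b))
    diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    n_edits <- n_edits + length(diff_pos)
    for (rec in gc$reports[[id]]$records) {
      fl <- Filter(Negate(is.null),
                   c(list(rec$finding, rec$negation, rec$certainty,
                          rec$anatomy),
                     rec$finding_qualifiers, rec$anatomy_qualifiers))
      for (s in fl) {
        expect_false(any(diff_pos > s$start & diff_pos <= s$start + s$offset))
      }
    }
  }
  # Poisson(0.83) per document over 60 documents
  expect_gt(n_edits, 10)
  expect_lt(n_edits, 120)
})

test_that("write_corpus emits report text and gold JSON files", {
  dir <- withr::local_tempdir()
  gc <- generate_corpus(corpus_config(n_reports = 2, seed = 4))
  write_corpus(gc, dir)
  expect_length(list.files(dir, pattern = "\\.txt$"), 2)
  gj <- list.files(dir, pattern = "gold\\.json$", full.names = TRUE)
  expect_length(gj, 2)
  back <- from_json(paste(readLines(gj[1], warn = FALSE), collapse = ""))
  expect_equal(back, gc$reports[[1]]$records)
})
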