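test_that("jaro_winkler matches the standard worked values", {
  for (s in c("a", "meniscus", "medial collateral ligament")) {
    expect_equal(jaro_winkler(s, s), 1.0)
  }
  # classic pair: Jaro 0.9444, three-character prefix boost
  expect_equal(jaro_winkler("MARTHA", "MARHTA"), 0.9611111, tolerance = 1e-6)
  expect_equal(jaro_winkler("DWAYNE", "DUANE"), 0.84, tolerance = 1e-6)
  expect_equal(jaro_winkler("abc", "xyz"), 0)
  expect_equal(jaro_winkler("", "abc"), 0)
})

test_that("soft_tfidf scores morphological variants above the threshold", {
  idf <- toy_dict$idf
  expect_equal(soft_tfidf(c("lateral", "meniscus"),
                          c("lateral", "meniscus"), idf), 1)
  expect_equal(soft_tfidf(c("qqq", "zzz"), c("lateral", "meniscus"), idf), 0)

  sc <- soft_tfidf(c("lateral", "menisci"), c("lateral", "meniscus"), idf,
                   default_idf = toy_dict$default_idf)
  expect_gte(sc, toy_cfg$match$threshold)
  # value equals the weighted pair composition computed by hand
  w <- function(toks) {
    v <- ifelse(toks %in% names(idf), idf[toks], toy_dict$default_idf)
    v / sqrt(sum(v^2))
  }
  wa <- w(c("lateral", "menisci")); wb <- w(c("lateral", "meniscus"))
  manual <- wa[1] * wb[1] * 1 +
    wa[2] * wb[2] * jaro_winkler("menisci", "meniscus")
  expect_equal(sc, unname(manual), tolerance = 1e-9)
})

test_that("one window token cannot consume two entry tokens (and vice versa)", {
  idf <- toy_dict$idf
  # "patella and the patellar" must not outscore against the entry "patella"
  sc <- soft_tfidf(c("patella", "and", "the", "patellar"), "patella", idf,
                   default_idf = toy_dict$default_idf)
  expect_lt(sc, 0.9)
})

test_that("match_dictionary splits composite expressions into components", {
  doc <- "HISTORY Twisting injury, ACL rupture and medial meniscal tear."
  tk <- tokenize(doc)
  m <- match_dictionary(tk, 1, nrow(tk), toy_dict, toy_cfg$match, doc)
  expect_true(any(m$text == "ACL" & m$concept_id == "TRAK:0000049"))
  expect_true(any(m$text == "rupture" & m$concept_id == "TRAK:0000211"))
  expect_false("TRAK:0000513" %in% m$concept_id)

  doc2 <- "qqx wwx eex rrx ttx"
  tk2 <- tokenize(doc2)
  expect_equal(nrow(match_dictionary(tk2, 1, nrow(tk2), toy_dict,
                                     toy_cfg$match, doc2)), 0)
})

test_that("dictionary surfaces appearing verbatim match with score 1", {
  surfaces <- c("lateral meniscus", "ACL", "posterior horn",
                "medial collateral ligament", "joint effusion")
  for (s in surfaces) {
    doc <- paste("Sentence mentioning the", s, "here.")
    tk <- tokenize(doc)
    m <- match_dictionary(tk, 1, nrow(tk), toy_dict, toy_cfg$match, doc)
    hit <- m[tolower(m$text) == tolower(s), ]
    expect_equal(nrow(hit), 1, info = s)
    expect_equal(hit$score, 1, info = s)
  }
})

test_that("returned mentions never overlap and respect the threshold", {
  docs <- c(
    "There is a small undisplaced vertical radial tear of the posterior horn of the lateral meniscus.",
    "There is bone bruising or subchondral marrow oedema at the inferior patella.",
    "The cruciate and collateral ligaments are intact.")
  for (doc in docs) {
    tk <- tokenize(doc)
    m <- match_dictionary(tk, 1, nrow(tk), toy_dict, toy_cfg$match, doc)
    if (nrow(m) > 1) {
      ends <- m$start + m$length
      expect_true(all(m$start[-1] >= ends[-nrow(m)]))
    }
    expect_true(all(m$score >= toy_cfg$match$threshold))
  }
})

test_that("raising the threshold never adds a mention", {
  doc <- "There is a tiny peripheral vertical longitudinal tear of the lateral menisci."
  tk <- tokenize(doc)
  lo <- match_dictionary(tk, 1, nrow(tk), toy_dict,
                         match_config(threshold = 0.85), doc)
  hi <- match_dictionary(tk, 1, nrow(tk), toy_dict,
                         match_config(threshold = 0.97), doc)
  key <- function(m) paste(m$start, m$length, m$concept_id)
  expect_true(all(key(hi) %in% key(lo)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("longest-match output equals brute-force window enumeration", {
  set.seed(1234)
  vocab <- unique(c(names(toy_dict$idf),
                    "there", "is", "the", "of", "at", "noted", "query",
                    "mild", "signal", "region", "zone"))
  for (rep in seq_len(20)) {
    words <- sample(vocab, 8, replace = TRUE)
    doc <- paste(paste(words, collapse = " "), ".")
    tk <- tokenize(doc)
    got <- match_dictionary(tk, 1, nrow(tk), toy_dict, toy_cfg$match, doc)
    want <- oracle_match(tk, toy_dict, toy_cfg$match)
    expect_equal(got$start, want$start, info = doc)
    expect_equal(got$length, want$length, info = doc)
    expect_equal(got$concept_id, want$concept_id, info = doc)
    expect_equal(got$score, want$score, tolerance = 1e-9, info = doc)
  }
})
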