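mk_filler <- function(id, text = id, start = 0) {
  list(text = text, start = as.integer(start), offset = nchar(text),
       id = id, name = text)
}
mk_record <- function(finding, anatomy = NULL, fq = character(),
                      neg = FALSE, start = 0) {
  r <- list(finding = mk_filler(finding, start = start),
            finding_qualifiers = lapply(fq, mk_filler),
            negation = if (neg) mk_filler("", "no") else NULL,
            certainty = NULL,
            anatomy = if (!is.null(anatomy)) mk_filler(anatomy) else NULL,
            anatomy_qualifiers = list())
  r
}

test_that("record comparison counts slot-level agreement", {
  gold <- list(r1 = list(mk_record("F:1", "A:1", fq = c("Q:1", "Q:2")),
                         mk_record("F:2", "A:2", neg = TRUE)))
  # perfect prediction
  m <- compare_records(gold, gold)
  expect_equal(sum(m[, "FP"]), 0)
  expect_equal(sum(m[, "FN"]), 0)
  expect_equal(unname(m["record", "TP"]), 2)

  # wrong anatomy on one record: one FP and one FN in the anatomy slot
  pred <- list(r1 = list(mk_record("F:1", "A:9", fq = c("Q:1", "Q:2")),
                         mk_record("F:2", "A:2", neg = TRUE)))
  m2 <- compare_records(pred, gold)
  expect_equal(unname(m2["anatomy", ]), c(1L, 1L, 1L))
  expect_equal(unname(m2["record", ]), c(1L, 1L, 1L))

  # missing record entirely: every filled gold slot becomes a FN
  pred3 <- list(r1 = list(mk_record("F:1", "A:1", fq = c("Q:1", "Q:2"))))
  m3 <- compare_records(pred3, gold)
  expect_equal(unname(m3["finding", "FN"]), 1L)
  expect_equal(unname(m3["anatomy", "FN"]), 1L)
  expect_equal(unname(m3["negation", "FN"]), 1L)

  expect_error(compare_records(pred, list(r2 = gold$r1)), "ids differ")
})

test_that("prf reproduces the published per-slot arithmetic", {
  rows <- list(
    finding = c(1251, 5, 3, 99.60, 99.76, 99.68),
    finding_qualifier = c(636, 19, 15, 97.10, 97.70, 97.40),
    negation = c(91, 1, 4, 98.91, 95.79, 97.33),
    certainty = c(232, 8, 2, 96.67, 99.15, 97.89),
    anatomy = c(1313, 30, 38, 97.77, 97.19, 97.48),
    anatomy_qualifier = c(439, 18, 34, 96.06, 92.81, 94.41),
    overall = c(3962, 81, 96, 98.00, 97.63, 97.81))
  for (nm in names(rows)) {
    v <- rows[[nm]]
    m <- prf(v[1], v[2], v[3])
    expect_equal(m$precision_pct, v[4], info = nm)
    expect_equal(m$recall_pct, v[5], info = nm)
    expect_equal(m$f_pct, v[6], info = nm)
  }
  # the overall row is the sum of the slot rows
  slot_rows <- rows[names(rows) != "overall"]
  expect_equal(Reduce(`+`, lapply(slot_rows, function(v) v[1:3])),
               rows$overall[1:3])
})

test_that("undefined metrics are reported as not applicable, not zero", {
  m <- prf(0, 0, 5)
  expect_true(is.na(m$precision))
  expect_equal(m$recall, 0)
  expect_true(is.na(m$f_pct))
  m2 <- prf(0, 0, 0)
  expect_true(is.na(m2$precision) && is.na(m2$recall))
})

test_that("F collapses to P and R when FP equals FN", {
  for (case in list(c(10, 3, 3), c(7, 0, 0), c(100, 25, 25))) {
    m <- prf(case[1], case[2], case[3])
    expect_equal(m$precision, m$recall)
    expect_equal(m$f, m$precision)
  }
})

test_that("kappa follows the chance-corrected agreement formula", {
  expect_equal(kappa(1, 0.3), 1)
  expect_equal(kappa(1, 0.99), 1)
  expect_equal(kappa(0.5, 0.5), 0)
  expect_equal(kappa(0.87, 0.26), (0.87 - 0.26) / (1 - 0.26))
  expect_equal(kappa(0.87, 0.26), 0.8243243, tolerance = 1e-6)
  expect_error(kappa(0.9, 1), "undefined")
})

test_that("observed and expected agreement come from the marginals", {
  A <- c(i1 = "x", i2 = "x", i3 = "y", i4 = "y")
  B <- c(i1 = "x", i2 = "x", i3 = "y", i4 = "x")
  ag <- agreement_from_annotations(A, B)
  expect_equal(ag$Ao, 0.75)
  expect_equal(ag$Ae, 0.5)  # 0.5*0.75 + 0.5*0.25
  expect_equal(ag$kappa, 0.5)

  # identical annotations
  expect_equal(agreement_from_annotations(A, A)$Ao, 1)
  # disjoint category use
  C <- c(i1 = "z", i2 = "z", i3 = "z", i4 = "z")
  expect_equal(agreement_from_annotations(A, C)$Ao, 0)
  expect_error(agreement_from_annotations(A, B[1:3]), "same named items")
})

test_that("kappa is invariant under category relabelling", {
  A <- c(i1 = "x", i2 = "x", i3 = "y", i4 = "z", i5 = "y")
  B <- c(i1 = "x", i2 = "y", i3 = "y", i4 = "z", i5 = "z")
  relab <- c(x = "cat1", y = "cat2", z = "cat3")
  k1 <- agreement_from_annotations(A, B)$kappa
  k2 <- agreement_from_annotations(
    stats::setNames(relab[A], names(A)),
    stats::setNames(relab[B], names(B)))$kappa
  expect_equal(k1, k2)
})

test_that("metrics_table aggregates per-slot counts into the overall row", {
  gold <- list(r1 = list(mk_record("F:1", "A:1", fq = "Q:1"),
                         mk_record("F:2", "A:2")))
  pred <- list(r1 = list(mk_record("F:1", "A:1", fq = "Q:1")))
  tb <- metrics_table(compare_records(pred, gold))
  ov <- tb[tb$slot == "overall", ]
  slots <- tb[!(tb$slot %in% c("overall", "record")), ]
  expect_equal(ov$TP, sum(slots$TP))
  expect_equal(ov$FP, sum(slots$FP))
  expect_equal(ov$FN, sum(slots$FN))
})
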