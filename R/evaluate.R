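.SLOTS <- c("finding", "finding_qualifier", "negation", "certainty",
            "anatomy", "anatomy_qualifier")

.slot_keys <- function(rec, slot) {
  # comparison is at the conceptual level: concept ids (negation: cue text)
  switch(slot,
         finding = if (is.null(rec$finding)) character() else rec$finding$id,
         finding_qualifier = vapply(rec$finding_qualifiers, `[[`, "", "id"),
         negation = if (is.null(rec$negation)) character() else
           tolower(rec$negation$text),
         certainty = if (is.null(rec$certainty)) character() else
           rec$certainty$id,
         anatomy = if (is.null(rec$anatomy)) character() else rec$anatomy$id,
         anatomy_qualifier = vapply(rec$anatomy_qualifiers, `[[`, "", "id"))
}

.empty_counts <- function() {
  m <- matrix(0L, nrow = length(.SLOTS) + 1L, ncol = 3,
              dimnames = list(c(.SLOTS, "record"), c("TP", "FP", "FN")))
  m
}

# align two record lists of one report: greedy on finding concept id,
# nearest finding span first
.align_records <- function(pred, gold) {
  pairs <- list()
  used_p <- logical(length(pred))
  gid <- vapply(gold, function(r) if (is.null(r$finding)) "" else r$finding$id, "")
  pid <- vapply(pred, function(r) if (is.null(r$finding)) "" else r$finding$id, "")
  gst <- vapply(gold, function(r) if (is.null(r$finding)) -1L else r$finding$start, 0L)
  pst <- vapply(pred, function(r) if (is.null(r$finding)) -1L else r$finding$start, 0L)
  for (g in seq_along(gold)) {
    cand <- which(!used_p & pid == gid[g])
    if (!length(cand)) next
    p <- cand[which.min(abs(pst[cand] - gst[g]))]
    used_p[p] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(g, p)
  }
  list(pairs = pairs, unpaired_pred = which(!used_p),
       unpaired_gold = setdiff(seq_along(gold),
                               vapply(pairs, `[[`, 0L, 1L)))
}

.count_multiset <- function(a, b) {
  # returns c(tp, fp, fn) comparing predicted multiset a vs gold multiset b
  tp <- 0L
  b_left <- b
  for (x in a) {
    hit <- match(x, b_left)
    if (!is.na(hit)) { tp <- tp + 1L; b_left <- b_left[-hit] }
  }
  c(tp, length(a) - tp, length(b) - tp)
}

#' Compare predicted templates with gold templates
#'
#' Slot fillers are matched at the conceptual level (concept ids; cue text
#' for negation) after aligning records by finding concept and nearest span.
#' Vertical counts are per slot; the horizontal `record` row counts whole
#' records in which every slot matches.
#'
#' @param predicted,gold Named lists: report id -> list of records. Names
#'   must be unique and agree.
#' @return Object of class `confusion_counts`: integer matrix with rows per
#'   slot plus `record`, columns TP/FP/FN, and an `overall` attribute giving
#'   the per-slot sums.
#' @export
compare_records <- function(predicted, gold) {
  if (anyDuplicated(names(predicted)) || anyDuplicated(names(gold))) {
    stop("duplicate report ids")
  }
  if (!setequal(names(predicted), names(gold))) {
    stop("predicted and gold report ids differ")
  }
  m <- .empty_counts()
  for (rid in names(gold)) {
    al <- .align_records(predicted[[rid]], gold[[rid]])
    for (pr in al$pairs) {
      g <- gold[[rid]][[pr[1]]]; p <- predicted[[rid]][[pr[2]]]
      all_ok <- TRUE
      for (slot in .SLOTS) {
        cmp <- .count_multiset(.slot_keys(p, slot), .slot_keys(g, slot))
        m[slot, ] <- m[slot, ] + cmp
        if (cmp[2] > 0 || cmp[3] > 0) all_ok <- FALSE
      }
      m["record", ] <- m["record", ] +
        if (all_ok) c(1L, 0L, 0L) else c(0L, 1L, 1L)
    }
    for (p in al$unpaired_pred) {
      rec <- predicted[[rid]][[p]]
      for (slot in .SLOTS) {
        m[slot, "FP"] <- m[slot, "FP"] + length(.slot_keys(rec, slot))
      }
      m["record", "FP"] <- m["record", "FP"] + 1L
    }
    for (g in al$unpaired_gold) {
      rec <- gold[[rid]][[g]]
      for (slot in .SLOTS) {
        m[slot, "FN"] <- m[slot, "FN"] + length(.slot_keys(rec, slot))
      }
      m["record", "FN"] <- m["record", "FN"] + 1L
    }
  }
  structure(m, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Round half up
#' @param x Numeric. @param digits Decimal places.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Precision, recall and F-measure from confusion counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F = 2PR/(P+R). Percentages are rounded
#' half-up to two decimals; the reported F is computed from the rounded
#' percentages (matching how such tables are conventionally printed), while
#' `precision`/`recall`/`f` keep full precision. A metric whose denominator
#' is zero is not applicable and reported as `NA`.
#'
#' @param tp,fp,fn Non-negative counts; alternatively pass a single-row slice
#'   of a `confusion_counts` object as `tp`.
#' @return List of class `prf_metrics`: `precision`, `recall`, `f` (raw
#'   proportions) and `precision_pct`, `recall_pct`, `f_pct`.
#' @export
prf <- function(tp, fp = NULL, fn = NULL) {
  if (is.null(fp) && length(tp) == 3) { fn <- tp[[3]]; fp <- tp[[2]]; tp <- tp[[1]] }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
  p_pct <- round_half_up(100 * p)
  r_pct <- round_half_up(100 * r)
  f_pct <- if (!is.na(p_pct) && !is.na(r_pct) && p_pct + r_pct > 0) {
    round_half_up(2 * p_pct * r_pct / (p_pct + r_pct))
  } else NA_real_
  structure(list(precision = p, recall = r, f = f,
                 precision_pct = p_pct, recall_pct = r_pct, f_pct = f_pct),
            class = "prf_metrics")
}

#' @export
print.prf_metrics <- function(x, ...) {
  cat(sprintf("P = %.2f %%  R = %.2f %%  F = %.2f %%\n",
              x$precision_pct, x$recall_pct, x$f_pct))
  invisible(x)
}

#' Metrics table from confusion counts
#' @param counts A `confusion_counts`.
#' @return data.frame with one row per slot plus `overall` (per-slot sums)
#'   and `record` (horizontal evaluation).
#' @export
metrics_table <- function(counts) {
  rows <- c(.SLOTS, "overall", "record")
  out <- data.frame(slot = rows, TP = 0L, FP = 0L, FN = 0L,
                    P = NA_real_, R = NA_real_, F = NA_real_,
                    stringsAsFactors = FALSE)
  total <- colSums(counts[.SLOTS, , drop = FALSE])
  for (i in seq_along(rows)) {
    cnt <- if (rows[i] == "overall") total else counts[rows[i], ]
    m <- prf(cnt[[1]], cnt[[2]], cnt[[3]])
    out[i, 2:4] <- as.list(as.integer(cnt))
    out[i, 5:7] <- list(m$precision_pct, m$recall_pct, m$f_pct)
  }
  out
}

#' Chance-corrected inter-annotator agreement
#'
#' k = (Ao - Ae) / (1 - Ae), on a -1..1 scale: 1 perfect agreement, 0 chance
#' agreement, negative values systematic disagreement.
#'
#' @param Ao Observed agreement in [0, 1].
#' @param Ae Expected chance agreement in [0, 1); `Ae = 1` is undefined.
#' @export
kappa <- function(Ao, Ae) {
  stopifnot(Ao >= 0, Ao <= 1, Ae >= 0)
  if (Ae >= 1) stop("kappa undefined for Ae = 1")
  (Ao - Ae) / (1 - Ae)
}

#' Observed and expected agreement of two annotators
#'
#' Ao is the proportion of items on which the annotators agree. Ae assumes
#' both assign categories independently at random following their own
#' marginal category distributions (include a missing-annotation category
#' for items one annotator skipped).
#'
#' @param A,B Named vectors item -> category; must cover the same items.
#' @param categories Optional category universe (defaults to the union).
#' @return List with `Ao`, `Ae` and `kappa`.
#' @export
agreement_from_annotations <- function(A, B, categories = NULL) {
  if (!setequal(names(A), names(B)) || is.null(names(A))) {
    stop("annotators must cover the same named items")
  }
  B <- B[names(A)]
  if (is.null(categories)) categories <- sort(unique(c(A, B)))
  Ao <- mean(A == B)
  pa <- table(factor(A, levels = categories)) / length(A)
  pb <- table(factor(B, levels = categories)) / length(B)
  Ae <- sum(as.numeric(pa) * as.numeric(pb))
  list(Ao = Ao, Ae = Ae, kappa = kappa(Ao, Ae))
}

#' Concept-ablation experiment
#'
#' Shuffles `removable_ids` once (deterministically for a seed), then for
#' each k removes the first k concepts from the matcher dictionary, reruns
#' the extraction pipeline on the corpus and scores it against the fixed
#' gold standard.
#'
#' @param cfg A [pipeline_config()]; its ontology/overrides are reused, with
#'   the ablated concepts appended to the ignore list.
#' @param removable_ids Concept ids eligible for removal.
#' @param k_values Ablation sizes, e.g. `c(0, 10, 20, ...)`.
#' @param seed Integer seed for the shuffle.
#' @param corpus Named character vector / list: report id -> report text.
#' @param gold Named list: report id -> gold records.
#' @return data.frame with `k`, `P`, `R`, `F` (overall vertical metrics, %).
#' @export
run_ablation <- function(cfg, removable_ids, k_values, seed, corpus, gold) {
  set.seed(seed)
  order_ids <- sample(removable_ids)
  out <- data.frame(k = integer(), P = numeric(), R = numeric(),
                    F = numeric())
  for (k in k_values) {
    stopifnot(k <= length(order_ids))
    cfg_k <- cfg
    if (k > 0) {
      gone <- order_ids[seq_len(k)]
      ov <- cfg$overrides
      ov$ignored_concepts <- unique(c(ov$ignored_concepts, gone))
      ov$remaps <- ov$remaps[!(ov$remaps$to %in% gone), , drop = FALSE]
      ov$added_entries <-
        ov$added_entries[!(ov$added_entries$id %in% gone), , drop = FALSE]
      cfg_k$overrides <- ov
      cfg_k$dict <- compile_dictionary(cfg$ontology, ov)
    }
    pred <- lapply(corpus, function(txt) process_report(txt, cfg_k)$records)
    names(pred) <- names(corpus)
    counts <- compare_records(pred, gold)
    total <- colSums(counts[.SLOTS, , drop = FALSE])
    m <- prf(total[[1]], total[[2]], total[[3]])
    out[nrow(out) + 1L, ] <- list(as.integer(k), m$precision_pct,
                                  m$recall_pct, m$f_pct)
  }
  out
}
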