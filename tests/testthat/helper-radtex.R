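# Shared fixtures: built once per test run.

toy_cfg <- toy_pipeline_config()
toy_ont <- toy_cfg$ontology
toy_dict <- toy_cfg$dict

# A small hand-written ontology used where the toy fixture is too large.
mini_obo <- "
[Term]
id: X:1
name: root

[Term]
id: X:2
name: middle node
is_a: X:1

[Term]
id: X:3
name: leaf node
synonym: \"leafy\" EXACT []
is_a: X:2
"

# Independent longest-match oracle: enumerate every window of word tokens
# (never crossing punctuation, up to max_window), score it against EVERY
# dictionary entry with soft_tfidf, keep windows at or above the threshold
# and resolve overlaps longest-first (ties: leftmost, then highest score);
# same-span concept ties prefer official entries, then the smaller id.
oracle_match <- function(tokens, dict, cfg) {
  n <- nrow(tokens)
  word <- which(!tokens$is_punct)
  runs <- split(word, cumsum(c(1, diff(word) != 1)))
  cands <- list()
  for (run in runs) {
    for (i in seq_along(run)) {
      for (L in seq_len(min(cfg$max_window, length(run) - i + 1))) {
        span <- run[i:(i + L - 1)]
        wtoks <- tolower(tokens$text[span])
        best <- 0; best_entries <- integer()
        for (e in seq_len(nrow(dict$entries))) {
          s <- soft_tfidf(wtoks, dict$tokens[[e]], dict$idf,
                          theta = cfg$theta, prefix_scale = cfg$prefix_scale,
                          default_idf = dict$default_idf)
          if (s > best + 1e-12) { best <- s; best_entries <- e }
          else if (abs(s - best) <= 1e-12) best_entries <- c(best_entries, e)
        }
        if (best >= cfg$threshold) {
          off <- dict$entries$official[best_entries]
          if (any(off)) best_entries <- best_entries[off]
          pick <- best_entries[order(dict$entries$concept_id[best_entries])][1]
          cands[[length(cands) + 1]] <- list(
            tf = span[1], tt = span[L], L = L, score = best,
            concept = dict$entries$concept_id[pick])
        }
      }
    }
  }
  if (!length(cands)) {
    return(data.frame(start = integer(), length = integer(),
                      concept_id = character(), score = numeric()))
  }
  ord <- order(-vapply(cands, `[[`, 0, "L"),
               vapply(cands, `[[`, 0, "tf"),
               -vapply(cands, `[[`, 0, "score"))
  taken <- rep(FALSE, n)
  out <- data.frame(start = integer(), length = integer(),
                    concept_id = character(), score = numeric())
  for (k in ord) {
    c_ <- cands[[k]]
    span <- c_$tf:c_$tt
    if (any(taken[span])) next
    taken[span] <- TRUE
    st <- tokens$start[c_$tf]
    en <- tokens$start[c_$tt] + tokens$length[c_$tt]
    out[nrow(out) + 1, ] <- list(st, en - st, c_$concept, c_$score)
  }
  out[order(out$start), ]
}

# does some extracted record satisfy the partial spec?
record_matching <- function(records, spec) {
  for (r in records) {
    ok <- TRUE
    if (!is.null(spec$finding_id)) {
      ok <- !is.null(r$finding) && r$finding$id == spec$finding_id
    }
    if (ok && !is.null(spec$negated)) {
      ok <- identical(spec$negated, !is.null(r$negation))
    }
    if (ok && !is.null(spec$anatomy_id)) {
      ok <- !is.null(r$anatomy) && r$anatomy$id == spec$anatomy_id
    }
    if (ok && !is.null(spec$anatomy_text)) {
      ok <- !is.null(r$anatomy) && r$anatomy$text == spec$anatomy_text
    }
    if (ok && !is.null(spec$certainty_id)) {
      ok <- !is.null(r$certainty) && r$certainty$id == spec$certainty_id
    }
    if (ok && !is.null(spec$fq_ids)) {
      got <- vapply(r$finding_qualifiers, `[[`, "", "id")
      ok <- setequal(got, spec$fq_ids) && length(got) == length(spec$fq_ids)
    }
    if (ok && !is.null(spec$aq_ids)) {
      ok <- setequal(vapply(r$anatomy_qualifiers, `[[`, "", "id"),
                     spec$aq_ids)
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# check one worked-example case end to end; returns character() when clean
check_worked_example <- function(case, cfg = toy_cfg) {
  res <- process_report(case$text, cfg)
  ex <- case$expect
  probs <- character()
  if (!is.null(ex$mentions_include)) {
    for (i in seq_len(nrow(ex$mentions_include))) {
      hit <- any(res$mentions$text == ex$mentions_include$text[i] &
                   res$mentions$concept_id == ex$mentions_include$concept_id[i])
      if (!hit) {
        probs <- c(probs, sprintf("missing mention %s -> %s",
                                  ex$mentions_include$text[i],
                                  ex$mentions_include$concept_id[i]))
      }
    }
  }
  if (!is.null(ex$mentions_absent) &&
      any(ex$mentions_absent %in% res$mentions$concept_id)) {
    probs <- c(probs, "pruned/ignored concept still present")
  }
  if (!is.null(ex$negation_cues) &&
      !identical(sort(res$negations$text), sort(ex$negation_cues))) {
    probs <- c(probs, sprintf("negation cues [%s]",
                              paste(res$negations$text, collapse = ",")))
  }
  if (!is.null(ex$n_segments) && nrow(res$segments) != ex$n_segments) {
    probs <- c(probs, sprintf("%d segments, expected %d",
                              nrow(res$segments), ex$n_segments))
  }
  if (!is.null(ex$records)) {
    for (er in ex$records) {
      if (!record_matching(res$records, er)) {
        probs <- c(probs, sprintf("no record matching finding %s",
                                  er$finding_id))
      }
    }
  }
  probs
}

mention_df <- function(res) res$mentions
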