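#' Jaro-Winkler similarity
#'
#' Standard Jaro similarity (matches within half the longer string, half the
#' out-of-order matches counted as transpositions) with the Winkler boost for
#' a shared prefix of up to four characters.
#'
#' @param a,b Strings (compared as given; callers fold case).
#' @param prefix_scale Winkler prefix weight, conventionally 0.1.
#' @return Similarity in [0, 1].
#' @export
jaro_winkler <- function(a, b, prefix_scale = 0.1) {
  if (identical(a, b)) return(1)
  s1 <- utf8ToInt(a); s2 <- utf8ToInt(b)
  n1 <- length(s1); n2 <- length(s2)
  if (!n1 || !n2) return(0)
  window <- max(floor(max(n1, n2) / 2) - 1, 0)
  used2 <- logical(n2)
  match1 <- integer(0)
  match2pos <- integer(0)
  for (i in seq_len(n1)) {
    lo <- max(1L, i - window); hi <- min(n2, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!used2[j] && s2[j] == s1[i]) {
        used2[j] <- TRUE
        match1 <- c(match1, s1[i])
        match2pos <- c(match2pos, j)
        break
      }
    }
  }
  m <- length(match1)
  if (!m) return(0)
  t <- sum(match1 != s2[sort(match2pos)]) / 2
  jaro <- (m / n1 + m / n2 + (m - t) / m) / 3
  l <- 0L
  for (k in seq_len(min(4L, n1, n2))) {
    if (s1[k] == s2[k]) l <- k else break
  }
  jaro + l * prefix_scale * (1 - jaro)
}

#' Soft TF-IDF phrase similarity
#'
#' Cosine-style TF-IDF similarity between two token sequences, restricted to
#' token pairs whose Jaro-Winkler similarity reaches `theta`; each retained
#' pair's contribution is weighted by that similarity. Pairing is one-to-one
#' (greedy, most similar pairs first), so two window tokens can never both
#' consume the same entry token — without this, a window like "patella and
#' the patellar" outscores the true compound "patellar tendon" against the
#' single-token entry "patella". Token weights are `(1 + log(tf)) * idf`,
#' L2-normalised per phrase. Tokens absent from the idf table receive
#' `default_idf`.
#'
#' @param phrase_tokens,entry_tokens Character vectors of (lower-cased)
#'   tokens.
#' @param idf Named numeric vector of inverse document frequencies.
#' @param theta Internal pairing threshold on Jaro-Winkler similarity.
#' @param prefix_scale Winkler prefix weight.
#' @param default_idf Weight for unseen tokens (defaults to `max(idf)`).
#' @return Similarity in [0, 1] (1 for identical token sequences).
#' @export
soft_tfidf <- function(phrase_tokens, entry_tokens, idf, theta = 0.9,
                       prefix_scale = 0.1, default_idf = NULL) {
  if (!length(phrase_tokens) || !length(entry_tokens)) return(0)
  if (identical(unname(phrase_tokens), unname(entry_tokens))) return(1)
  if (is.null(default_idf)) {
    default_idf <- if (length(idf)) max(idf) else 1
  }
  wa <- .tfidf_weights(phrase_tokens, idf, default_idf)
  wb <- .tfidf_weights(entry_tokens, idf, default_idf)
  pairs <- list()
  for (ta in names(wa)) {
    for (tb in names(wb)) {
      s <- jaro_winkler(ta, tb, prefix_scale)
      if (s >= theta) pairs[[length(pairs) + 1L]] <- list(ta, tb, s)
    }
  }
  if (!length(pairs)) return(0)
  sims <- vapply(pairs, `[[`, 0, 3L)
  used_a <- character(); used_b <- character()
  score <- 0
  for (k in order(-sims)) {
    ta <- pairs[[k]][[1]]; tb <- pairs[[k]][[2]]
    if (ta %in% used_a || tb %in% used_b) next
    used_a <- c(used_a, ta); used_b <- c(used_b, tb)
    score <- score + wa[[ta]] * wb[[tb]] * pairs[[k]][[3]]
  }
  min(score, 1)
}

.tfidf_weights <- function(tokens, idf, default_idf) {
  if (!anyDuplicated(tokens)) {
    w <- idf[tokens]
    w[is.na(w)] <- default_idf
    names(w) <- tokens
  } else {
    tf <- table(tokens)
    w <- (1 + log(as.numeric(tf))) *
      ifelse(names(tf) %in% names(idf), idf[names(tf)], default_idf)
    names(w) <- names(tf)
  }
  w <- pmax(w, 1e-9)  # guard: a token occurring in every entry has idf 0
  w / sqrt(sum(w^2))
}

#' Matching configuration
#'
#' @param threshold Minimum SoftTFIDF score for a dictionary mention.
#' @param theta Internal Jaro-Winkler pairing threshold.
#' @param prefix_scale Winkler prefix weight.
#' @param max_window Longest candidate window in tokens.
#' @export
match_config <- function(threshold = 0.9, theta = 0.9, prefix_scale = 0.1,
                         max_window = 6L) {
  stopifnot(threshold > 0, threshold <= 1, theta > 0, theta <= 1,
            prefix_scale > 0, prefix_scale <= 1, max_window >= 1)
  structure(list(threshold = threshold, theta = theta,
                 prefix_scale = prefix_scale,
                 max_window = as.integer(max_window)),
            class = "match_config")
}

# entry tokens whose Jaro-Winkler similarity to `tok` reaches theta;
# memoised on the dictionary so repeated corpus tokens are cheap
.close_entry_tokens <- function(tok, dict, cfg) {
  key <- paste0(cfg$theta, "|", tok)
  hit <- dict$close_cache[[key]]
  if (!is.null(hit)) return(hit)
  all_tok <- names(dict$idf)
  keep <- vapply(all_tok, function(tb)
    jaro_winkler(tok, tb, cfg$prefix_scale) >= cfg$theta, logical(1))
  res <- all_tok[keep]
  dict$close_cache[[key]] <- res
  res
}

# candidate entry indices that could pair at least one token with the window
.candidate_entries <- function(win_tokens, dict, cfg) {
  idx <- integer(0)
  for (tok in unique(win_tokens)) {
    for (etok in .close_entry_tokens(tok, dict, cfg)) {
      idx <- c(idx, dict$token_index[[etok]])
    }
  }
  sort(unique(idx))
}

# best entry for a token window: list(score, entry_idx) or NULL.
# .candidate_entries is a complete prefilter: an entry with no token pair at
# JW >= theta scores exactly 0, so skipping it never changes the result.
# Results are memoised per window string (windows repeat heavily across a
# corpus); the cache key carries the thresholds so configs cannot collide.
.score_window <- function(win_tokens, dict, cfg) {
  cache <- dict$score_cache
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(cfg$threshold, cfg$theta, cfg$prefix_scale,
                 paste(win_tokens, collapse = " "), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) {
      return(if (identical(hit, "none")) NULL else hit)
    }
  }
  res <- .score_window_raw(win_tokens, dict, cfg)
  if (!is.null(cache)) cache[[key]] <- if (is.null(res)) "none" else res
  res
}

.score_window_raw <- function(win_tokens, dict, cfg) {
  cand <- .candidate_entries(win_tokens, dict, cfg)
  if (!length(cand)) return(NULL)
  best <- 0; best_i <- integer(0)
  for (i in cand) {
    s <- soft_tfidf(win_tokens, dict$tokens[[i]], dict$idf,
                    theta = cfg$theta, prefix_scale = cfg$prefix_scale,
                    default_idf = dict$default_idf)
    if (s > best + 1e-12) { best <- s; best_i <- i }
    else if (abs(s - best) <= 1e-12) best_i <- c(best_i, i)
  }
  if (best < cfg$threshold) return(NULL)
  list(score = best, entry = .break_tie(dict, best_i))
}

# equal-score tie on one span: prefer official entries, then smaller id
.break_tie <- function(dict, idx) {
  if (length(idx) == 1) return(idx)
  off <- dict$entries$official[idx]
  if (any(off)) idx <- idx[off]
  idx[order(dict$entries$concept_id[idx], method = "radix")][1]
}

.empty_mentions <- function() {
  data.frame(text = character(), start = integer(), length = integer(),
             concept_id = character(), score = numeric(), source = character(),
             tok_from = integer(), tok_to = integer(),
             base = integer(), uid = integer(), stringsAsFactors = FALSE)
}

#' Soft dictionary lookup over a sentence
#'
#' Enumerates candidate token windows (contiguous word tokens, never crossing
#' punctuation, up to `cfg$max_window` tokens), scores each against the
#' dictionary with SoftTFIDF, and keeps windows reaching `cfg$threshold`.
#' Overlaps are resolved longest-match-first (ties: leftmost, then highest
#' score), so returned mentions are mutually non-overlapping. Case is folded
#' for scoring; `text` preserves the original document casing.
#'
#' @param tokens Token data.frame of the whole document (from [tokenize()]).
#' @param from,to Token index range (inclusive) forming the sentence.
#' @param dict A `matcher_dictionary`.
#' @param cfg A [match_config()].
#' @param doc_text The original document string.
#' @return Mention data.frame: `text`, `start`, `length` (0-based character
#'   span), `concept_id`, `score`, `source` (`"dictionary"`), plus token
#'   bookkeeping columns `tok_from`, `tok_to`, `base`.
#' @export
match_dictionary <- function(tokens, from, to, dict, cfg = match_config(),
                             doc_text = NULL) {
  out <- .empty_mentions()
  if (to < from) return(out)
  idxs <- from:to
  word <- idxs[!tokens$is_punct[idxs]]
  if (!length(word)) return(out)
  # contiguous word runs (no punctuation inside a window)
  runs <- split(word, cumsum(c(1, diff(word) != 1)))
  cands <- list()
  for (run in runs) {
    nr <- length(run)
    for (i in seq_len(nr)) {
      for (L in seq_len(min(cfg$max_window, nr - i + 1L))) {
        wtoks <- tolower(tokens$text[run[i:(i + L - 1L)]])
        hit <- .score_window(wtoks, dict, cfg)
        if (!is.null(hit)) {
          cands[[length(cands) + 1L]] <-
            list(tf = run[i], tt = run[i + L - 1L], L = L,
                 score = hit$score, entry = hit$entry)
        }
      }
    }
  }
  if (!length(cands)) return(out)
  Ls <- vapply(cands, `[[`, 0, "L")
  tfs <- vapply(cands, `[[`, 0, "tf")
  scs <- vapply(cands, `[[`, 0, "score")
  ord <- order(-Ls, tfs, -scs)
  taken <- rep(FALSE, nrow(tokens))
  for (k in ord) {
    c_ <- cands[[k]]
    span <- c_$tf:c_$tt
    if (any(taken[span])) next
    taken[span] <- TRUE
    st <- tokens$start[c_$tf]
    en <- tokens$start[c_$tt] + tokens$length[c_$tt]
    txt <- if (is.null(doc_text)) {
      paste(tokens$text[span[!tokens$is_punct[span]]], collapse = " ")
    } else substr(doc_text, st + 1, en)
    out[nrow(out) + 1L, ] <- list(
      txt, st, en - st, dict$entries$concept_id[c_$entry], c_$score,
      "dictionary", c_$tf, c_$tt, NA_integer_, NA_integer_)
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
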