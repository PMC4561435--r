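#' Default clause-boundary lexical clues
#'
#' Discourse connectives that open a new statement about a finding. Multiword
#' clues are matched as token sequences.
#' @export
default_clue_words <- function() {
  c("but", "which", "consistent with", "although", "though", "suggesting",
    "in keeping with")
}

.tok_in_mention <- function(idx, mentions) {
  if (!nrow(mentions)) return(rep(FALSE, length(idx)))
  vapply(idx, function(i) any(mentions$tok_from <= i & mentions$tok_to >= i),
         logical(1))
}

#' Split one sentence into clause-level segments (first pass)
#'
#' In history and conclusion sections sentences are comma-separated lists and
#' are split at commas. Elsewhere a segment boundary is opened before each
#' lexical clue occurrence (the clue starts the new segment). A clue or comma
#' inside a recognised mention span never splits.
#'
#' @param tokens Document tokens.
#' @param from,to Sentence token range (inclusive).
#' @param section_label One of `mri_header`, `indication`, `history`,
#'   `findings`, `conclusion`, `other`.
#' @param clue_words Character vector; see [default_clue_words()].
#' @param mentions Mentions of the sentence (for mention integrity).
#' @return data.frame with `tok_from`, `tok_to`, one row per segment, in
#'   order and jointly covering the sentence.
#' @export
segment_sentence <- function(tokens, from, to, section_label,
                             clue_words = default_clue_words(),
                             mentions = .empty_mentions()) {
  bounds <- integer(0)  # token indices that START a new segment
  if (section_label %in% c("history", "conclusion")) {
    for (i in from:to) {
      if (tokens$text[i] == "," && !any(.tok_in_mention(i, mentions)) &&
          i < to) {
        bounds <- c(bounds, i + 1L)
      }
    }
  } else {
    clue_toks <- strsplit(tolower(clue_words), " ", fixed = TRUE)
    i <- from
    while (i <= to) {
      if (!tokens$is_punct[i]) {
        for (ct in clue_toks) {
          L <- length(ct)
          if (i + L - 1L <= to &&
              identical(tolower(tokens$text[i:(i + L - 1L)]), ct) &&
              !any(.tok_in_mention(i:(i + L - 1L), mentions))) {
            if (i > from) bounds <- c(bounds, i)
            break
          }
        }
      }
      i <- i + 1L
    }
  }
  bounds <- sort(unique(bounds))
  starts <- c(from, bounds)
  ends <- c(bounds - 1L, to)
  data.frame(tok_from = starts, tok_to = ends)
}

.base_findings_in <- function(mentions, tf, tt) {
  sum(!is.na(mentions$slot) & mentions$slot == "finding" &
        is.na(mentions$base) & mentions$tok_from >= tf & mentions$tok_to <= tt)
}

#' Finding-aware conjunction splitting (second pass)
#'
#' Once finding slot candidates are known, a segment is additionally split at
#' "and"/"with" iff both resulting halves contain at least one finding
#' candidate. "or" never splits (its fillers are shared during filling).
#'
#' @param tokens Document tokens.
#' @param segments Segment data.frame from [segment_sentence()].
#' @param mentions Mentions with a `slot` column (finding candidates
#'   assigned); enumeration satellites (`base` set) do not count as separate
#'   findings.
#' @return Refined segment data.frame.
#' @export
resegment_with_findings <- function(tokens, segments, mentions) {
  out <- data.frame(tok_from = integer(), tok_to = integer())
  for (s in seq_len(nrow(segments))) {
    stack <- list(c(segments$tok_from[s], segments$tok_to[s]))
    while (length(stack)) {
      seg <- stack[[1]]; stack <- stack[-1]
      split_at <- NA_integer_
      for (i in seg[1]:seg[2]) {
        if (tokens$is_punct[i]) next
        if (!(tolower(tokens$text[i]) %in% c("and", "with"))) next
        if (any(.tok_in_mention(i, mentions))) next
        if (i == seg[1] || i == seg[2]) next
        if (.base_findings_in(mentions, seg[1], i - 1L) >= 1 &&
            .base_findings_in(mentions, i, seg[2]) >= 1) {
          split_at <- i
          break
        }
      }
      if (is.na(split_at)) {
        out[nrow(out) + 1L, ] <- list(seg[1], seg[2])
      } else {
        out[nrow(out) + 1L, ] <- list(seg[1], split_at - 1L)
        stack <- c(list(c(split_at, seg[2])), stack)
      }
    }
  }
  out
}
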