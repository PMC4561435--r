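#' @keywords internal
.lookup_exact_concept <- function(dict, norm_tokens) {
  idx <- dict$exact[[paste(norm_tokens, collapse = " ")]]
  if (is.null(idx)) return(NULL)
  dict$entries$concept_id[.break_tie(dict, idx)]
}

.add_mention <- function(mentions, tokens, doc_text, tok_from, tok_to,
                         concept_id, source, base = NA_integer_) {
  st <- tokens$start[tok_from]
  en <- tokens$start[tok_to] + tokens$length[tok_to]
  dup <- mentions$start == st & mentions$length == en - st &
    mentions$concept_id == concept_id
  if (any(dup)) return(mentions)
  uid <- if (nrow(mentions)) max(mentions$uid, na.rm = TRUE) + 1L else 1L
  mentions[nrow(mentions) + 1L, ] <- list(
    substr(doc_text, st + 1, en), st, en - st, concept_id, 1,
    source, tok_from, tok_to, base, uid)
  mentions
}

.word_tokens_in <- function(tokens, from, to) {
  idx <- from:to
  idx[!tokens$is_punct[idx]]
}

#' Resolve coordinated references ("medial and lateral meniscus")
#'
#' For the pattern <modifier> (and|or) [the] <compound mention>, where the
#' ontology holds a sibling concept whose surface form combines the modifier
#' with the compound's head, a mention of that sibling is added, anchored on
#' the modifier span. Rules only ever add mentions.
#'
#' @param tokens Document tokens.
#' @param from,to Sentence token range.
#' @param mentions Current mention data.frame.
#' @param ontology,dict Ontology and compiled dictionary.
#' @param doc_text Original document string.
#' @param allow_or Whether "or" also triggers the sibling rule.
#' @return Updated mention data.frame (superset of the input).
#' @export
apply_coordination <- function(tokens, from, to, mentions, ontology, dict,
                               doc_text, allow_or = TRUE) {
  conj <- c("and", if (allow_or) "or")
  for (c_idx in from:to) {
    if (tokens$is_punct[c_idx] || !(tolower(tokens$text[c_idx]) %in% conj)) next
    # right conjunct: first dictionary mention starting within 2 word tokens
    b_start <- c_idx + 1L
    while (b_start <= to &&
           (tokens$is_punct[b_start] ||
            tolower(tokens$text[b_start]) %in% c("the", "a", "an"))) {
      b_start <- b_start + 1L
    }
    brow <- which(mentions$tok_from == b_start &
                    mentions$source == "dictionary")
    if (!length(brow)) next
    brow <- brow[[1]]
    b_words <- .word_tokens_in(tokens, mentions$tok_from[brow],
                               mentions$tok_to[brow])
    if (length(b_words) < 2) next       # need a modifier+head compound
    head_toks <- tolower(tokens$text[b_words[-1]])
    # left conjunct: a 1-2 token modifier ending just before the conjunction
    x_to <- c_idx - 1L
    if (x_to < from || tokens$is_punct[x_to]) next
    for (x_len in 1:2) {
      x_from <- x_to - x_len + 1L
      if (x_from < from || any(tokens$is_punct[x_from:x_to])) break
      x_toks <- tolower(tokens$text[x_from:x_to])
      if (any(x_toks %in% c("the", "a", "an", "both", "and", "or"))) break
      cand <- .lookup_exact_concept(dict, c(x_toks, head_toks))
      if (!is.null(cand) && cand != mentions$concept_id[brow] &&
          length(intersect(ontology$concepts[[cand]]$parents,
                           ontology$concepts[[mentions$concept_id[brow]]]$parents))) {
        mentions <- .add_mention(mentions, tokens, doc_text, x_from, x_to,
                                 cand, "rule:coordination")
        break
      }
    }
  }
  mentions
}

#' Expand enumerated compound modifiers ("peripheral vertical longitudinal tear")
#'
#' When a compound term <modifier + head> has been matched, each additional
#' modifier token walking left from the compound is checked: if
#' <modifier + head> is itself a dictionary entry, a mention of that concept
#' is added, anchored on the modifier token and linked to the base compound
#' as a satellite (`base` column).
#'
#' @inheritParams apply_coordination
#' @export
apply_enumeration <- function(tokens, from, to, mentions, dict, doc_text) {
  n0 <- nrow(mentions)
  for (i in seq_len(n0)) {
    if (mentions$source[i] != "dictionary") next
    if (mentions$tok_from[i] < from || mentions$tok_to[i] > to) next
    words <- .word_tokens_in(tokens, mentions$tok_from[i], mentions$tok_to[i])
    if (length(words) < 2) next
    head_tok <- tolower(tokens$text[words[length(words)]])
    j <- mentions$tok_from[i] - 1L
    while (j >= from && !tokens$is_punct[j]) {
      cand <- .lookup_exact_concept(dict, c(tolower(tokens$text[j]), head_tok))
      if (is.null(cand)) break
      mentions <- .add_mention(mentions, tokens, doc_text, j, j, cand,
                               "rule:enumeration", base = mentions$uid[i])
      j <- j - 1L
    }
  }
  mentions
}

#' Default implicit-anatomy derivation table
#'
#' Morphologically implied anatomy: in "medial meniscectomy" the finding
#' mention (meniscectomy) implies the anatomical entity (medial meniscus)
#' through the modifier. Rows: `modifier` (lexeme), `finding_id`,
#' `anatomy_id`. User-extensible via a TSV of the same shape.
#' @export
default_derivation_table <- function() {
  data.frame(
    modifier = c("medial", "patellar", "prepatellar"),
    finding_id = c("TRAK:0001511", "TRAK:0000229", "TRAK:0000225"),
    anatomy_id = c("TRAK:0001090", "TRAK:0000053", "TRAK:0001054"),
    stringsAsFactors = FALSE)
}

#' Add implicit anatomical references ("medial meniscectomy")
#'
#' @inheritParams apply_coordination
#' @param derivation_table data.frame as [default_derivation_table()].
#' @export
apply_implicit_anatomy <- function(tokens, from, to, mentions, ontology,
                                   derivation_table, doc_text) {
  n0 <- nrow(mentions)
  for (i in seq_len(n0)) {
    if (mentions$tok_from[i] < from || mentions$tok_to[i] > to) next
    hits <- which(derivation_table$finding_id == mentions$concept_id[i])
    if (!length(hits)) next
    j <- mentions$tok_from[i] - 1L
    if (j < from || tokens$is_punct[j]) next
    mod <- tolower(tokens$text[j])
    for (h in hits) {
      if (derivation_table$modifier[h] == mod &&
          !is.null(ontology$concepts[[derivation_table$anatomy_id[h]]])) {
        mentions <- .add_mention(mentions, tokens, doc_text, j, j,
                                 derivation_table$anatomy_id[h],
                                 "rule:implicit_anatomy")
      }
    }
  }
  mentions
}

.NEGATION_CUES <- c("no", "not", "without")

#' Detect negation cues in a sentence
#'
#' Cues are "no", "not", "without" and the bigram "rather than". The cue
#' "no" is ignored when followed by "further" (the finding then stays
#' positive).
#'
#' @param tokens Document tokens.
#' @param from,to Sentence token range.
#' @param doc_text Original document string.
#' @return data.frame with `text`, `start`, `length`, `cue`, `tok_from`,
#'   `tok_to`, one row per accepted cue occurrence.
#' @export
detect_negation <- function(tokens, from, to, doc_text) {
  out <- data.frame(text = character(), start = integer(), length = integer(),
                    cue = character(), tok_from = integer(),
                    tok_to = integer(), stringsAsFactors = FALSE)
  i <- from
  while (i <= to) {
    if (tokens$is_punct[i]) { i <- i + 1L; next }
    w <- tolower(tokens$text[i])
    tf <- NA_integer_; tt <- NA_integer_; cue <- NULL
    if (w == "rather" && i < to && tolower(tokens$text[i + 1L]) == "than") {
      tf <- i; tt <- i + 1L; cue <- "rather than"
    } else if (w %in% .NEGATION_CUES) {
      if (w == "no" && i < to && tolower(tokens$text[i + 1L]) == "further") {
        i <- i + 2L; next
      }
      tf <- i; tt <- i; cue <- w
    }
    if (!is.null(cue)) {
      st <- tokens$start[tf]
      en <- tokens$start[tt] + tokens$length[tt]
      out[nrow(out) + 1L, ] <- list(substr(doc_text, st + 1, en), st,
                                    en - st, cue, tf, tt)
      i <- tt + 1L
    } else i <- i + 1L
  }
  out
}

#' Run the full additive rule layer over one sentence
#' @inheritParams apply_coordination
#' @param derivation_table See [default_derivation_table()].
#' @export
apply_rules <- function(tokens, from, to, mentions, ontology, dict, doc_text,
                        derivation_table = default_derivation_table(),
                        allow_or = TRUE) {
  mentions <- apply_coordination(tokens, from, to, mentions, ontology, dict,
                                 doc_text, allow_or = allow_or)
  mentions <- apply_enumeration(tokens, from, to, mentions, dict, doc_text)
  apply_implicit_anatomy(tokens, from, to, mentions, ontology,
                         derivation_table, doc_text)
}
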