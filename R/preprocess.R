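#' Tokenise a document
#'
#' Alphanumeric runs (hyphenated words and internal apostrophes kept whole,
#' so "infra-patellar" and "McMurray's" are single tokens) and individual
#' punctuation marks become tokens. Offsets are 0-based character positions
#' into the original document; `substr(doc, start+1, start+length)` always
#' reproduces `text`.
#'
#' @param text Document string (UTF-8).
#' @return data.frame with columns `text`, `start`, `length`, `is_punct`,
#'   `line` (0-based line number, used so headings never span line breaks).
#' @export
tokenize <- function(text) {
  empty <- data.frame(text = character(), start = integer(),
                      length = integer(), is_punct = logical(),
                      line = integer(), stringsAsFactors = FALSE)
  if (is.null(text) || !nzchar(text)) return(empty)
  pat <- "[[:alnum:]]+(?:[-'’][[:alnum:]]+)*|[^[:alnum:][:space:]]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[[1]] == -1) return(empty)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  toks <- substring(text, starts + 1L, starts + lens)
  nl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  lines <- if (nl[[1]] == -1) rep(0L, length(starts)) else
    findInterval(starts, as.integer(nl) - 1L)
  data.frame(text = toks, start = starts, length = lens,
             is_punct = !grepl("[[:alnum:]]", toks),
             line = as.integer(lines), stringsAsFactors = FALSE)
}

.SENT_FINAL <- c(".", "!", "?")

#' Split tokens into sentence spans
#'
#' Boundaries fall after sentence-final punctuation and around section
#' headings (a heading forms its own span, so section bodies never overlap
#' headings). A trailing sentence without final punctuation still yields a
#' span.
#'
#' @param tokens Token data.frame from [tokenize()].
#' @param heading_vocab Upper-case tokens that may form a section heading.
#' @return data.frame with `from`, `to` (token row indices, inclusive) and
#'   `is_heading`.
#' @export
split_sentences <- function(tokens, heading_vocab = default_heading_vocab()) {
  n <- nrow(tokens)
  out <- data.frame(from = integer(), to = integer(), is_heading = logical())
  if (!n) return(out)
  head_runs <- .heading_runs(tokens, heading_vocab)
  in_heading <- rep(FALSE, n)
  for (r in head_runs) in_heading[seq(r[1], r[2])] <- TRUE
  from <- 1L
  i <- 1L
  push <- function(from, to, heading) {
    if (to >= from) {
      out[nrow(out) + 1L, ] <<- list(from, to, heading)
    }
  }
  while (i <= n) {
    if (in_heading[i]) {
      push(from, i - 1L, FALSE)
      j <- i
      while (j < n && in_heading[j + 1L]) j <- j + 1L
      push(i, j, TRUE)
      i <- j + 1L
      from <- i
      next
    }
    if (tokens$text[i] %in% .SENT_FINAL) {
      push(from, i, FALSE)
      from <- i + 1L
    }
    i <- i + 1L
  }
  push(from, n, FALSE)
  out
}

#' Default section-heading vocabulary
#'
#' Fifteen upper-case tokens covering the headings seen in knee MRI reports
#' (scanner line, indication, history, findings, conclusion) plus common
#' variants. Configurable everywhere it is consumed.
#' @export
default_heading_vocab <- function() {
  c("MRI", "OF", "THE", "LEFT", "RIGHT", "KNEE", "INDICATION", "HISTORY",
    "FINDINGS", "FINDING", "CONCLUSION", "CONCLUSIONS", "REPORT",
    "CLINICAL", "IMPRESSION")
}

.heading_runs <- function(tokens, heading_vocab) {
  n <- nrow(tokens)
  is_head <- tokens$text %in% heading_vocab &
    tokens$text == toupper(tokens$text) & !tokens$is_punct
  line <- if ("line" %in% names(tokens)) tokens$line else rep(0L, n)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (is_head[i]) {
      j <- i
      while (j < n && is_head[j + 1L] && line[j + 1L] == line[j]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

.heading_label <- function(words) {
  w <- toupper(words)
  if (any(w %in% c("INDICATION"))) return("indication")
  if (any(w %in% c("HISTORY"))) return("history")
  if (any(w %in% c("FINDINGS", "FINDING"))) return("findings")
  if (any(w %in% c("CONCLUSION", "CONCLUSIONS", "IMPRESSION"))) return("conclusion")
  if (any(w %in% c("MRI", "KNEE"))) return("mri_header")
  "other"
}

#' Detect upper-case section headings and partition a report into sections
#'
#' A maximal run of upper-case tokens drawn from `heading_vocab` is a
#' heading; the section label derives from its keywords (HISTORY -> history,
#' etc.). Text before any heading belongs to an `other` section.
#'
#' @param tokens Token data.frame from [tokenize()].
#' @param heading_vocab Character vector of heading tokens.
#' @return data.frame with `label`, `head_from`, `head_to` (token indices of
#'   the heading, NA for the implicit leading section) and `body_from`,
#'   `body_to` (token indices of the section body; NA when empty).
#' @export
detect_sections <- function(tokens, heading_vocab = default_heading_vocab()) {
  stopifnot(length(heading_vocab) > 0)
  n <- nrow(tokens)
  runs <- .heading_runs(tokens, heading_vocab)
  secs <- data.frame(label = character(), head_from = integer(),
                     head_to = integer(), body_from = integer(),
                     body_to = integer(), stringsAsFactors = FALSE)
  if (!n) return(secs)
  add <- function(label, hf, ht, bf, bt) {
    if (!is.na(bf) && bt < bf) { bf <- NA_integer_; bt <- NA_integer_ }
    secs[nrow(secs) + 1L, ] <<- list(label, hf, ht, bf, bt)
  }
  if (!length(runs)) {
    add("other", NA_integer_, NA_integer_, 1L, n)
    return(secs)
  }
  first <- runs[[1]][1]
  if (first > 1L) add("other", NA_integer_, NA_integer_, 1L, first - 1L)
  for (k in seq_along(runs)) {
    r <- runs[[k]]
    bt <- if (k < length(runs)) runs[[k + 1]][1] - 1L else n
    add(.heading_label(tokens$text[r[1]:r[2]]), r[1], r[2],
        if (r[2] + 1L <= bt) r[2] + 1L else NA_integer_, bt)
  }
  secs
}

#' Section label covering a given token index
#' @keywords internal
.section_of_token <- function(sections, tok_idx) {
  for (i in seq_len(nrow(sections))) {
    lo <- min(sections$head_from[i], sections$body_from[i], na.rm = TRUE)
    hi <- max(sections$head_to[i], sections$body_to[i], na.rm = TRUE)
    if (!is.infinite(lo) && tok_idx >= lo && tok_idx <= hi) {
      return(sections$label[i])
    }
  }
  "other"
}
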