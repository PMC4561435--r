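#' Label mentions as slot candidates by semantic type
#'
#' Each mention is typed through [semantic_slot()]. One co-occurrence
#' override applies: when a cartilage-descendant anatomy mention co-occurs in
#' the sentence with other anatomy mentions, those others become anatomy
#' qualifier candidates while cartilage keeps the anatomy slot (the finding
#' applies to the cartilage as object). Mentions with no slot are labelled
#' `NA` and excluded from filling.
#'
#' @param mentions Mentions of one sentence.
#' @param ontology An `ontology`.
#' @param slot_map See [default_slot_map()].
#' @param cartilage_id Root of the cartilage branch (`NULL` disables the
#'   override).
#' @return Mentions with a `slot` column added.
#' @export
assign_slot_candidates <- function(mentions, ontology,
                                   slot_map = default_slot_map(),
                                   cartilage_id = NULL) {
  mentions$slot <- vapply(mentions$concept_id, function(id) {
    if (is.null(ontology$concepts[[id]])) return(NA_character_)
    semantic_slot(ontology, id, slot_map)
  }, character(1), USE.NAMES = FALSE)
  if (!is.null(cartilage_id) && !is.null(ontology$concepts[[cartilage_id]])) {
    cart <- descendants(ontology, cartilage_id)
    anat <- which(!is.na(mentions$slot) & mentions$slot == "anatomy")
    is_cart <- mentions$concept_id[anat] %in% cart
    if (any(is_cart) && any(!is_cart)) {
      mentions$slot[anat[!is_cart]] <- "anatomy_qualifier"
    }
  }
  mentions
}

#' Default finding/anatomy compatibility rules
#'
#' Each row says: a finding descending from `finding_root` requires an
#' anatomy descending from `anatomy_root`. A finding with no applicable rule
#' accepts any anatomy. Tears and ruptures require soft tissue.
#' @export
default_compatibility_rules <- function() {
  data.frame(finding_root = c("TOY:0000157", "TRAK:0000211"),
             anatomy_root = c("TOY:0000010", "TOY:0000010"),
             stringsAsFactors = FALSE)
}

#' Check semantic compatibility of a finding/anatomy pair
#'
#' @param finding_id,anatomy_id Concept ids.
#' @param ontology An `ontology`.
#' @param rules data.frame as [default_compatibility_rules()].
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
check_compatibility <- function(finding_id, anatomy_id, ontology,
                                rules = default_compatibility_rules()) {
  if (is.null(rules) || !nrow(rules)) return(TRUE)
  f_anc <- ancestors(ontology, finding_id)
  applicable <- rules[rules$finding_root %in% f_anc, , drop = FALSE]
  if (!nrow(applicable)) return(TRUE)
  a_anc <- ancestors(ontology, anatomy_id)
  any(applicable$anatomy_root %in% a_anc)
}

#' Default list of self-contained findings
#'
#' Findings that need no anatomical localisation because the anatomy is
#' implied by the finding itself (Osgood-Schlatter disease: traction
#' apophysitis of the anterior tibial tubercle), plus whole branches whose
#' members are never localised anatomically: physical examinations and
#' accidents. A finding is self-contained when its concept descends from
#' (or equals) a listed id.
#' @export
default_self_contained <- function() {
  c("TOY:0000167", "TRAK:0000656", "TRAK:0000362")
}

.slot_filler <- function(ontology, text, start, length, id, name = NULL) {
  if (is.null(name)) {
    name <- if (nzchar(id) && !is.null(ontology$concepts[[id]])) {
      ontology$concepts[[id]]$name
    } else ""
  }
  list(text = text, start = as.integer(start), offset = as.integer(length),
       id = id, name = name)
}

.filler_from_mention <- function(ontology, mentions, i) {
  .slot_filler(ontology, mentions$text[i], mentions$start[i],
               mentions$length[i], mentions$concept_id[i])
}

.empty_record <- function() {
  list(finding = NULL, finding_qualifiers = list(), negation = NULL,
       certainty = NULL, anatomy = NULL, anatomy_qualifiers = list())
}

# Link each anatomy-qualifier candidate to an anatomy candidate.
# Forward noun-phrase pattern: <AQ> (aspect|part|portion)? (of|to) (the|a|an)?
# <anatomy>; otherwise the nearest anatomy by character distance.
.link_aq <- function(tokens, mentions, aq_rows, anat_rows) {
  link <- rep(NA_integer_, length(aq_rows))
  glue <- c("aspect", "part", "portion", "of", "to", "the", "a", "an")
  for (k in seq_along(aq_rows)) {
    q <- aq_rows[k]
    nxt <- anat_rows[mentions$tok_from[anat_rows] > mentions$tok_to[q]]
    if (length(nxt)) {
      a <- nxt[which.min(mentions$tok_from[nxt])]
      g0 <- mentions$tok_to[q] + 1L
      g1 <- mentions$tok_from[a] - 1L
      gap <- if (g1 >= g0) g0:g1 else integer(0)
      gap_words <- tolower(tokens$text[gap][!tokens$is_punct[gap]])
      if (length(gap_words) <= 3 && all(gap_words %in% glue) &&
          (length(gap_words) == 0 || any(gap_words %in% c("of", "to")))) {
        link[k] <- a
        next
      }
    }
    if (length(anat_rows)) {
      mid_q <- mentions$start[q] + mentions$length[q] / 2
      mid_a <- mentions$start[anat_rows] + mentions$length[anat_rows] / 2
      link[k] <- anat_rows[which.min(abs(mid_a - mid_q))]
    }
  }
  link
}

# Fill records for a candidate group containing exactly one base finding.
# `context` is an environment carrying `prev_anatomy` (data.frame of anatomy
# mentions from earlier segments, most recent LAST) and accumulated warnings.
.fill_one <- function(tokens, mentions, rows, f_row, negations, ontology,
                      context, self_contained, compat_rules) {
  rec <- .empty_record()
  rec$finding <- .filler_from_mention(ontology, mentions, f_row)
  f_start <- mentions$start[f_row]
  # enumeration satellites of this finding attach as qualifiers
  sat <- which(!is.na(mentions$base) &
                 mentions$base == mentions$uid[f_row])
  fq_rows <- rows[!is.na(mentions$slot[rows]) &
                    mentions$slot[rows] == "finding_qualifier"]
  fq_rows <- union(fq_rows, intersect(sat, rows))
  for (i in fq_rows[order(mentions$start[fq_rows])]) {
    rec$finding_qualifiers[[length(rec$finding_qualifiers) + 1L]] <-
      .filler_from_mention(ontology, mentions, i)
  }
  if (nrow(negations)) {
    prior <- negations[negations$start < f_start, , drop = FALSE]
    if (nrow(prior)) {
      i <- which.max(prior$start)
      rec$negation <- .slot_filler(ontology, prior$text[i], prior$start[i],
                                   prior$length[i], "", "")
    }
  }
  cert_rows <- rows[!is.na(mentions$slot[rows]) &
                      mentions$slot[rows] == "certainty"]
  if (length(cert_rows)) {
    i <- cert_rows[which.min(abs(mentions$start[cert_rows] - f_start))]
    rec$certainty <- .filler_from_mention(ontology, mentions, i)
  }
  anat_rows <- rows[!is.na(mentions$slot[rows]) &
                      mentions$slot[rows] == "anatomy"]
  aq_rows <- rows[!is.na(mentions$slot[rows]) &
                    mentions$slot[rows] == "anatomy_qualifier"]
  aq_link <- .link_aq(tokens, mentions, aq_rows, anat_rows)
  records <- list()
  if (!length(anat_rows)) {
    f_id <- mentions$concept_id[f_row]
    self <- any(vapply(self_contained, function(s)
      !is.null(ontology$concepts[[s]]) && is_descendant(ontology, f_id, s),
      logical(1)))
    if (!self && !is.null(context$prev_anatomy) &&
        nrow(context$prev_anatomy)) {
      prev <- context$prev_anatomy
      for (i in rev(seq_len(nrow(prev)))) {
        if (check_compatibility(f_id, prev$concept_id[i], ontology,
                                compat_rules)) {
          rec$anatomy <- .slot_filler(ontology, prev$text[i], prev$start[i],
                                      prev$length[i], prev$concept_id[i])
          break
        }
      }
    }
    if (is.null(rec$anatomy) && !self) {
      context$warnings <- c(context$warnings, sprintf(
        "no anatomy found for finding '%s' at %d", mentions$text[f_row],
        f_start))
    }
    for (q in aq_rows[order(mentions$start[aq_rows])]) {
      rec$anatomy_qualifiers[[length(rec$anatomy_qualifiers) + 1L]] <-
        .filler_from_mention(ontology, mentions, q)
    }
    if (!is.null(rec$anatomy) && length(rec$anatomy_qualifiers) == 0 &&
        length(aq_rows) == 0) {
      # nothing further
    }
    records[[1]] <- rec
  } else {
    for (a in anat_rows[order(mentions$start[anat_rows])]) {
      r <- rec
      r$anatomy <- .filler_from_mention(ontology, mentions, a)
      mine <- aq_rows[!is.na(aq_link) & aq_link == a]
      orphan <- aq_rows[is.na(aq_link)]
      for (q in sort(c(mine, orphan))) {
        r$anatomy_qualifiers[[length(r$anatomy_qualifiers) + 1L]] <-
          .filler_from_mention(ontology, mentions, q)
      }
      records[[length(records) + 1L]] <- r
    }
  }
  records
}

#' Fill templates for one segment (single-finding case)
#'
#' All qualifier/negation/certainty/anatomy candidates within the segment
#' attach to its single finding; a negation cue attaches only when it
#' precedes the finding. Anatomy qualifiers are linked to anatomy fillers
#' through shallow noun-phrase structure ("X aspect of Y"). When the segment
#' has no anatomy and the finding is not self-contained, preceding segments
#' are searched (nearest first) for a compatible anatomy. A segment whose
#' single finding co-occurs with several anatomy candidates yields one record
#' per anatomy, sharing the remaining fillers.
#'
#' @param tokens Document tokens.
#' @param mentions Slot-labelled mentions (whole report).
#' @param rows Row indices of `mentions` lying in the segment.
#' @param negations Negation marks of the segment.
#' @param ontology An `ontology`.
#' @param context Environment with `prev_anatomy` from earlier segments.
#' @param self_contained See [default_self_contained()].
#' @param compat_rules See [default_compatibility_rules()].
#' @return List of records.
#' @export
fill_single_finding <- function(tokens, mentions, rows, negations, ontology,
                                context = new.env(),
                                self_contained = default_self_contained(),
                                compat_rules = default_compatibility_rules()) {
  f_rows <- rows[!is.na(mentions$slot[rows]) &
                   mentions$slot[rows] == "finding" &
                   is.na(mentions$base[rows])]
  stopifnot(length(f_rows) == 1)
  .fill_one(tokens, mentions, rows, f_rows, negations, ontology, context,
            self_contained, compat_rules)
}

#' Fill templates for one segment (two-finding case)
#'
#' The end of the first finding is the boundary dividing the remaining slot
#' fillers between the two findings. When the findings are joined by "or",
#' the non-finding fillers are shared between both records instead. More
#' than two findings fall back to left-to-right boundary division (with a
#' warning recorded on the context).
#'
#' @inheritParams fill_single_finding
#' @return List of records (normally two).
#' @export
fill_two_findings <- function(tokens, mentions, rows, negations, ontology,
                              context = new.env(),
                              self_contained = default_self_contained(),
                              compat_rules = default_compatibility_rules()) {
  f_rows <- rows[!is.na(mentions$slot[rows]) &
                   mentions$slot[rows] == "finding" &
                   is.na(mentions$base[rows])]
  f_rows <- f_rows[order(mentions$start[f_rows])]
  if (length(f_rows) == 1) {
    return(fill_single_finding(tokens, mentions, rows, negations, ontology,
                               context, self_contained, compat_rules))
  }
  if (length(f_rows) > 2) {
    context$warnings <- c(context$warnings,
                          "more than two findings in a segment; dividing left-to-right")
  }
  shared_or <- FALSE
  if (length(f_rows) == 2) {
    between <- tokens$text[
      tokens$start > mentions$start[f_rows[1]] + mentions$length[f_rows[1]] &
        tokens$start < mentions$start[f_rows[2]]]
    shared_or <- any(tolower(between) == "or")
  }
  records <- list()
  if (shared_or) {
    for (f in f_rows) {
      sub <- setdiff(rows, setdiff(f_rows, f))
      records <- c(records, .fill_one(tokens, mentions, sub, f, negations,
                                      ontology, context, self_contained,
                                      compat_rules))
    }
    return(records)
  }
  bounds <- mentions$start[f_rows] + mentions$length[f_rows]
  lo <- -1
  for (k in seq_along(f_rows)) {
    hi <- if (k < length(f_rows)) bounds[k] else Inf
    grp <- rows[mentions$start[rows] > lo & mentions$start[rows] <= hi]
    neg <- negations[negations$start > lo & negations$start <= hi, ,
                     drop = FALSE]
    recs <- .fill_one(tokens, mentions, grp, f_rows[k], neg, ontology,
                      context, self_contained, compat_rules)
    records <- c(records, recs)
    # anatomy seen in this group becomes available to the next
    anat <- grp[!is.na(mentions$slot[grp]) & mentions$slot[grp] == "anatomy"]
    if (length(anat)) {
      anat <- anat[order(mentions$start[anat])]
      context$prev_anatomy <- rbind(
        context$prev_anatomy,
        mentions[anat, c("text", "start", "length", "concept_id")])
    }
    lo <- bounds[k]
  }
  records
}

#' Serialise filled templates to JSON
#'
#' Schema: an array of records, each with keys `finding`,
#' `finding_qualifiers`, `negation`, `certainty`, `anatomy`,
#' `anatomy_qualifiers` in that order; every slot filler carries `text`,
#' `start`, `offset`, `id`, `name`. Optional slots are `null`; list slots
#' are arrays. Output is deterministic for identical input.
#'
#' @param records List of records.
#' @param report_id Optional id; when given the output is an object
#'   `{"report_id": ..., "records": [...]}` rather than a bare array.
#' @param pretty Pretty-print flag.
#' @return JSON string (UTF-8).
#' @export
to_json <- function(records, report_id = NULL, pretty = FALSE) {
  body <- lapply(records, function(r) {
    list(finding = r$finding,
         finding_qualifiers = r$finding_qualifiers,
         negation = r$negation,
         certainty = r$certainty,
         anatomy = r$anatomy,
         anatomy_qualifiers = r$anatomy_qualifiers)
  })
  payload <- if (is.null(report_id)) body else
    list(report_id = report_id, records = body)
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                                digits = NA, pretty = pretty))
}

#' Parse template JSON back into records
#' @param json JSON string produced by [to_json()] (bare array form) or an
#'   object with a `records` key.
#' @return List of records.
#' @export
from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!is.null(names(x)) && "records" %in% names(x)) x <- x$records
  lapply(x, function(r) {
    fix <- function(s) {
      if (is.null(s)) return(NULL)
      s$start <- as.integer(s$start); s$offset <- as.integer(s$offset)
      s[c("text", "start", "offset", "id", "name")]
    }
    list(finding = fix(r$finding),
         finding_qualifiers = lapply(r$finding_qualifiers, fix),
         negation = fix(r$negation),
         certainty = fix(r$certainty),
         anatomy = fix(r$anatomy),
         anatomy_qualifiers = lapply(r$anatomy_qualifiers, fix))
  })
}
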