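#' Concept ids whose mentions trigger hyponym coreference resolution
#'
#' Meniscus, ligament and tendon: hypernyms that radiologists routinely use
#' to corefer with an earlier, more specific mention.
#' @export
default_coreference_triggers <- function() {
  c("TRAK:0000045", "TRAK:0001027", "TRAK:0000046")
}

#' Resolve hyponym coreference over a report
#'
#' A mention of a trigger (hypernym) concept is retargeted to the concept of
#' the nearest preceding mention that is a strict descendant of it. With no
#' preceding descendant the mention is left unchanged. The search window is
#' the entire preceding report text.
#'
#' @param mentions Mention data.frame in document order for the whole report.
#' @param ontology An `ontology`.
#' @param trigger_ids Hypernym ids; see [default_coreference_triggers()].
#' @return Updated mention data.frame (only `concept_id` may change).
#' @export
resolve_hyponym_coreference <- function(mentions, ontology,
                                        trigger_ids = default_coreference_triggers()) {
  if (!nrow(mentions)) return(mentions)
  ord <- order(mentions$start)
  for (k in seq_along(ord)) {
    i <- ord[k]
    cid <- mentions$concept_id[i]
    if (!(cid %in% trigger_ids)) next
    if (is.null(ontology$concepts[[cid]])) next
    desc <- setdiff(descendants(ontology, cid), cid)
    if (k == 1) next
    prev <- rev(ord[seq_len(k - 1)])
    hit <- prev[mentions$concept_id[prev] %in% desc]
    if (length(hit)) mentions$concept_id[i] <- mentions$concept_id[hit[[1]]]
  }
  mentions
}

#' Default polysemy co-occurrence rules
#'
#' One shipped rule: "rupture" co-occurring with any descendant of the cyst
#' concept is reinterpreted from the injury reading to the morphologic one.
#' Rows: `ambiguous_id`, `context_id` (any descendant triggers),
#' `replacement_id`. Extensible via a TSV of the same shape.
#' @export
default_cooccurrence_rules <- function() {
  data.frame(ambiguous_id = "TRAK:0000211",
             context_id = "TRAK:0001396",
             replacement_id = "TRAK:0001461",
             stringsAsFactors = FALSE)
}

#' Resolve polysemous mentions by sentence co-occurrence
#'
#' @param mentions Mentions of one sentence (the co-occurrence window).
#' @param ontology An `ontology`.
#' @param rules data.frame as [default_cooccurrence_rules()].
#' @return Updated mention data.frame.
#' @export
resolve_polysemy <- function(mentions, ontology,
                             rules = default_cooccurrence_rules()) {
  if (!nrow(mentions) || is.null(rules) || !nrow(rules)) return(mentions)
  for (r in seq_len(nrow(rules))) {
    amb <- which(mentions$concept_id == rules$ambiguous_id[r])
    if (!length(amb)) next
    ctx_desc <- descendants(ontology, rules$context_id[r])
    ctx <- which(mentions$concept_id %in% ctx_desc)
    ctx <- setdiff(ctx, amb)
    if (length(ctx)) mentions$concept_id[amb] <- rules$replacement_id[r]
  }
  mentions
}

#' Prune nested quality mentions
#'
#' After the rule layer, mentions may nest. A mention wholly contained in
#' another mention's span (including span-identical pairs introduced by the
#' rules) is removed iff its concept descends from `removable_root` (the
#' quality branch by default); other nested mentions are retained.
#'
#' @param mentions Mention data.frame.
#' @param ontology An `ontology`.
#' @param removable_root Branch whose descendants are droppable when nested.
#' @return Pruned mention data.frame.
#' @export
prune_nested <- function(mentions, ontology, removable_root = "TRAK:0000133") {
  n <- nrow(mentions)
  if (n < 2) return(mentions)
  if (is.null(ontology$concepts[[removable_root]])) return(mentions)
  removable <- descendants(ontology, removable_root)
  ends <- mentions$start + mentions$length
  drop <- logical(n)
  for (i in seq_len(n)) {
    if (!(mentions$concept_id[i] %in% removable)) next
    container <- which(seq_len(n) != i &
                         mentions$start <= mentions$start[i] &
                         ends >= ends[i] &
                         !(mentions$concept_id %in% removable &
                             mentions$start == mentions$start[i] &
                             ends == ends[i]))
    if (length(container)) drop[i] <- TRUE
  }
  out <- mentions[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
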