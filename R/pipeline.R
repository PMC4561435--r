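#' Assemble a pipeline configuration
#'
#' Bundles the ontology, compiled dictionary, rule tables and matcher
#' settings consumed by [process_report()]. All tables are validated at
#' construction time.
#'
#' @param ontology An `ontology` or path to an OBO file.
#' @param overrides A `dict_overrides` or path to an override TSV.
#' @param slot_map Named vector type-root id -> slot label.
#' @param match MatchConfig from [match_config()].
#' @param heading_vocab Section-heading token list.
#' @param clue_words Segmentation clue words.
#' @param derivation_table Implicit-anatomy derivations (data.frame or TSV
#'   path).
#' @param cooccurrence_rules Polysemy rules (data.frame or TSV path).
#' @param compatibility_rules Finding/anatomy compatibility (data.frame or
#'   TSV path).
#' @param self_contained Ids of self-contained findings (vector or TSV path
#'   with column `id`).
#' @param coreference_triggers Hypernym ids for coreference resolution.
#' @param cartilage_id Cartilage branch root for the anatomy-qualifier
#'   co-occurrence override (`NULL` disables it).
#' @param quality_root Branch whose nested mentions are pruned.
#' @param allow_or Whether "or" triggers the coordination sibling rule.
#' @param rules_enabled Disable the pattern-rule layer entirely (for
#'   ablation/debugging).
#' @return List of class `pipeline_config` (includes the compiled `dict`).
#' @export
pipeline_config <- function(ontology,
                            overrides = dict_overrides(),
                            slot_map = default_slot_map(),
                            match = match_config(),
                            heading_vocab = default_heading_vocab(),
                            clue_words = default_clue_words(),
                            derivation_table = default_derivation_table(),
                            cooccurrence_rules = default_cooccurrence_rules(),
                            compatibility_rules = default_compatibility_rules(),
                            self_contained = default_self_contained(),
                            coreference_triggers = default_coreference_triggers(),
                            cartilage_id = NULL,
                            quality_root = "TRAK:0000133",
                            allow_or = TRUE,
                            rules_enabled = TRUE) {
  if (is.character(ontology)) ontology <- parse_obo(ontology)
  if (is.character(overrides)) overrides <- read_overrides(overrides)
  read_tsv <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      utils::read.delim(x, colClasses = "character", comment.char = "#")
    } else x
  }
  derivation_table <- read_tsv(derivation_table)
  cooccurrence_rules <- read_tsv(cooccurrence_rules)
  compatibility_rules <- read_tsv(compatibility_rules)
  if (is.character(self_contained) && length(self_contained) == 1 &&
      file.exists(self_contained)) {
    self_contained <- utils::read.delim(self_contained,
                                        colClasses = "character")$id
  }
  structure(list(
    ontology = ontology, overrides = overrides,
    dict = compile_dictionary(ontology, overrides),
    slot_map = slot_map, match = match,
    heading_vocab = heading_vocab, clue_words = clue_words,
    derivation_table = derivation_table,
    cooccurrence_rules = cooccurrence_rules,
    compatibility_rules = compatibility_rules,
    self_contained = self_contained,
    coreference_triggers = coreference_triggers,
    cartilage_id = cartilage_id, quality_root = quality_root,
    allow_or = allow_or, rules_enabled = rules_enabled),
    class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> %d concepts, %d dictionary entries\n",
              length(x$ontology$concepts), nrow(x$dict$entries)))
  invisible(x)
}

.sentence_of_token <- function(sentences, tok) {
  which(sentences$from <= tok & sentences$to >= tok)[1]
}

#' Run the full extraction pipeline on one report
#'
#' Stage order: tokenisation and sentence/section detection; soft dictionary
#' matching; pattern rules (coordination, enumeration, implicit anatomy) and
#' negation detection; disambiguation (hyponym coreference, polysemy, nested
#' pruning); clause segmentation; semantic slot typing; finding-aware
#' resegmentation; template filling; JSON serialisation. Intermediate
#' annotations are kept on the returned object for debugging.
#'
#' @param text Report text (UTF-8).
#' @param cfg A [pipeline_config()].
#' @param report_id Optional id recorded in the JSON.
#' @return List of class `report_extraction`: `records`, `json`, `mentions`,
#'   `negations`, `segments`, `sections`, `sentences`, `tokens`,
#'   `warnings`, `n_rule_mentions`.
#' @export
process_report <- function(text, cfg, report_id = NULL) {
  tokens <- tokenize(text)
  sections <- detect_sections(tokens, cfg$heading_vocab)
  sentences <- split_sentences(tokens, cfg$heading_vocab)
  mentions <- .empty_mentions()
  negations <- detect_negation(tokens, 1L, 0L, text)  # empty frame
  body <- which(!sentences$is_heading)
  for (s in body) {
    m <- match_dictionary(tokens, sentences$from[s], sentences$to[s],
                          cfg$dict, cfg$match, doc_text = text)
    mentions <- rbind(mentions, m)
  }
  if (nrow(mentions)) mentions$uid <- seq_len(nrow(mentions))
  n_dict <- nrow(mentions)
  for (s in body) {
    if (cfg$rules_enabled) {
      mentions <- apply_rules(tokens, sentences$from[s], sentences$to[s],
                              mentions, cfg$ontology, cfg$dict, text,
                              derivation_table = cfg$derivation_table,
                              allow_or = cfg$allow_or)
    }
    neg <- detect_negation(tokens, sentences$from[s], sentences$to[s], text)
    negations <- rbind(negations, neg)
  }
  n_rule <- nrow(mentions) - n_dict
  mentions <- resolve_hyponym_coreference(mentions, cfg$ontology,
                                          cfg$coreference_triggers)
  if (nrow(mentions)) {
    sent_of <- vapply(mentions$tok_from, function(t)
      .sentence_of_token(sentences, t), 0L)
    for (s in unique(sent_of)) {
      rows <- which(sent_of == s)
      mentions[rows, ] <- resolve_polysemy(mentions[rows, , drop = FALSE],
                                           cfg$ontology,
                                           cfg$cooccurrence_rules)
    }
  }
  mentions <- prune_nested(mentions, cfg$ontology, cfg$quality_root)
  # lexical segmentation pass, then semantic typing (the cartilage override
  # is scoped to the clause-level segment so that comma-separated list items
  # in conclusions do not cross-link), then the finding-aware pass
  mentions$slot <- rep(NA_character_, nrow(mentions))
  seg1_all <- data.frame(tok_from = integer(), tok_to = integer())
  for (s in body) {
    lab <- .section_of_token(sections, sentences$from[s])
    seg1 <- segment_sentence(tokens, sentences$from[s], sentences$to[s], lab,
                             cfg$clue_words, mentions)
    seg1_all <- rbind(seg1_all, seg1)
  }
  if (nrow(mentions)) {
    seg_of <- vapply(mentions$tok_from, function(t) {
      w <- which(seg1_all$tok_from <= t & seg1_all$tok_to >= t)
      if (length(w)) w[[1]] else NA_integer_
    }, 0L)
    for (s in unique(seg_of)) {
      rows <- which(!is.na(seg_of) & seg_of == s)
      if (!length(rows)) next
      mentions[rows, ] <- assign_slot_candidates(
        mentions[rows, , drop = FALSE], cfg$ontology, cfg$slot_map,
        cfg$cartilage_id)
    }
  }
  segments <- resegment_with_findings(tokens, seg1_all, mentions)
  # template filling
  context <- new.env()
  context$prev_anatomy <- NULL
  context$warnings <- character()
  records <- list()
  for (g in seq_len(nrow(segments))) {
    tf <- segments$tok_from[g]; tt <- segments$tok_to[g]
    rows <- which(mentions$tok_from >= tf & mentions$tok_to <= tt)
    neg <- negations[negations$tok_from >= tf & negations$tok_to <= tt, ,
                     drop = FALSE]
    f_rows <- rows[!is.na(mentions$slot[rows]) &
                     mentions$slot[rows] == "finding" &
                     is.na(mentions$base[rows])]
    if (length(f_rows) == 1) {
      records <- c(records, fill_single_finding(
        tokens, mentions, rows, neg, cfg$ontology, context,
        cfg$self_contained, cfg$compatibility_rules))
    } else if (length(f_rows) >= 2) {
      records <- c(records, fill_two_findings(
        tokens, mentions, rows, neg, cfg$ontology, context,
        cfg$self_contained, cfg$compatibility_rules))
    }
    anat <- rows[!is.na(mentions$slot[rows]) &
                   mentions$slot[rows] == "anatomy"]
    if (length(anat)) {
      anat <- anat[order(mentions$start[anat])]
      context$prev_anatomy <- rbind(
        context$prev_anatomy,
        mentions[anat, c("text", "start", "length", "concept_id")])
    }
  }
  structure(list(records = records,
                 json = to_json(records, report_id),
                 mentions = mentions, negations = negations,
                 segments = segments, sections = sections,
                 sentences = sentences, tokens = tokens,
                 warnings = context$warnings,
                 n_rule_mentions = n_rule, n_dict_mentions = n_dict),
            class = "report_extraction")
}

#' @export
print.report_extraction <- function(x, ...) {
  cat(sprintf("<report_extraction> %d mention(s), %d record(s), %d segment(s)\n",
              nrow(x$mentions), length(x$records), nrow(x$segments)))
  invisible(x)
}

#' Process a corpus of reports
#'
#' @param corpus Either a directory of `.txt` report files or a named
#'   character vector id -> text.
#' @param cfg A [pipeline_config()].
#' @param output_dir Optional; when given, one `<id>.json` per report plus a
#'   `corpus.jsonl` and a `log.tsv` of mention/record counts are written.
#' @return Named list id -> `report_extraction` (invisibly when writing).
#' @export
process_corpus <- function(corpus, cfg, output_dir = NULL) {
  if (length(corpus) == 1 && is.character(corpus) && dir.exists(corpus)) {
    files <- list.files(corpus, pattern = "\\.txt$", full.names = TRUE)
    texts <- vapply(files, function(f)
      paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = "\n"),
      "")
    names(texts) <- sub("\\.txt$", "", basename(files))
    corpus <- texts
  }
  out <- vector("list", length(corpus))
  names(out) <- names(corpus)
  for (id in names(corpus)) {
    res <- tryCatch(process_report(corpus[[id]], cfg, report_id = id),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("report %s failed: %s", id, conditionMessage(res)))
      next
    }
    out[[id]] <- res
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    con <- file(file.path(output_dir, "corpus.jsonl"), "w", encoding = "UTF-8")
    on.exit(close(con))
    log <- data.frame(report_id = character(), n_mentions = integer(),
                      n_rule_mentions = integer(), n_records = integer())
    for (id in names(out)) {
      if (is.null(out[[id]])) next
      writeLines(out[[id]]$json, file.path(output_dir, paste0(id, ".json")),
                 useBytes = TRUE)
      writeLines(to_json(out[[id]]$records, report_id = id), con,
                 useBytes = TRUE)
      log[nrow(log) + 1L, ] <- list(id, nrow(out[[id]]$mentions),
                                    out[[id]]$n_rule_mentions,
                                    length(out[[id]]$records))
    }
    utils::write.table(log, file.path(output_dir, "log.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
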