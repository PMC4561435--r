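#' Read a dictionary-override table
#'
#' Overrides adjust the ontology-to-dictionary export without touching the
#' ontology itself: informal surface forms are *added*, whole concepts or
#' branches are *ignored*, and surface forms can be *remapped* from one
#' concept to another (e.g. a hypernym whose mentions always denote one
#' specific child in this sublanguage).
#'
#' @param path TSV with columns `kind` (`add`, `ignore`, `ignore_branch`,
#'   `remap`), `surface` (empty for ignores), `id`, and `to_id` (remaps
#'   only). `ignore` excludes a single concept; `ignore_branch` excludes a
#'   concept together with all of its descendants.
#' @return A list of class `dict_overrides` with `added_entries`
#'   (data.frame surface/id), `ignored_concepts` (exact ids),
#'   `ignored_branches` (branch roots) and `remaps` (data.frame
#'   surface/from/to).
#' @export
read_overrides <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          fill = TRUE, comment.char = "#")
  dict_overrides(
    added_entries = df[df$kind == "add", c("surface", "id")],
    ignored_concepts = df$id[df$kind == "ignore"],
    ignored_branches = df$id[df$kind == "ignore_branch"],
    remaps = data.frame(surface = df$surface[df$kind == "remap"],
                        from = df$id[df$kind == "remap"],
                        to = df$to_id[df$kind == "remap"],
                        stringsAsFactors = FALSE))
}

#' Construct dictionary overrides in code
#' @param added_entries data.frame with `surface`, `id`.
#' @param ignored_concepts character vector of individual concept ids.
#' @param ignored_branches character vector of branch-root ids; the whole
#'   descendant closure is excluded.
#' @param remaps data.frame with `surface`, `from`, `to`.
#' @export
dict_overrides <- function(added_entries = NULL, ignored_concepts = character(),
                           ignored_branches = character(), remaps = NULL) {
  if (is.null(added_entries)) {
    added_entries <- data.frame(surface = character(), id = character(),
                                stringsAsFactors = FALSE)
  }
  if (is.null(remaps)) {
    remaps <- data.frame(surface = character(), from = character(),
                         to = character(), stringsAsFactors = FALSE)
  }
  structure(list(added_entries = added_entries,
                 ignored_concepts = ignored_concepts,
                 ignored_branches = ignored_branches,
                 remaps = remaps),
            class = "dict_overrides")
}

.validate_overrides <- function(ontology, overrides) {
  refd <- c(overrides$added_entries$id, overrides$ignored_concepts,
            overrides$ignored_branches,
            overrides$remaps$from, overrides$remaps$to)
  bad <- setdiff(refd, names(ontology$concepts))
  if (length(bad)) {
    stop(sprintf("override references unknown concept id(s): %s",
                 paste(unique(bad), collapse = ", ")))
  }
  ignored <- .ignored_set(ontology, overrides)
  clash <- intersect(overrides$remaps$to, ignored)
  if (length(clash)) {
    stop(sprintf("id(s) both ignored and remap target: %s",
                 paste(clash, collapse = ", ")))
  }
  invisible(TRUE)
}

.ignored_set <- function(ontology, overrides) {
  unique(c(overrides$ignored_concepts,
           unlist(lapply(overrides$ignored_branches,
                         function(id) descendants(ontology, id)))))
}

#' Compile the soft-matcher dictionary from an ontology
#'
#' Every name and synonym of every non-ignored concept becomes a dictionary
#' entry. Surface forms listed as remaps point to the remap target; override
#' additions are flagged informal. Inverse document frequencies are computed
#' over the entry collection itself (one "document" per entry).
#'
#' @param ontology An `ontology`.
#' @param overrides A `dict_overrides` (default: none).
#' @return An object of class `matcher_dictionary`: list with
#'   \describe{
#'     \item{entries}{data.frame `surface` (normalised), `concept_id`,
#'       `official` (logical), `n_tokens`}
#'     \item{tokens}{list of token vectors parallel to `entries`}
#'     \item{idf}{named numeric, token -> inverse document frequency}
#'     \item{default_idf}{weight used for tokens unseen in the entries}
#'   }
#' @export
compile_dictionary <- function(ontology, overrides = dict_overrides()) {
  .validate_overrides(ontology, overrides)
  ignored <- .ignored_set(ontology, overrides)
  surfaces <- character(); cids <- character(); official <- logical()
  add <- function(surface, id, off) {
    surfaces <<- c(surfaces, surface); cids <<- c(cids, id)
    official <<- c(official, off)
  }
  for (id in setdiff(names(ontology$concepts), ignored)) {
    co <- ontology$concepts[[id]]
    for (s in unique(c(co$name, co$synonyms))) {
      if (is.na(s) || !nzchar(s)) next
      add(s, id, TRUE)
    }
  }
  if (nrow(overrides$remaps)) {
    for (i in seq_len(nrow(overrides$remaps))) {
      add(overrides$remaps$surface[[i]], overrides$remaps$to[[i]], TRUE)
    }
  }
  if (nrow(overrides$added_entries)) {
    for (i in seq_len(nrow(overrides$added_entries))) {
      add(overrides$added_entries$surface[[i]],
          overrides$added_entries$id[[i]], FALSE)
    }
  }
  toks <- lapply(surfaces, .norm_tokens)
  norm <- vapply(toks, paste, "", collapse = " ")
  keep <- !duplicated(paste(norm, cids))
  toks <- toks[keep]; norm <- norm[keep]
  entries <- data.frame(surface = norm, concept_id = cids[keep],
                        official = official[keep],
                        n_tokens = lengths(toks),
                        stringsAsFactors = FALSE)
  # order-normalised entry set: deterministic regardless of input order
  ord <- order(entries$surface, entries$concept_id, method = "radix")
  entries <- entries[ord, , drop = FALSE]
  toks <- toks[ord]
  rownames(entries) <- NULL
  n_doc <- nrow(entries)
  df <- table(unlist(lapply(toks, unique)))
  idf <- log(n_doc / as.numeric(df))
  names(idf) <- names(df)
  dict <- structure(
    list(entries = entries, tokens = toks, idf = idf,
         default_idf = log(max(n_doc, 1))),
    class = "matcher_dictionary")
  dict$exact <- .build_exact_index(dict)
  dict$token_index <- .build_token_index(dict)
  dict$close_cache <- new.env(parent = emptyenv())
  dict$score_cache <- new.env(parent = emptyenv())
  dict
}

.norm_tokens <- function(s) {
  t <- tokenize(s)
  tolower(t$text[!t$is_punct])
}

.build_exact_index <- function(dict) {
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(dict$entries))) {
    key <- dict$entries$surface[[i]]
    env[[key]] <- c(env[[key]], i)
  }
  env
}

.build_token_index <- function(dict) {
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(dict$entries))) {
    for (tok in unique(dict$tokens[[i]])) env[[tok]] <- c(env[[tok]], i)
  }
  env
}

#' @export
print.matcher_dictionary <- function(x, ...) {
  cat(sprintf("<matcher_dictionary> %d entries over %d concepts (%d informal)\n",
              nrow(x$entries), length(unique(x$entries$concept_id)),
              sum(!x$entries$official)))
  invisible(x)
}

#' Dump a matcher dictionary as a TSV for inspection
#' @param dict A `matcher_dictionary`.
#' @param path Output file.
#' @export
write_dictionary_tsv <- function(dict, path) {
  utils::write.table(dict$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
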