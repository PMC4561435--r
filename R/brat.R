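#' Read gold annotations in BRAT standoff format
#'
#' Minimal reader for the annotation layout used when marking up reports:
#' `T` lines carry entity spans labelled with slot names (`Finding`,
#' `FindingQualifier`, `Negation`, `Certainty`, `Anatomy`,
#' `AnatomyQualifier`), `R` lines carry `observed_in` relations linking a
#' non-finding entity to its finding, and `#` AnnotatorNotes lines may carry
#' the concept id for an entity. Entities without a note are mapped to a
#' concept by exact dictionary lookup of their text.
#'
#' @param ann_path Path to the `.ann` file.
#' @param text Report text (for slot filler text extraction).
#' @param dict Optional `matcher_dictionary` for id lookup by surface form.
#' @return List of records (one per `Finding` entity, in span order).
#' @export
read_brat <- function(ann_path, text, dict = NULL) {
  lines <- readLines(ann_path, warn = FALSE, encoding = "UTF-8")
  ents <- list(); notes <- list(); rels <- list()
  for (ln in lines) {
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    tag <- parts[[1]]
    if (startsWith(tag, "T")) {
      meta <- strsplit(parts[[2]], " ", fixed = TRUE)[[1]]
      ents[[tag]] <- list(label = meta[[1]],
                          start = as.integer(meta[[2]]),
                          end = as.integer(meta[[3]]),
                          text = parts[[3]])
    } else if (startsWith(tag, "R")) {
      meta <- strsplit(parts[[2]], " ", fixed = TRUE)[[1]]
      if (meta[[1]] == "observed_in") {
        rels[[length(rels) + 1L]] <- c(
          sub("^Arg1:", "", meta[[2]]), sub("^Arg2:", "", meta[[3]]))
      }
    } else if (startsWith(tag, "#")) {
      meta <- strsplit(parts[[2]], " ", fixed = TRUE)[[1]]
      if (meta[[1]] == "AnnotatorNotes" && length(parts) >= 3) {
        notes[[meta[[2]]]] <- trimws(parts[[3]])
      }
    }
  }
  concept_of <- function(tid) {
    if (!is.null(notes[[tid]])) return(notes[[tid]])
    if (!is.null(dict)) {
      hit <- .lookup_exact_concept(dict, .norm_tokens(ents[[tid]]$text))
      if (!is.null(hit)) return(hit)
    }
    ""
  }
  f_ids <- names(ents)[vapply(ents, function(e) e$label == "Finding",
                              logical(1))]
  f_ids <- f_ids[order(vapply(f_ids, function(t) ents[[t]]$start, 0L))]
  slot_of <- c(Finding = "finding", FindingQualifier = "finding_qualifier",
               Negation = "negation", Certainty = "certainty",
               Anatomy = "anatomy", AnatomyQualifier = "anatomy_qualifier")
  records <- list()
  for (f in f_ids) {
    rec <- .empty_record()
    mk <- function(tid, id) {
      e <- ents[[tid]]
      list(text = e$text, start = e$start, offset = e$end - e$start,
           id = id, name = "")
    }
    rec$finding <- mk(f, concept_of(f))
    for (rel in rels) {
      if (rel[[2]] != f) next
      e <- ents[[rel[[1]]]]
      slot <- slot_of[[e$label]]
      if (is.null(slot)) next
      sf <- mk(rel[[1]], if (slot == "negation") "" else concept_of(rel[[1]]))
      if (slot == "finding_qualifier") {
        rec$finding_qualifiers[[length(rec$finding_qualifiers) + 1L]] <- sf
      } else if (slot == "anatomy_qualifier") {
        rec$anatomy_qualifiers[[length(rec$anatomy_qualifiers) + 1L]] <- sf
      } else if (slot != "finding") {
        rec[[slot]] <- sf
      }
    }
    records[[length(records) + 1L]] <- rec
  }
  records
}
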