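#' Parse an OBO 1.2 flat file into an ontology
#'
#' Reads `[Term]` stanzas and captures, for each non-obsolete term, its id,
#' name, synonyms, definition, `is_a` parents and `xref`s. Anything outside
#' the OBO 1.2 subset used by small taxonomies (typedefs, intersections,
#' relationship axioms other than `is_a`) is ignored.
#'
#' @param x Path to an OBO file, or a character vector of OBO lines, or a
#'   single string containing the whole document.
#' @return An object of class `ontology`: a list with elements
#'   \describe{
#'     \item{concepts}{named list of concepts, each a list with `id`, `name`,
#'       `synonyms`, `def`, `parents`, `xrefs`}
#'     \item{children}{named list mapping each id to its child ids}
#'     \item{roots}{ids with no parents}
#'   }
#' @details The is-a graph must be acyclic; a cycle raises a validation
#'   error. A malformed tag line raises a parse error naming the line.
#' @export
parse_obo <- function(x) {
  lines <- .obo_lines(x)
  concepts <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !isTRUE(cur$obsolete)) {
      if (is.null(cur$id)) stop("OBO term stanza without an id")
      concepts[[cur$id]] <<- cur
    }
  }
  for (i in seq_along(lines)) {
    line <- sub("\\s*!.*$", "", lines[[i]])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush()
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(id = NULL, name = NA_character_, synonyms = character(),
                    def = NA_character_, parents = character(),
                    xrefs = character(), obsolete = FALSE)
      }
      next
    }
    if (!in_term) next
    if (!grepl("^[A-Za-z_]+\\s*:", line)) {
      stop(sprintf("malformed OBO line %d: %s", i, lines[[i]]))
    }
    tag <- sub("^([A-Za-z_]+)\\s*:.*$", "\\1", line)
    val <- trimws(sub("^[A-Za-z_]+\\s*:", "", line))
    if (tag == "id") cur$id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "is_a") cur$parents <- c(cur$parents, sub("\\s.*$", "", val))
    else if (tag == "xref") cur$xrefs <- c(cur$xrefs, val)
    else if (tag == "def") cur$def <- .obo_quoted(val, i)
    else if (tag == "synonym") cur$synonyms <- c(cur$synonyms, .obo_quoted(val, i))
    else if (tag == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    # other tags ignored
  }
  flush()
  ids <- names(concepts)
  for (id in ids) {
    bad <- setdiff(concepts[[id]]$parents, ids)
    if (length(bad)) {
      stop(sprintf("concept %s has unresolved parent(s): %s",
                   id, paste(bad, collapse = ", ")))
    }
  }
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in concepts[[id]]$parents) children[[p]] <- c(children[[p]], id)
  }
  onto <- structure(
    list(concepts = concepts, children = children,
         roots = ids[vapply(concepts, function(co) length(co$parents) == 0L,
                            logical(1))]),
    class = "ontology")
  .check_acyclic(onto)
  onto
}

.obo_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE, encoding = "UTF-8"))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

.obo_quoted <- function(val, lineno) {
  m <- regmatches(val, regexpr('"(\\\\.|[^"\\\\])*"', val))
  if (!length(m)) stop(sprintf("malformed quoted value on OBO line %d", lineno))
  gsub('\\\\(.)', "\\1", substr(m, 2, nchar(m) - 1))
}

.check_acyclic <- function(onto) {
  state <- new.env(parent = emptyenv())
  visit <- function(id) {
    s <- state[[id]]
    if (identical(s, 1L)) stop(sprintf("cyclic is_a involving %s", id))
    if (identical(s, 2L)) return(invisible())
    state[[id]] <- 1L
    for (p in onto$concepts[[id]]$parents) visit(p)
    state[[id]] <- 2L
  }
  for (id in names(onto$concepts)) visit(id)
  invisible(onto)
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d concepts, %d roots\n",
              length(x$concepts), length(x$roots)))
  invisible(x)
}

#' Reflexive-transitive descendants of a concept
#'
#' @param ontology An `ontology`.
#' @param id Concept id; must exist.
#' @return Character vector of ids: the closure of `id` under child-of,
#'   always containing `id` itself.
#' @export
descendants <- function(ontology, id) {
  if (is.null(ontology$concepts[[id]])) stop(sprintf("unknown concept id: %s", id))
  seen <- character()
  queue <- id
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    queue <- c(queue, ontology$children[[cur]])
  }
  seen
}

#' Ancestors of a concept (reflexive)
#'
#' @inheritParams descendants
#' @return Character vector of ids on any is-a path from `id` to a root,
#'   including `id`.
#' @export
ancestors <- function(ontology, id) {
  if (is.null(ontology$concepts[[id]])) stop(sprintf("unknown concept id: %s", id))
  seen <- character()
  queue <- id
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    queue <- c(queue, ontology$concepts[[cur]]$parents)
  }
  seen
}

#' Is `id` a descendant of `root` (reflexively)?
#' @inheritParams descendants
#' @param root Candidate ancestor id.
#' @export
is_descendant <- function(ontology, id, root) {
  root %in% ancestors(ontology, id)
}

#' Map a concept to its template slot by semantic type
#'
#' Each template slot is associated with a set of type-root concepts. A
#' concept belongs to the slot whose type-root is among its ancestors.
#'
#' @param ontology An `ontology`.
#' @param id Concept id.
#' @param slot_map Named character vector: names are type-root concept ids,
#'   values are slot labels (`finding`, `finding_qualifier`, `certainty`,
#'   `anatomy`, `anatomy_qualifier`).
#' @return The slot label, or `NA_character_` when no type-root is an
#'   ancestor. An id falling under roots of two *different* slots is a
#'   configuration error and raises an error listing both.
#' @export
semantic_slot <- function(ontology, id, slot_map = default_slot_map()) {
  anc <- ancestors(ontology, id)
  hits <- slot_map[names(slot_map) %in% anc]
  slots <- unique(unname(hits))
  if (length(slots) > 1) {
    stop(sprintf("concept %s is typed under roots of several slots: %s",
                 id, paste(sprintf("%s->%s", names(hits), hits), collapse = ", ")))
  }
  if (!length(slots)) return(NA_character_)
  slots
}

#' Default slot/semantic-type table for the knee MRI template
#'
#' Maps semantic type-roots to the six template slots: findings cover
#' accidents, clinical manifestations, modality-related characteristics,
#' morphologic/normality/physiological-condition descriptors, pathological
#' conditions, physical examinations and surgery; finding qualifiers cover
#' the descriptor classes (size, orientation, distribution, composition,
#' quantity, status, temporal, stage of healing) plus clinical findings and
#' sports; certainty covers certainty and visibility descriptors; anatomy is
#' everything under anatomical entity; anatomy qualifiers cover anatomical
#' location descriptors, general anatomical terms and meniscus zones.
#'
#' @return Named character vector suitable for [semantic_slot()].
#' @export
default_slot_map <- function() {
  c("TRAK:0000362" = "finding",            # accident
    "TRAK:0000092" = "finding",            # clinical manifestation
    "TRAK:0001447" = "finding",            # modality-related characteristic
    "TRAK:0001456" = "finding",            # morphologic descriptor
    "TRAK:0001467" = "finding",            # normality descriptor
    "TRAK:0000204" = "finding",            # pathological condition
    "TRAK:0000656" = "finding",            # physical examination
    "TRAK:0001482" = "finding",            # physiological condition descriptor
    "TRAK:0000236" = "finding",            # surgery
    "TRAK:0000091" = "finding_qualifier",  # clinical finding
    "TRAK:0001322" = "finding_qualifier",  # composition descriptor
    "TRAK:0001441" = "finding_qualifier",  # distribution pattern
    "TRAK:0001529" = "finding_qualifier",  # orientation descriptor
    "TRAK:0001468" = "finding_qualifier",  # quantity descriptor
    "TRAK:0001485" = "finding_qualifier",  # size descriptor
    "TRAK:0000323" = "finding_qualifier",  # sport
    "TRAK:0001502" = "finding_qualifier",  # stage of healing descriptor
    "TRAK:0001478" = "finding_qualifier",  # status descriptor
    "TRAK:0001488" = "finding_qualifier",  # temporal descriptor
    "TRAK:0001422" = "certainty",          # certainty descriptor
    "TRAK:0001495" = "certainty",          # visibility descriptor
    "TRAK:0001337" = "anatomy",            # anatomical entity
    "TRAK:0001561" = "anatomy_qualifier",  # anatomical location descriptor
    "TRAK:0001581" = "anatomy_qualifier",  # general anatomical term
    "TRAK:0001345" = "anatomy_qualifier")  # meniscus zone
}
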