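# The annotated document container: report text plus entity spans and gold
# relations. Offsets are 0-based, half-open, counted in characters of the
# newline-normalized text (the convention of the BRAT annotation tool).

empty_entities <- function() {
  data.frame(id = character(), etype = character(),
             start = integer(), end = integer(), surface = character(),
             stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(id = character(), rtype = character(),
             source = character(), target = character(),
             stringsAsFactors = FALSE)
}

normalize_newlines <- function(x) gsub("\r\n?", "\n", x)

#' Construct an annotated clinical report
#'
#' Bundles a report text with its entity spans (Phenotype plus the 10
#' temporal entity types) and its gold temporal relations, validating all
#' container invariants: offsets within the text, surfaces matching the
#' covered text, unique ids, relation arguments resolving to entities of the
#' right kind (source a temporal entity, target a Phenotype), and no
#' duplicated (source, target, rtype) triples.
#'
#' @param doc_id Document identifier.
#' @param text Full report text (newlines are normalized to `"\n"`).
#' @param entities Data frame with columns `id`, `etype`, `start`, `end`,
#'   `surface`; offsets 0-based half-open in characters.
#' @param relations Data frame with columns `id`, `rtype`, `source`,
#'   `target` (entity ids; source = temporal entity, target = Phenotype).
#' @return An object of class `annotated_document`.
#' @export
annotated_document <- function(doc_id, text,
                               entities = empty_entities(),
                               relations = empty_relations()) {
  doc <- structure(
    list(doc_id = as.character(doc_id),
         text = normalize_newlines(text),
         entities = as.data.frame(entities, stringsAsFactors = FALSE),
         relations = as.data.frame(relations, stringsAsFactors = FALSE)),
    class = "annotated_document")
  rownames(doc$entities) <- NULL
  rownames(doc$relations) <- NULL
  validate_document(doc)
  doc
}

#' Validate an annotated document
#'
#' Checks every container invariant and stops with an informative message on
#' the first violation. Returns the document invisibly, so it can be used as
#' a pass-through guard.
#'
#' @param doc An `annotated_document`.
#' @return `doc`, invisibly.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "annotated_document"))
  ents <- doc$entities
  rels <- doc$relations
  n <- nchar(doc$text, type = "chars")
  if (nrow(ents)) {
    if (anyDuplicated(ents$id)) {
      stop("duplicate entity ids in document ", doc$doc_id, call. = FALSE)
    }
    bad <- !(ents$etype %in% entity_types())
    if (any(bad)) {
      stop("unknown entity type(s): ",
           paste(unique(ents$etype[bad]), collapse = ", "), call. = FALSE)
    }
    if (any(ents$start < 0L | ents$start >= ents$end | ents$end > n)) {
      stop("entity offsets outside document text in ", doc$doc_id,
           call. = FALSE)
    }
    got <- substring(doc$text, ents$start + 1L, ents$end)
    if (any(got != ents$surface)) {
      i <- which(got != ents$surface)[1]
      stop(sprintf("entity %s surface mismatch: stored %s, text has %s",
                   ents$id[i], dQuote(ents$surface[i]), dQuote(got[i])),
           call. = FALSE)
    }
  }
  if (nrow(rels)) {
    if (anyDuplicated(rels$id)) {
      stop("duplicate relation ids in document ", doc$doc_id, call. = FALSE)
    }
    bad <- !(rels$rtype %in% relation_types())
    if (any(bad)) {
      stop("unknown relation type(s): ",
           paste(unique(rels$rtype[bad]), collapse = ", "), call. = FALSE)
    }
    etype_of <- stats::setNames(ents$etype, ents$id)
    for (col in c("source", "target")) {
      miss <- !(rels[[col]] %in% ents$id)
      if (any(miss)) {
        stop("relation argument does not resolve to an entity: ",
             paste(rels[[col]][miss], collapse = ", "), call. = FALSE)
      }
    }
    if (any(etype_of[rels$source] == "Phenotype")) {
      stop("relation source must be a temporal entity, not a Phenotype",
           call. = FALSE)
    }
    if (any(etype_of[rels$target] != "Phenotype")) {
      stop("relation target must be a Phenotype", call. = FALSE)
    }
    if (anyDuplicated(rels[, c("source", "target", "rtype")])) {
      stop("duplicated (source, target, rtype) relation in ", doc$doc_id,
           call. = FALSE)
    }
  }
  invisible(doc)
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated_document %s: %d chars, %d entities, %d relations>\n",
              x$doc_id, nchar(x$text), nrow(x$entities), nrow(x$relations)))
  invisible(x)
}

entity_row <- function(doc, id) {
  i <- match(id, doc$entities$id)
  if (is.na(i)) {
    stop("entity ", id, " not found in document ", doc$doc_id, call. = FALSE)
  }
  doc$entities[i, ]
}
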