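# Candidate-pair enumeration and context-snippet extraction.
#
# A "token" is a whitespace-delimited word of the newline-normalized text —
# the simplest reproducible tokenization; swap `tokenizer` for anything
# returning 0-based character start/end offsets to change it. The snippet
# fed to prompts covers the union of [window tokens before/after the
# phenotype] and [window tokens before/after the temporal entity], with both
# entities wrapped in XML-style markers; an entity is never truncated.

#' Whitespace tokenization with character offsets
#'
#' @param text A string.
#' @return Data frame with 0-based half-open `start`/`end` character
#'   offsets, one row per whitespace-delimited token.
#' @export
tokenize <- function(text) {
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer()))
  }
  start <- as.integer(m) - 1L
  data.frame(start = start, end = start + attr(m, "match.length"))
}

mark_entity <- function(etype, surface) {
  if (etype == "Phenotype") {
    paste0("<phenotype>", surface, "</phenotype>")
  } else {
    sprintf('<time type="%s">%s</time>', etype, surface)
  }
}

# token index range [first, last] covering character span [s, e)
entity_token_range <- function(toks, s, e) {
  idx <- which(toks$end > s & toks$start < e)
  if (!length(idx)) stop("entity span covers no token", call. = FALSE)
  range(idx)
}

#' Extract the entity-marked context snippet for a candidate pair
#'
#' Builds the prompt snippet for one (temporal entity, phenotype) pair: up
#' to `window` tokens before and after each of the two entities, merged into
#' a single contiguous snippet when the two windows meet, otherwise joined
#' with an ellipsis separator. Both entities are wrapped in markers
#' (`<phenotype>...</phenotype>`, `<time type="...">...</time>`) and never
#' truncated.
#'
#' @param doc An `annotated_document`.
#' @param source_id,target_id Entity ids of the temporal entity and the
#'   phenotype.
#' @param window Per-entity token window (default 1000).
#' @param toks Optional precomputed [tokenize()] result for `doc$text`.
#' @return The marked snippet (single string).
#' @export
extract_context <- function(doc, source_id, target_id, window = 1000L,
                            toks = NULL) {
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  src <- entity_row(doc, source_id)
  tgt <- entity_row(doc, target_id)
  if (tgt$etype != "Phenotype") {
    stop("target entity must be a Phenotype", call. = FALSE)
  }
  if (is.null(toks)) toks <- tokenize(doc$text)
  n <- nrow(toks)

  win_range <- function(ent) {
    tr <- entity_token_range(toks, ent$start, ent$end)
    c(max(1L, tr[1] - window), min(n, tr[2] + window))
  }
  r1 <- win_range(src)
  r2 <- win_range(tgt)
  if (r1[1] > r2[1]) { tmp <- r1; r1 <- r2; r2 <- tmp }
  segments <- if (r2[1] <= r1[2] + 1L) {
    list(c(r1[1], max(r1[2], r2[2])))
  } else {
    list(r1, r2)
  }

  ents <- rbind(src, tgt)
  render_segment <- function(seg) {
    cs <- toks$start[seg[1]]
    ce <- toks$end[seg[2]]
    inside <- ents[ents$start >= cs & ents$end <= ce, , drop = FALSE]
    inside <- inside[order(inside$start), , drop = FALSE]
    out <- character(0)
    pos <- cs
    for (i in seq_len(nrow(inside))) {
      e <- inside[i, ]
      out <- c(out, substring(doc$text, pos + 1L, e$start),
               mark_entity(e$etype, e$surface))
      pos <- e$end
    }
    out <- c(out, substring(doc$text, pos + 1L, ce))
    paste(out, collapse = "")
  }
  paste(vapply(segments, render_segment, character(1)),
        collapse = "\n[...]\n")
}

#' Enumerate candidate (temporal entity, phenotype) pairs of a document
#'
#' One instance per (non-Phenotype entity, Phenotype entity) pair within the
#' configured token distance (default unlimited, i.e. the whole document).
#' When the document carries gold relations, each instance's `gold` column
#' is filled from them; pairs without a gold relation are gold-`NONE`.
#'
#' @param doc An `annotated_document`.
#' @param window Per-entity token window for snippet extraction.
#' @param max_token_distance Maximum token gap between the two entities
#'   (default `Inf`: all pairs).
#' @param gold Fill gold labels (set `FALSE` for unlabeled corpora; gold is
#'   then `NA`).
#' @param snippets Compute marked snippets (set `FALSE` to enumerate only).
#' @return Data frame with one row per candidate pair: `doc_id`, `source`,
#'   `target`, `source_type`, `gold`, `snippet`.
#' @export
enumerate_pairs <- function(doc, window = 1000L, max_token_distance = Inf,
                            gold = TRUE, snippets = TRUE) {
  validate_document(doc)
  ents <- doc$entities
  temporals <- ents[ents$etype != "Phenotype", , drop = FALSE]
  phenos <- ents[ents$etype == "Phenotype", , drop = FALSE]
  if (!nrow(temporals) || !nrow(phenos)) {
    return(data.frame(doc_id = character(), source = character(),
                      target = character(), source_type = character(),
                      gold = character(), snippet = character(),
                      stringsAsFactors = FALSE))
  }
  out <- expand.grid(source = temporals$id, target = phenos$id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$source, ents$id), match(out$target, ents$id)),
             , drop = FALSE]
  rownames(out) <- NULL
  out$doc_id <- doc$doc_id
  out$source_type <- temporals$etype[match(out$source, temporals$id)]

  toks <- tokenize(doc$text)
  if (is.finite(max_token_distance)) {
    tok_mid <- function(e) {
      mean(entity_token_range(toks, e["start"], e["end"]))
    }
    mids <- apply(ents[, c("start", "end")], 1, tok_mid)
    names(mids) <- ents$id
    gap <- abs(mids[out$source] - mids[out$target])
    out <- out[gap <= max_token_distance, , drop = FALSE]
    rownames(out) <- NULL
  }

  if (gold) {
    key <- function(s, t) paste(s, t, sep = "\r")
    gold_map <- stats::setNames(doc$relations$rtype,
                                key(doc$relations$source,
                                    doc$relations$target))
    g <- gold_map[key(out$source, out$target)]
    g[is.na(g)] <- NONE_LABEL
    out$gold <- unname(g)
  } else {
    out$gold <- NA_character_
  }

  out$snippet <- if (snippets && nrow(out)) {
    vapply(seq_len(nrow(out)), function(i) {
      extract_context(doc, out$source[i], out$target[i], window = window,
                      toks = toks)
    }, character(1))
  } else {
    rep(NA_character_, nrow(out))
  }
  out[, c("doc_id", "source", "target", "source_type", "gold", "snippet")]
}

#' Enumerate candidate pairs for every document of a corpus
#'
#' @param corpus A list of `annotated_document`s.
#' @inheritParams enumerate_pairs
#' @return A single data frame, rows from all documents.
#' @export
enumerate_corpus_pairs <- function(corpus, window = 1000L,
                                   max_token_distance = Inf, gold = TRUE,
                                   snippets = TRUE) {
  do.call(rbind, c(lapply(corpus, enumerate_pairs, window = window,
                          max_token_distance = max_token_distance,
                          gold = gold, snippets = snippets),
                   list(make.row.names = FALSE)))
}
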