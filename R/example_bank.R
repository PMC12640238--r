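# The example bank: curated labeled snippets, the raw material of few-shot
# prompts. Banks are ordered and consumed deterministically (the first k
# examples per label, no random sampling), mirroring manual curation from a
# dedicated prompting corpus kept separate from the evaluation corpus.

marker_integrity_ok <- function(snippet) {
  lengths(regmatches(snippet, gregexpr("<phenotype>", snippet,
                                       fixed = TRUE))) == 1L &
  lengths(regmatches(snippet, gregexpr("</phenotype>", snippet,
                                       fixed = TRUE))) == 1L &
  lengths(regmatches(snippet, gregexpr("<time type=\"", snippet,
                                       fixed = TRUE))) == 1L &
  lengths(regmatches(snippet, gregexpr("</time>", snippet,
                                       fixed = TRUE))) == 1L
}

#' Create an example bank
#'
#' @param examples Data frame with columns `snippet` (marked context
#'   snippet), `label` (a relation type or `"NONE"`) and optionally
#'   `source_doc`. Every snippet must contain exactly one phenotype marker
#'   pair and one time marker pair.
#' @param provenance Free-text note on where the examples come from (e.g.
#'   "20-report synthetic prompting corpus, seed 2020").
#' @param source_counts Optional [training_counts()]-style named vector of
#'   per-relation annotation counts in the bank's source corpus; used as the
#'   default rarity prior of [resolve_conflict()].
#' @return An object of class `example_bank`.
#' @export
example_bank <- function(examples, provenance = "",
                         source_counts = NULL) {
  examples <- as.data.frame(examples, stringsAsFactors = FALSE)
  stopifnot(all(c("snippet", "label") %in% names(examples)))
  if (is.null(examples$source_doc)) examples$source_doc <- NA_character_
  bad <- !(examples$label %in% all_labels())
  if (any(bad)) {
    stop("example labels outside vocabulary: ",
         paste(unique(examples$label[bad]), collapse = ", "), call. = FALSE)
  }
  ok <- marker_integrity_ok(examples$snippet)
  if (!all(ok)) {
    stop("example snippet(s) fail marker integrity (need exactly one ",
         "phenotype and one time marker pair): rows ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  if (!is.null(source_counts)) source_counts <- training_counts(source_counts)
  .ptrex_env$bank_counter <- .ptrex_env$bank_counter + 1L
  structure(list(examples = examples[, c("snippet", "label", "source_doc")],
                 provenance = provenance,
                 source_counts = source_counts,
                 uid = sprintf("bank%06d", .ptrex_env$bank_counter)),
            class = "example_bank")
}

#' @export
print.example_bank <- function(x, ...) {
  cat(sprintf("<example_bank: %d examples (%s)>\n", nrow(x$examples),
              paste(names(table(x$examples$label)),
                    table(x$examples$label), sep = "=", collapse = " ")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

bank_examples_for <- function(bank, label, k) {
  hits <- bank$examples[bank$examples$label == label, , drop = FALSE]
  if (nrow(hits) < k) {
    stop(sprintf("example bank holds %d %s example(s), need %d",
                 nrow(hits), label, k), call. = FALSE)
  }
  hits[seq_len(k), , drop = FALSE]
}

#' Build an example bank from an annotated corpus
#'
#' Walks the corpus in document order and takes the first `per_type`
#' gold-labeled snippets of every relation type, plus the first `n_none`
#' gold-NONE snippets (a dedicated NONE pool, never other relations'
#' positives). Deterministic given the corpus.
#'
#' @param corpus List of `annotated_document`s (typically a dedicated
#'   prompting corpus, as in a curated 20-report example set).
#' @param per_type Examples kept per relation type (3 covers both the
#'   multi-class regime, which uses 2, and the binary regime, which uses 3).
#' @param n_none NONE examples kept.
#' @param window Token window for example snippets; small by default so
#'   prompts stay compact.
#' @param provenance Provenance note stored in the bank.
#' @return An `example_bank` whose `source_counts` are the corpus's
#'   per-relation annotation counts.
#' @export
build_example_bank <- function(corpus, per_type = 3L, n_none = 3L,
                               window = 30L,
                               provenance = "synthetic prompting corpus") {
  need <- stats::setNames(rep(per_type, 7L), relation_types())
  need[NONE_LABEL] <- n_none
  rows <- list()
  for (doc in corpus) {
    if (all(need == 0L)) break
    pairs <- enumerate_pairs(doc, snippets = FALSE)
    for (i in seq_len(nrow(pairs))) {
      lbl <- pairs$gold[i]
      if (need[[lbl]] == 0L) next
      snip <- extract_context(doc, pairs$source[i], pairs$target[i],
                              window = window)
      rows[[length(rows) + 1L]] <- data.frame(
        snippet = snip, label = lbl, source_doc = doc$doc_id,
        stringsAsFactors = FALSE)
      need[[lbl]] <- need[[lbl]] - 1L
      if (all(need == 0L)) break
    }
  }
  if (any(need > 0L)) {
    stop("corpus does not provide enough examples for: ",
         paste(names(need)[need > 0L], collapse = ", "), call. = FALSE)
  }
  ex <- do.call(rbind, rows)
  ex <- ex[order(match(ex$label, all_labels())), , drop = FALSE]
  rownames(ex) <- NULL
  example_bank(ex, provenance = provenance,
               source_counts = counts_from_corpus(corpus))
}

#' Default example bank from a seeded prompting corpus
#'
#' Generates a dedicated 20-document synthetic prompting corpus (kept
#' separate from any evaluation corpus by its own seed) and curates a bank
#' from it. Cached per session.
#'
#' @param seed Seed of the prompting corpus.
#' @param ... Passed to [build_example_bank()].
#' @return An `example_bank`.
#' @export
default_example_bank <- function(seed = 2020L, ...) {
  key <- paste0("default_bank_", seed)
  if (is.null(.ptrex_env[[key]])) {
    corp <- generate_corpus(generation_config(n_docs = 20L, seed = seed))
    .ptrex_env[[key]] <- build_example_bank(
      corp, ...,
      provenance = sprintf("20-report synthetic prompting corpus, seed %d",
                           seed))
  }
  .ptrex_env[[key]]
}

#' Read or write an example bank as JSON lines
#'
#' One JSON object per line with fields `snippet`, `label`, `source_doc`,
#' so banks can be curated outside R.
#'
#' @param bank An `example_bank`.
#' @param path File path.
#' @param provenance,source_counts See [example_bank()].
#' @return `write_example_bank()` the path invisibly; `read_example_bank()`
#'   an `example_bank`.
#' @export
write_example_bank <- function(bank, path) {
  lines <- vapply(seq_len(nrow(bank$examples)), function(i) {
    jsonlite::toJSON(as.list(bank$examples[i, ]), auto_unbox = TRUE)
  }, character(1))
  write_utf8(paste0(paste(lines, collapse = "\n"), "\n"), path)
  invisible(path)
}

#' @rdname write_example_bank
#' @export
read_example_bank <- function(path, provenance = path,
                              source_counts = NULL) {
  lines <- strsplit(read_utf8(path), "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  example_bank(do.call(rbind, rows), provenance = provenance,
               source_counts = source_counts)
}
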