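# BRAT standoff I/O.
#
# A document is a .txt file plus a .ann file of T-lines (entities) and
# R-lines (relations):
#   T1<TAB>Phenotype 0 6<TAB>fièvre
#   R1<TAB>BEGINS-AT Arg1:T2 Arg2:T1
# Offsets are 0-based half-open character offsets into the newline-normalized
# text. Discontinuous spans (semicolon-separated fragments) are rejected.
# Arg1 is the temporal entity and Arg2 the phenotype; reversed arguments are
# auto-normalized with a warning.

#' Parse a BRAT standoff document
#'
#' Reads a report text and its standoff annotation into an
#' [annotated_document()]. Entity T-lines with a vocabulary type become
#' entities; R-lines become relations. Offsets and surfaces are validated
#' against the text. Unknown entity types are skipped with a warning by
#' default (`on_unknown_entity = "reject"` turns them into errors); unknown
#' relation types, dangling relation arguments and discontinuous spans are
#' always parse errors naming the offending line.
#'
#' @param txt_content The report text (a single string).
#' @param ann_content The standoff annotation (single string or character
#'   vector of lines).
#' @param doc_id Document identifier to attach.
#' @param on_unknown_entity `"skip"` (default, with warning) or `"reject"`.
#' @return An `annotated_document`.
#' @examples
#' doc <- read_brat("fièvre depuis hier", "T1\tPhenotype 0 6\tfièvre")
#' nrow(doc$entities)
#' @export
read_brat <- function(txt_content, ann_content, doc_id = "doc",
                      on_unknown_entity = c("skip", "reject")) {
  on_unknown_entity <- match.arg(on_unknown_entity)
  text <- normalize_newlines(txt_content)
  lines <- if (length(ann_content) == 1L) {
    strsplit(normalize_newlines(ann_content), "\n", fixed = TRUE)[[1]]
  } else {
    as.character(ann_content)
  }
  lines <- lines[nzchar(trimws(lines))]
  n <- nchar(text, type = "chars")

  ents <- list()
  rel_lines <- character(0)
  for (line in lines) {
    first <- substring(line, 1L, 1L)
    if (first == "T") {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L) {
        stop("malformed T-line: ", dQuote(line), call. = FALSE)
      }
      head <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      if (grepl(";", parts[2], fixed = TRUE)) {
        stop("discontinuous spans are not supported: ", dQuote(line),
             call. = FALSE)
      }
      if (length(head) != 3L) {
        stop("malformed entity header in line: ", dQuote(line), call. = FALSE)
      }
      etype <- head[1]
      start <- suppressWarnings(as.integer(head[2]))
      end <- suppressWarnings(as.integer(head[3]))
      if (is.na(start) || is.na(end)) {
        stop("non-numeric offsets in line: ", dQuote(line), call. = FALSE)
      }
      if (!etype %in% entity_types()) {
        if (on_unknown_entity == "reject") {
          stop("unknown entity type ", dQuote(etype), " in line: ",
               dQuote(line), call. = FALSE)
        }
        warning("skipping entity with unknown type ", dQuote(etype),
                " in line: ", dQuote(line), call. = FALSE)
        next
      }
      if (start < 0L || start >= end || end > n) {
        stop(sprintf("offsets [%d,%d) outside text (length %d) in line: %s",
                     start, end, n, dQuote(line)), call. = FALSE)
      }
      surface <- if (length(parts) >= 3L) {
        paste(parts[-(1:2)], collapse = "\t")
      } else {
        ""
      }
      got <- substring(text, start + 1L, end)
      # BRAT renders newlines in surfaces as spaces
      if (surface != got && surface != gsub("\n", " ", got, fixed = TRUE)) {
        stop(sprintf("surface mismatch (%s vs text %s) in line: %s",
                     dQuote(surface), dQuote(got), dQuote(line)),
             call. = FALSE)
      }
      ents[[length(ents) + 1L]] <- data.frame(
        id = parts[1], etype = etype, start = start, end = end,
        surface = got, stringsAsFactors = FALSE)
    } else if (first == "R") {
      rel_lines <- c(rel_lines, line)
    } else if (first %in% c("#", "A", "M", "N")) {
      # comments / attributes / normalizations: irrelevant to this schema
      next
    } else {
      warning("ignoring unrecognized standoff line: ", dQuote(line),
              call. = FALSE)
    }
  }
  entities <- if (length(ents)) do.call(rbind, ents) else empty_entities()
  etype_of <- stats::setNames(entities$etype, entities$id)

  rels <- list()
  for (line in rel_lines) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    head <- strsplit(trimws(parts[2] %||% ""), " +")[[1]]
    if (length(parts) < 2L || length(head) != 3L) {
      stop("malformed R-line: ", dQuote(line), call. = FALSE)
    }
    rtype <- head[1]
    if (!rtype %in% relation_types()) {
      stop("unknown relation type ", dQuote(rtype), " in line: ",
           dQuote(line), call. = FALSE)
    }
    args <- sub("^Arg[12]:", "", head[2:3])
    if (!all(args %in% entities$id)) {
      stop("dangling relation argument in line: ", dQuote(line),
           call. = FALSE)
    }
    src <- args[1]; tgt <- args[2]
    if (etype_of[[src]] == "Phenotype" && etype_of[[tgt]] != "Phenotype") {
      warning("reversed relation arguments normalized in line: ",
              dQuote(line), call. = FALSE)
      tmp <- src; src <- tgt; tgt <- tmp
    }
    rels[[length(rels) + 1L]] <- data.frame(
      id = parts[1], rtype = rtype, source = src, target = tgt,
      stringsAsFactors = FALSE)
  }
  relations <- if (length(rels)) do.call(rbind, rels) else empty_relations()
  annotated_document(doc_id, text, entities, relations)
}

#' Serialize an annotated document to BRAT standoff
#'
#' Emits the `.txt` and `.ann` payloads for a document. The output reparses
#' to an equal document (round-trip identity). Documents violating the
#' container invariants are refused (validation runs first). Entity surfaces
#' containing newlines are refused since their standoff form would not
#' round-trip.
#'
#' @param doc An `annotated_document`.
#' @return A list with elements `txt` and `ann` (single strings).
#' @export
write_brat <- function(doc) {
  validate_document(doc)
  if (nrow(doc$entities) && any(grepl("\n", doc$entities$surface,
                                      fixed = TRUE))) {
    stop("refusing to serialize entity surfaces containing newlines",
         call. = FALSE)
  }
  t_lines <- if (nrow(doc$entities)) {
    sprintf("%s\t%s %d %d\t%s",
            doc$entities$id, doc$entities$etype,
            doc$entities$start, doc$entities$end, doc$entities$surface)
  } else {
    character(0)
  }
  r_lines <- if (nrow(doc$relations)) {
    sprintf("%s\t%s Arg1:%s Arg2:%s",
            doc$relations$id, doc$relations$rtype,
            doc$relations$source, doc$relations$target)
  } else {
    character(0)
  }
  ann <- paste0(paste(c(t_lines, r_lines), collapse = "\n"),
                if (length(t_lines) + length(r_lines)) "\n" else "")
  list(txt = doc$text, ann = ann)
}

#' Read or write a corpus directory of BRAT document pairs
#'
#' `write_corpus()` writes one `<doc_id>.txt` / `<doc_id>.ann` pair per
#' document (UTF-8), plus a `<doc_id>.timeline.json` sidecar when the
#' document carries a latent timeline (synthetic corpora do; see
#' [generate_corpus()]). `read_corpus()` reads all pairs back, reattaching
#' sidecars.
#'
#' @param corpus A list of `annotated_document`s.
#' @param dir Directory path.
#' @param ... Passed on to [read_brat()].
#' @return `write_corpus()` the directory path invisibly; `read_corpus()` a
#'   list of documents named by `doc_id`.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in corpus) {
    payload <- write_brat(doc)
    write_utf8(payload$txt, file.path(dir, paste0(doc$doc_id, ".txt")))
    write_utf8(payload$ann, file.path(dir, paste0(doc$doc_id, ".ann")))
    tl <- attr(doc, "timeline")
    if (!is.null(tl)) {
      jsonlite::write_json(
        encode_timeline(tl),
        file.path(dir, paste0(doc$doc_id, ".timeline.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir, ...) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- lapply(txts, function(txt_path) {
    doc_id <- sub("\\.txt$", "", basename(txt_path))
    ann_path <- file.path(dir, paste0(doc_id, ".ann"))
    if (!file.exists(ann_path)) {
      stop("missing .ann file for ", doc_id, call. = FALSE)
    }
    doc <- read_brat(read_utf8(txt_path), read_utf8(ann_path),
                     doc_id = doc_id, ...)
    side <- file.path(dir, paste0(doc_id, ".timeline.json"))
    if (file.exists(side)) {
      attr(doc, "timeline") <- decode_timeline(
        jsonlite::read_json(side, simplifyVector = FALSE))
    }
    doc
  })
  stats::setNames(docs, vapply(docs, function(d) d$doc_id, character(1)))
}

write_utf8 <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(x)), con)
  invisible(path)
}

read_utf8 <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  txt
}
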