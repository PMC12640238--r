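# Seeded generator of French-flavored annotated reports with a latent
# patient timeline, so every downstream stage is testable without access to
# private hospital data.
#
# The latent world is an abstract integer day axis with day 0 = date of
# birth. Each document gets a current-visit day, a few past visits, and one
# generated sentence per relation: a time expression is realized on the
# axis, a phenotype interval is constructed so that label_relation() yields
# the requested relation type (checked at generation time), and both are
# rendered into a French sentence with tracked character offsets. All
# temporal-entity x phenotype pairs without a generated relation are
# gold-NONE by construction.

#' Relation-type counts of the original annotated corpus
#'
#' The published 10 x 7 count matrix of relation types per temporal entity
#' type for the original 25-report annotated corpus (706 relations in
#' total), used as the default distribution target of the synthetic
#' generator and as the documented alternative source of training counts
#' for [resolve_conflict()].
#'
#' @return Integer matrix, rows the 10 temporal entity types, columns the 7
#'   relation types.
#' @examples
#' published_relation_counts()["DOV", "BEFORE-OVERLAP"]  # 181
#' sum(published_relation_counts())                      # 706
#' @export
published_relation_counts <- function() {
  m <- matrix(c(
     1, 0, 1,  0,   7,  0,  0,   # DOB
     1, 0, 0,  0,   2,  0,  0,   # DOR
    85, 0, 7,  2, 181, 11,  0,   # DOV
    50, 4, 1, 38,  59, 10,  0,   # DOPV
     0, 0, 0,  0,   0,  0,  0,   # DOFV
     0, 0, 0,  0,   0,  0,  0,   # DOTHER
     9, 1, 1, 14,   9,  0,  0,   # Age
    22, 0, 9, 10,  58,  0, 11,   # Duration
     0, 0, 0,  0,   0,  0,  3,   # Frequency
    34, 2, 3, 16,  41,  3,  0    # Time
  ), nrow = 10, byrow = TRUE,
  dimnames = list(TEMPORAL_TYPES, RELATION_TYPES))
  storage.mode(m) <- "integer"
  m
}

#' @rdname published_relation_counts
#' @export
published_relation_totals <- function() colSums(published_relation_counts())

# Entity types semantically able to carry each relation: date-like entities
# are time points, so relations requiring a proper time span (containment,
# residual overlap, co-extension) are restricted to span-valued types.
RELATION_COMPAT <- list(
  "BEGINS-AT"      = c("DOB", "DOR", "DOV", "DOPV", "Age", "Duration", "Time"),
  "ENDS-AT"        = c("DOPV", "Age", "Time"),
  "CONTAINS"       = c("Age", "Duration", "Time"),
  "OVERLAP"        = c("Age", "Duration", "Time"),
  "BEFORE-OVERLAP" = c("DOB", "DOR", "DOV", "DOPV", "Age", "Duration", "Time"),
  "BEFORE"         = c("DOV", "DOPV", "Time"),
  "SIMULTANEOUS"   = c("Duration", "Frequency")
)

# Feminine phenotype terms so article/participle agreement stays uniform.
PHENOTYPE_TERMS <- c(
  "fièvre", "protéinurie", "hématurie", "hypotonie", "anémie",
  "polyurie", "dyspnée", "constipation", "toux", "éruption cutanée",
  "hépatomégalie", "splénomégalie", "insuffisance rénale",
  "hypertension artérielle", "infection urinaire",
  "cassure staturo-pondérale")

MONTHS_FR <- c("janvier", "février", "mars", "avril", "mai", "juin",
               "juillet", "août", "septembre", "octobre", "novembre",
               "décembre")

#' Configuration of the synthetic corpus generator
#'
#' The defaults state the emulated world: 25 documents with on average 28
#' phenotype mentions (hence relations) each, matching the 706 relations of
#' the original 25-report corpus, and a relation mix proportional to its
#' published totals. The seed fully determines the output.
#'
#' @param n_docs Number of documents.
#' @param seed Integer seed; same seed, same corpus, byte for byte.
#' @param relation_mix Non-negative target proportions over the 7 relation
#'   types (named or in schema order); normalized to sum to 1.
#' @param mean_phenotypes_per_doc Poisson mean of phenotype mentions (one
#'   relation each) per document.
#' @param entity_types Temporal entity types the generator may use.
#' @return A `generation_config` list.
#' @export
generation_config <- function(n_docs = 25L, seed = 1L,
                              relation_mix = published_relation_totals(),
                              mean_phenotypes_per_doc = 28,
                              entity_types = temporal_entity_types()) {
  if (n_docs < 0) stop("n_docs must be non-negative", call. = FALSE)
  mix <- as.numeric(relation_mix)
  if (length(mix) != 7L) stop("relation_mix must have 7 entries",
                              call. = FALSE)
  if (!is.null(names(relation_mix))) {
    if (!setequal(names(relation_mix), RELATION_TYPES)) {
      stop("relation_mix names must be the 7 relation types", call. = FALSE)
    }
    mix <- as.numeric(relation_mix[RELATION_TYPES])
  }
  if (any(is.na(mix) | mix < 0) || sum(mix) <= 0) {
    stop("relation_mix must be non-negative with a positive sum",
         call. = FALSE)
  }
  mix <- mix / sum(mix)
  names(mix) <- RELATION_TYPES
  entity_types <- match.arg(entity_types, temporal_entity_types(),
                            several.ok = TRUE)
  for (r in RELATION_TYPES[mix > 0]) {
    if (!length(intersect(RELATION_COMPAT[[r]], entity_types))) {
      stop("unsatisfiable relation_mix: ", r,
           " requested but no compatible entity type enabled (needs one of ",
           paste(RELATION_COMPAT[[r]], collapse = ", "), ")", call. = FALSE)
    }
  }
  if (mean_phenotypes_per_doc <= 0) {
    stop("mean_phenotypes_per_doc must be positive", call. = FALSE)
  }
  structure(list(n_docs = as.integer(n_docs), seed = as.integer(seed),
                 relation_mix = mix,
                 mean_phenotypes_per_doc = mean_phenotypes_per_doc,
                 entity_types = entity_types),
            class = "generation_config")
}

with_preserved_rng <- function(code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

# --- incremental text builder with character-offset tracking --------------

new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$chunks <- character(0)
  b$pos <- 0L
  b$ents <- list()
  b$ent_n <- 0L
  b$spans <- list()
  b
}

emit_lit <- function(b, text) {
  b$chunks <- c(b$chunks, text)
  b$pos <- b$pos + nchar(text, type = "chars")
  invisible(b)
}

emit_ent <- function(b, etype, surface, latent_span) {
  b$ent_n <- b$ent_n + 1L
  id <- paste0("T", b$ent_n)
  start <- b$pos
  emit_lit(b, surface)
  b$ents[[id]] <- data.frame(id = id, etype = etype, start = start,
                             end = b$pos, surface = surface,
                             stringsAsFactors = FALSE)
  b$spans[[id]] <- as.numeric(latent_span)
  id
}

# --- time-expression realization ------------------------------------------

fr_date <- function(dob_date, day) format(dob_date + day, "%d/%m/%Y")

fr_month <- function(first_of_month) {
  paste(MONTHS_FR[as.integer(format(first_of_month, "%m"))],
        format(first_of_month, "%Y"))
}

# Returns list(pre, surf, post, span) for one time-expression mention.
realize_timeexp <- function(etype, rtype, dob_date, v_day, past_visits) {
  before <- rtype == "BEFORE"
  switch(etype,
    DOV = list(
      pre = if (before) "avant la consultation du " else
        "lors de la consultation du ",
      surf = fr_date(dob_date, v_day), post = "", span = c(v_day, v_day)),
    DOPV = {
      p <- past_visits[sample.int(length(past_visits), 1L)]
      list(pre = if (before) "avant la visite du " else
             "lors de la visite du ",
           surf = fr_date(dob_date, p), post = "", span = c(p, p))
    },
    DOR = list(pre = "à la date de ce compte rendu, le ",
               surf = fr_date(dob_date, v_day), post = "",
               span = c(v_day, v_day)),
    DOB = list(pre = "à la naissance, le ",
               surf = fr_date(dob_date, 0), post = "", span = c(0, 0)),
    Age = {
      a <- sample.int(max(1L, (v_day - 365L) %/% 365L), 1L)
      list(pre = "à l'âge de ",
           surf = paste(a, "ans"), post = "",
           span = c(365 * a, 365 * a + 364))
    },
    Duration = {
      m <- if (rtype == "CONTAINS") sample(3:18, 1L) else sample(1:12, 1L)
      d <- 30L * m
      pre <- switch(rtype,
                    "CONTAINS" = "au cours des ",
                    "OVERLAP" = "au cours des ",
                    "SIMULTANEOUS" = "pendant exactement ",
                    "depuis ")
      post <- if (rtype %in% c("CONTAINS", "OVERLAP")) " écoulés"
              else ""
      list(pre = pre, surf = paste(m, "mois"), post = post,
           span = c(v_day - d, v_day))
    },
    Time = {
      m <- sample(60:max(61L, v_day - 40L), 1L)
      first <- as.Date(format(dob_date + m, "%Y-%m-01"))
      nxt <- seq(first, by = "month", length.out = 2L)[2L]
      list(pre = if (before) "avant " else "en ",
           surf = fr_month(first), post = "",
           span = c(as.integer(first - dob_date),
                    as.integer(nxt - 1L - dob_date)))
    },
    Frequency = {
      m <- sample(1:12, 1L)
      list(pre = "",
           surf = sample(c("quotidienne", "pluriquotidienne",
                           "hebdomadaire"), 1L),
           post = paste0(" depuis ", m, " mois"),
           span = c(v_day - 30L * m, v_day))
    },
    stop("no surface template for entity type ", etype, call. = FALSE)
  )
}

# Construct a phenotype interval realizing `rtype` against tspan.
realize_phenotype_span <- function(rtype, tspan) {
  ts <- tspan[1]; te <- tspan[2]
  switch(rtype,
    "BEGINS-AT" = {
      pe <- ts + sample(30:400, 1L)
      if (pe == te) pe <- pe + 7
      c(ts, pe)
    },
    "ENDS-AT" = {
      ps <- te - sample(30:400, 1L)
      if (ps == ts) ps <- ps - 7
      c(ps, te)
    },
    "CONTAINS" = {
      g <- te - ts
      stopifnot(g >= 2)
      a <- sample.int(g - 1L, 1L)
      b <- sample.int(g - a, 1L)
      c(ts + a, te - b)
    },
    "OVERLAP" = c(ts + sample.int(te - ts, 1L), te + sample(30:200, 1L)),
    "BEFORE-OVERLAP" = {
      ps <- ts - sample(30:1000, 1L)
      pe <- if (stats::runif(1) < 0.5) Inf else te + sample(7:300, 1L)
      c(ps, pe)
    },
    "BEFORE" = {
      pe <- ts - sample(10:200, 1L)
      c(pe - sample(10:400, 1L), pe)
    },
    "SIMULTANEOUS" = c(ts, te),
    stop("unknown relation type ", rtype, call. = FALSE)
  )
}

elide <- function(article, phen) {
  if (grepl("^[aeéiouh]", phen)) {
    article <- sub("de la $", "de l'", article)
    article <- sub("La $", "L'", article)
  }
  article
}

# One French sentence per relation; article chosen by template (with
# elision before vowel-initial terms).
emit_relation_sentence <- function(b, rtype, etype, phen, tx, pspan) {
  emit_time <- function() {
    emit_lit(b, tx$pre)
    id <- emit_ent(b, etype, tx$surf, tx$span)
    emit_lit(b, tx$post)
    id
  }
  emit_phen <- function(article) {
    emit_lit(b, elide(article, phen))
    emit_ent(b, "Phenotype", phen, pspan)
  }
  ids <- switch(rtype,
    "BEGINS-AT" = {
      p <- emit_phen("Apparition d'une ")
      emit_lit(b, " ")
      t <- emit_time()
      c(t, p)
    },
    "ENDS-AT" = {
      p <- emit_phen("Disparition de la ")
      emit_lit(b, " ")
      t <- emit_time()
      c(t, p)
    },
    "CONTAINS" = {
      p <- emit_phen("Bref épisode résolutif de ")
      emit_lit(b, ", ")
      t <- emit_time()
      c(t, p)
    },
    "OVERLAP" = {
      p <- emit_phen("Une ")
      emit_lit(b, " a été notée, en partie ")
      t <- emit_time()
      c(t, p)
    },
    "BEFORE-OVERLAP" = {
      p <- emit_phen("La ")
      emit_lit(b, ", apparue antérieurement, persiste ")
      t <- emit_time()
      c(t, p)
    },
    "BEFORE" = {
      p <- emit_phen("La ")
      emit_lit(b, " avait déjà disparu ")
      t <- emit_time()
      c(t, p)
    },
    "SIMULTANEOUS" = {
      if (etype == "Frequency") {
        p <- emit_phen("Une ")
        emit_lit(b, " ")
        t <- emit_time()
        emit_lit(b, " est rapportée")
      } else {
        p <- emit_phen("Une ")
        emit_lit(b, " a été présente ")
        t <- emit_time()
        emit_lit(b, ", jusqu'à ce jour")
      }
      c(t, p)
    })
  emit_lit(b, ".\n")
  ids  # c(source temporal id, target phenotype id)
}

generate_document <- function(doc_id, config) {
  dob_date <- as.Date("2008-01-01") + sample.int(4000L, 1L)
  v_day <- sample(730:5475, 1L)
  past_visits <- sort(unique(sample(100:(v_day - 60L),
                                    sample(2:4, 1L), replace = TRUE)))
  n_rel <- max(1L, stats::rpois(1L, config$mean_phenotypes_per_doc))
  rtypes <- sample(RELATION_TYPES, n_rel, replace = TRUE,
                   prob = config$relation_mix)
  counts <- published_relation_counts()

  b <- new_builder()
  emit_lit(b, "Compte rendu de consultation du ")
  emit_ent(b, "DOR", fr_date(dob_date, v_day), c(v_day, v_day))
  emit_lit(b, ".\nPatient né le ")
  emit_ent(b, "DOB", fr_date(dob_date, 0), c(0, 0))
  emit_lit(b, ", suivi pour une ciliopathie.\nConsultation du ")
  emit_ent(b, "DOV", fr_date(dob_date, v_day), c(v_day, v_day))
  emit_lit(b, ".\nHistoire de la maladie :\n")

  rels <- list()
  for (k in seq_len(n_rel)) {
    rtype <- rtypes[k]
    compat <- intersect(RELATION_COMPAT[[rtype]], config$entity_types)
    w <- counts[compat, rtype]
    if (sum(w) == 0) w <- rep(1, length(compat))
    etype <- if (length(compat) == 1L) compat else
      sample(compat, 1L, prob = w)
    tx <- realize_timeexp(etype, rtype, dob_date, v_day, past_visits)
    pspan <- realize_phenotype_span(rtype, tx$span)
    phen <- sample(PHENOTYPE_TERMS, 1L)
    ids <- emit_relation_sentence(b, rtype, etype, phen, tx, pspan)
    # gold label must agree with the interval-semantics oracle by construction
    stopifnot(identical(label_relation(span(pspan[1], pspan[2]),
                                       span(tx$span[1], tx$span[2])),
                        rtype))
    rels[[k]] <- data.frame(id = paste0("R", k), rtype = rtype,
                            source = ids[1], target = ids[2],
                            stringsAsFactors = FALSE)
  }

  entities <- do.call(rbind, b$ents)
  relations <- if (length(rels)) do.call(rbind, rels) else empty_relations()
  doc <- annotated_document(doc_id, paste(b$chunks, collapse = ""),
                            entities, relations)
  attr(doc, "timeline") <- list(
    dob = 0,
    dob_date = format(dob_date, "%Y-%m-%d"),
    visits = c(past_visits, v_day),
    current_visit = v_day,
    entity_spans = b$spans)
  doc
}

#' Generate a seeded synthetic annotated corpus
#'
#' Produces `config$n_docs` French-flavored annotated reports. Each
#' document's gold relation labels equal [label_relation()] applied to the
#' latent spans (enforced at generation time); entity offsets are valid by
#' construction; the same seed yields a byte-identical corpus. The latent
#' timeline of each document (day axis spans of every entity) is attached as
#' the `"timeline"` attribute and serialized as a JSON sidecar by
#' [write_corpus()].
#'
#' @param config A [generation_config()].
#' @return A named list of `annotated_document`s.
#' @examples
#' corp <- generate_corpus(generation_config(n_docs = 2, seed = 42,
#'                                           mean_phenotypes_per_doc = 4))
#' corp[[1]]
#' @export
generate_corpus <- function(config = generation_config()) {
  stopifnot(inherits(config, "generation_config"))
  if (config$n_docs == 0L) return(stats::setNames(list(), character(0)))
  with_preserved_rng({
    set.seed(config$seed, kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    docs <- lapply(seq_len(config$n_docs), function(i) {
      generate_document(sprintf("doc%03d", i), config)
    })
    stats::setNames(docs, vapply(docs, function(d) d$doc_id, character(1)))
  })
}

# --- timeline sidecar (JSON) ----------------------------------------------

encode_bound <- function(x) {
  if (is.infinite(x)) {
    if (x > 0) "unbounded-right" else "unbounded-left"
  } else {
    x
  }
}

decode_bound <- function(x) {
  if (identical(x, "unbounded-right")) return(Inf)
  if (identical(x, "unbounded-left")) return(-Inf)
  as.numeric(x)
}

encode_timeline <- function(tl) {
  tl$entity_spans <- lapply(tl$entity_spans, function(s) {
    list(start = encode_bound(s[1]), end = encode_bound(s[2]))
  })
  tl
}

decode_timeline <- function(tl) {
  tl$visits <- as.numeric(unlist(tl$visits))
  tl$entity_spans <- lapply(tl$entity_spans, function(s) {
    c(decode_bound(s$start), decode_bound(s$end))
  })
  tl
}
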