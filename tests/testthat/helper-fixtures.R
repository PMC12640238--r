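# Shared fixtures, built in code. Corpora are cached per session since
# several files exercise the same seeded worlds.

.fixture_cache <- new.env(parent = emptyenv())

fixture_corpus <- function(n_docs, seed, mean = 28) {
  key <- sprintf("corpus_%d_%d_%s", n_docs, seed, mean)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_corpus(generation_config(
      n_docs = n_docs, seed = seed, mean_phenotypes_per_doc = mean))
  }
  .fixture_cache[[key]]
}

fixture_bank <- function() {
  if (is.null(.fixture_cache$bank)) {
    .fixture_cache$bank <- default_example_bank(seed = 2020L)
  }
  .fixture_cache$bank
}

# compact document builder: ents as list(id = c(etype, start, end)),
# rels as list(id = c(rtype, source, target))
make_doc <- function(text, ents = list(), rels = list(), doc_id = "t") {
  e <- if (length(ents)) {
    do.call(rbind, lapply(names(ents), function(id) {
      v <- ents[[id]]
      s <- as.integer(v[2]); en <- as.integer(v[3])
      data.frame(id = id, etype = v[1], start = s, end = en,
                 surface = substring(text, s + 1L, en),
                 stringsAsFactors = FALSE)
    }))
  } else {
    NULL
  }
  r <- if (length(rels)) {
    do.call(rbind, lapply(names(rels), function(id) {
      v <- rels[[id]]
      data.frame(id = id, rtype = v[1], source = v[2], target = v[3],
                 stringsAsFactors = FALSE)
    }))
  } else {
    NULL
  }
  annotated_document(doc_id, text,
                     if (is.null(e)) ptrex:::empty_entities() else e,
                     if (is.null(r)) ptrex:::empty_relations() else r)
}

expect_doc_equal <- function(a, b) {
  expect_identical(a$doc_id, b$doc_id)
  expect_identical(a$text, b$text)
  expect_identical(a$entities, b$entities)
  expect_identical(a$relations, b$relations)
}

# gold relation triples of a corpus, one data frame
corpus_relations <- function(corpus) {
  do.call(rbind, c(lapply(corpus, function(d) {
    if (!nrow(d$relations)) return(NULL)
    cbind(doc_id = d$doc_id, d$relations[, c("source", "target", "rtype")],
          stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
}

# backend answering with a fixed string for every request
constant_backend <- function(text) mock_backend(function(req) text)

# all permutations of a short vector (brute-force invariance checks)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
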