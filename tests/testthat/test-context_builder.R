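# a document whose offsets we control: n filler tokens, a phenotype, a gap,
# a date entity
filler_doc <- function(n_before = 20, gap = 3, n_after = 5) {
  words <- c(rep("mot", n_before), "fièvre", rep("puis", gap),
             "01/02/2021", rep("fin", n_after))
  text <- paste(words, collapse = " ")
  ps <- as.integer(regexpr("fièvre", text)) - 1L
  ds <- as.integer(regexpr("01/02/2021", text)) - 1L
  make_doc(text,
           list(T1 = c("Phenotype", ps, ps + 6L),
                T2 = c("DOV", ds, ds + 10L)),
           list(R1 = c("BEGINS-AT", "T2", "T1")))
}

tokens_before_marker <- function(snippet, marker = "<phenotype>") {
  before <- strsplit(snippet, marker, fixed = TRUE)[[1]][1]
  length(strsplit(trimws(before), "\\s+")[[1]])
}

strip_markers <- function(x) {
  gsub("</?phenotype>|<time type=\"[A-Za-z]+\">|</time>", "", x)
}

test_that("pair enumeration is the temporal x phenotype cartesian product", {
  text <- "aa bb cc dd ee ff"
  doc <- make_doc(text, list(T1 = c("DOV", 0, 2), T2 = c("Age", 3, 5),
                             T3 = c("Phenotype", 6, 8),
                             T4 = c("Phenotype", 9, 11),
                             T5 = c("Phenotype", 12, 14)))
  pairs <- enumerate_pairs(doc, snippets = FALSE)
  expect_equal(nrow(pairs), 6L)
  expect_setequal(unique(pairs$source), c("T1", "T2"))
  expect_true(all(pairs$gold == "NONE"))

  no_phen <- make_doc(text, list(T1 = c("DOV", 0, 2)))
  expect_equal(nrow(enumerate_pairs(no_phen)), 0L)
})

test_that("gold-labeled instances reproduce the document relation set", {
  corpus <- fixture_corpus(10, seed = 8, mean = 5)
  for (doc in corpus) {
    pairs <- enumerate_pairs(doc, snippets = FALSE)
    got <- pairs[pairs$gold != "NONE",
                 c("source", "target", "gold")]
    want <- doc$relations[, c("source", "target", "rtype")]
    names(want)[3] <- "gold"
    key <- function(d) sort(paste(d$source, d$target, d$gold))
    expect_identical(key(got), key(want))
    expect_equal(nrow(pairs),
                 sum(doc$entities$etype != "Phenotype") *
                   sum(doc$entities$etype == "Phenotype"))
  }
})

test_that("exactly `window` tokens precede the phenotype marker when context is longer", {
  doc <- filler_doc(n_before = 1500, gap = 3)
  snip <- extract_context(doc, "T2", "T1", window = 1000)
  expect_equal(tokens_before_marker(snip), 1000L)
  # and snippets carry exactly one marker pair per entity
  expect_true(ptrex:::marker_integrity_ok(snip))
})

test_that("a phenotype at document start has no preceding tokens and no padding", {
  doc <- filler_doc(n_before = 0, gap = 2)
  snip <- extract_context(doc, "T2", "T1", window = 1000)
  expect_equal(tokens_before_marker(snip), 0L)
  expect_true(startsWith(snip, "<phenotype>"))
})

test_that("overlapping windows merge into one contiguous snippet", {
  doc <- filler_doc(n_before = 40, gap = 10, n_after = 40)
  snip <- extract_context(doc, "T2", "T1", window = 1000)
  expect_false(grepl("[...]", snip, fixed = TRUE))
  expect_true(ptrex:::marker_integrity_ok(snip))
  # marker integrity: stripping markers yields a contiguous substring
  expect_true(grepl(strip_markers(snip), doc$text, fixed = TRUE))
})

test_that("disjoint windows are joined with an ellipsis, each side contiguous", {
  doc <- filler_doc(n_before = 5, gap = 60, n_after = 5)
  snip <- extract_context(doc, "T2", "T1", window = 4)
  expect_true(grepl("[...]", snip, fixed = TRUE))
  for (seg in strsplit(snip, "\n[...]\n", fixed = TRUE)[[1]]) {
    expect_true(grepl(strip_markers(seg), doc$text, fixed = TRUE))
  }
})

test_that("enlarging the window never shrinks the snippet", {
  doc <- filler_doc(n_before = 200, gap = 30, n_after = 200)
  sizes <- vapply(c(1, 5, 20, 80, 500), function(w) {
    nchar(extract_context(doc, "T2", "T1", window = w))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("unknown entities and bad windows are rejected", {
  doc <- filler_doc()
  expect_error(extract_context(doc, "T9", "T1"), "not found")
  expect_error(extract_context(doc, "T2", "T2"), "must be a Phenotype")
  expect_error(extract_context(doc, "T2", "T1", window = 0), "window")
})

test_that("the pairing distance restricts candidates", {
  doc <- filler_doc(n_before = 5, gap = 100, n_after = 5)
  expect_equal(nrow(enumerate_pairs(doc, snippets = FALSE)), 1L)
  expect_equal(nrow(enumerate_pairs(doc, snippets = FALSE,
                                    max_token_distance = 10)), 0L)
})
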