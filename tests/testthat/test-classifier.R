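one_instance <- function(gold = "BEGINS-AT") {
  list(snippet = paste0(
    "Apparition d'une <phenotype>fièvre</phenotype> lors de la ",
    "consultation du <time type=\"DOV\">01/02/2021</time>."),
    gold = gold)
}

test_that("single-instance classification is an identity map under the oracle", {
  bank <- fixture_bank()
  be <- oracle_backend()
  for (g in all_labels()) {
    expect_identical(classify_multiclass(one_instance(g), bank, be), g)
    expect_identical(
      classify_instance(one_instance(g), "binary", bank, be), g)
  }
  # unparseable model output falls back to NONE
  expect_identical(
    classify_multiclass(one_instance(), bank, constant_backend("euh...")),
    "NONE")
})

test_that("binary decomposition returns the positively answered subset", {
  bank <- fixture_bank()
  expect_identical(
    classify_binary_all(one_instance("OVERLAP"), bank, oracle_backend()),
    "OVERLAP")
  expect_identical(
    classify_binary_all(one_instance(), bank, constant_backend("NONE")),
    character(0))
  forced <- mock_backend(function(req) {
    if (req$meta$relation %in% c("BEFORE", "BEFORE-OVERLAP")) {
      req$meta$relation
    } else {
      "NONE"
    }
  })
  expect_setequal(classify_binary_all(one_instance(), bank, forced),
                  c("BEFORE", "BEFORE-OVERLAP"))
})

test_that("a failing backend sub-call counts as negative with a warning", {
  flaky <- mock_backend(function(req) {
    if (req$meta$relation == "CONTAINS") stop("boom")
    if (identical(req$meta$relation, req$meta$gold)) req$meta$relation
    else "NONE"
  })
  expect_warning(
    got <- classify_binary_all(one_instance("CONTAINS"), fixture_bank(),
                               flaky),
    "counted negative")
  expect_identical(got, character(0))
})

test_that("conflicts resolve to the rarest relation, tie-broken by schema order", {
  counts <- published_relation_totals()
  expect_identical(resolve_conflict(c("BEGINS-AT", "SIMULTANEOUS"), counts),
                   "SIMULTANEOUS")
  expect_identical(resolve_conflict(character(0), counts), "NONE")
  expect_identical(resolve_conflict("OVERLAP", counts), "OVERLAP")
  # schema order puts OVERLAP before BEFORE, so a 10/10 tie picks OVERLAP
  tied <- training_counts(stats::setNames(rep(10, 7), relation_types()))
  expect_identical(resolve_conflict(c("BEFORE", "OVERLAP"), tied),
                   "OVERLAP")
  expect_identical(resolve_conflict(c("OVERLAP", "BEFORE"), tied),
                   "OVERLAP")
  expect_error(resolve_conflict("AFTER", counts), "outside")
})

test_that("conflict resolution is permutation-invariant (brute force)", {
  withr::local_seed(7)
  for (k in 2:4) {
    for (trial in 1:10) {
      labels <- sample(relation_types(), k)
      counts <- training_counts(stats::setNames(
        sample(0:20, 7, replace = TRUE), relation_types()))
      results <- vapply(perms(labels), resolve_conflict, character(1),
                        counts = counts)
      expect_length(unique(results), 1L)
      expect_true(results[1] %in% labels)
      expect_equal(unname(counts[results[1]]), min(counts[labels]))
    }
  }
})

test_that("binary issues exactly 7 backend calls per pair, multiclass 1", {
  bank <- fixture_bank()
  be <- oracle_backend()
  invisible(classify_multiclass(one_instance(), bank, be))
  expect_equal(backend_calls(be), 1L)
  reset_backend_calls(be)
  invisible(classify_instance(one_instance(), "binary", bank, be))
  expect_equal(backend_calls(be), 7L)
  reset_backend_calls(be)
  invisible(classify_instance(one_instance(), "zeroshot", bank, be))
  expect_equal(backend_calls(be), 7L)
})

test_that("oracle-backed regimes reproduce gold over a corpus and agree", {
  corpus <- fixture_corpus(10, seed = 8, mean = 5)
  instances <- enumerate_corpus_pairs(corpus)
  bank <- fixture_bank()
  mc <- classify_corpus(instances, "multiclass", bank, oracle_backend())
  bin <- classify_corpus(instances, "binary", bank, oracle_backend())
  expect_identical(mc$pred, instances$gold)
  expect_identical(bin$pred, instances$gold)
  expect_identical(mc$pred, bin$pred)
  expect_identical(sort(table(mc$pred)), sort(table(instances$gold)))
})

test_that("training counts validate and derive from corpora", {
  expect_error(training_counts(c(a = 1)), "all 7 relation types")
  expect_error(
    training_counts(stats::setNames(c(-1, rep(1, 6)), relation_types())),
    "non-negative")
  corpus <- fixture_corpus(10, seed = 8, mean = 5)
  counts <- counts_from_corpus(corpus)
  expect_s3_class(counts, "training_counts")
  expect_equal(sum(counts),
               sum(vapply(corpus, function(d) nrow(d$relations), 1L)))
})
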