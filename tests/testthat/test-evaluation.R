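instances_df <- function(labels, prefix = "d1") {
  data.frame(doc_id = prefix, source = paste0("S", seq_along(labels)),
             target = paste0("P", seq_along(labels)), label = labels,
             stringsAsFactors = FALSE)
}

test_that("perfect predictions give F1 = 1 for every supported label", {
  gold <- instances_df(c("BEGINS-AT", "BEGINS-AT", "BEFORE", "NONE",
                         "SIMULTANEOUS"))
  rep <- score_relations(gold, gold)
  sup <- rep$per_relation[rep$per_relation$support > 0, ]
  expect_true(all(sup$f1 == 1))
  expect_equal(rep$micro_f1, 1)
  expect_equal(rep$n_instances, 5L)
})

test_that("the hand-computed contingency gives P = 0.6, R = 0.75, F1 ~ 0.667", {
  gold <- instances_df(c(rep("BEGINS-AT", 4), rep("NONE", 3)))
  pred <- gold
  pred$label <- c("BEGINS-AT", "BEGINS-AT", "BEGINS-AT", "NONE",
                  "BEGINS-AT", "BEGINS-AT", "NONE")
  rep <- score_relations(pred, gold)
  row <- rep$per_relation[rep$per_relation$relation == "BEGINS-AT", ]
  expect_equal(row$precision, 0.6)
  expect_equal(row$recall, 0.75)
  expect_equal(row$f1, 2 * (0.6 * 0.75) / (0.6 + 0.75), tolerance = 1e-12)
})

test_that("zero-support, zero-prediction labels score 0 with the undefined flag", {
  gold <- instances_df(c("BEGINS-AT", "NONE"))
  rep <- score_relations(gold, gold)
  row <- rep$per_relation[rep$per_relation$relation == "SIMULTANEOUS", ]
  expect_equal(row$f1, 0)
  expect_true(row$undefined)
  expect_false(rep$per_relation$undefined[
    rep$per_relation$relation == "BEGINS-AT"])
})

test_that("mismatched or duplicated instance sets are refused", {
  gold <- instances_df(c("BEGINS-AT", "BEFORE"))
  other <- gold
  other$target <- c("P1", "P9")
  expect_error(score_relations(other, gold), "different instance sets")
  expect_error(score_relations(rbind(gold, gold), rbind(gold, gold)),
               "duplicated")
})

test_that("scoring is order-independent and macro is permutation-invariant", {
  withr::local_seed(42)
  labels <- sample(all_labels(), 60, replace = TRUE)
  gold <- instances_df(labels)
  pred <- gold
  pred$label <- sample(all_labels(), 60, replace = TRUE)
  base <- score_relations(pred, gold)
  shuffled <- pred[sample(nrow(pred)), ]
  expect_equal(score_relations(shuffled, gold), base)

  # relabel both gold and predictions by a fixed permutation of the 7 types
  perm <- stats::setNames(c(sample(relation_types()), "NONE"), all_labels())
  gold2 <- gold; gold2$label <- unname(perm[gold$label])
  pred2 <- pred; pred2$label <- unname(perm[pred$label])
  expect_equal(score_relations(pred2, gold2)$macro_f1, base$macro_f1)
})

test_that("micro-F1 equals accuracy when predictions stay within the 7 types", {
  withr::local_seed(1)
  labels <- sample(relation_types(), 80, replace = TRUE)
  gold <- instances_df(labels)
  pred <- gold
  pred$label <- sample(relation_types(), 80, replace = TRUE)
  rep <- score_relations(pred, gold)
  expect_equal(rep$micro_f1, mean(pred$label == gold$label))
})

test_that("identical annotation sets have IAA 1 and the hand case gives 16/19", {
  ann <- instances_df(rep("OVERLAP", 10))
  names(ann)[4] <- "rtype"
  expect_equal(as.numeric(iaa(ann, ann)), 1)

  b <- ann[1:8, ]                       # misses 2
  b <- rbind(b, data.frame(doc_id = "d1", source = "S99", target = "P99",
                           rtype = "OVERLAP"))  # adds 1 spurious
  expect_equal(as.numeric(iaa(ann, b)), 16 / 19, tolerance = 1e-12)
})

test_that("IAA is symmetric over 100 seeded random annotation pairs", {
  withr::local_seed(2024)
  pool <- corpus_relations(fixture_corpus(10, seed = 8, mean = 5))
  for (trial in 1:100) {
    na <- sample(5:nrow(pool), 1)
    nb <- sample(5:nrow(pool), 1)
    a <- pool[sample(nrow(pool), na), ]
    b <- pool[sample(nrow(pool), nb), ]
    expect_equal(as.numeric(iaa(a, b)), as.numeric(iaa(b, a)),
                 tolerance = 1e-12)
  }
})

test_that("disjoint document sets are refused", {
  a <- instances_df("OVERLAP", prefix = "docA")
  names(a)[4] <- "rtype"
  b <- instances_df("OVERLAP", prefix = "docB")
  names(b)[4] <- "rtype"
  expect_error(iaa(a, b), "disjoint")
})

test_that("the metric table prints one row per report", {
  gold <- instances_df(c("BEGINS-AT", "BEFORE", "NONE"))
  rep <- score_relations(gold, gold)
  lines <- format_metric_table(list(oracle = rep, again = rep))
  expect_length(lines, 3L)
  expect_match(lines[1], "BEGINS-AT")
  expect_match(lines[2], "^oracle")
})
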