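# Per-pair classification under the three regimes.
#
# Multi-class: one prompt, one backend call, 8-way answer. Binary (and
# zero-shot): 7 independent yes/no prompts, one per relation type, then
# rarity-based conflict resolution — of several positive answers keep the
# relation with the smallest training sample count, on the assumption that
# rare types are less likely to be predicted spuriously.

#' Training sample counts per relation type
#'
#' Validates a named count vector over the 7 relation types, the rarity
#' prior of [resolve_conflict()]. Defaults come from the example bank's
#' source corpus ([counts_from_corpus()]); the published totals of the
#' original annotated corpus ([published_relation_totals()]) are the
#' documented alternative.
#'
#' @param counts Named non-negative numeric vector covering all 7 types.
#' @return Named numeric vector in schema order, class `training_counts`.
#' @export
training_counts <- function(counts) {
  if (inherits(counts, "training_counts")) return(counts)
  if (is.null(names(counts)) || !setequal(names(counts), RELATION_TYPES)) {
    stop("counts must be named with all 7 relation types", call. = FALSE)
  }
  counts <- as.numeric(counts[RELATION_TYPES])
  if (any(is.na(counts) | counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(stats::setNames(counts, RELATION_TYPES),
            class = "training_counts")
}

#' Per-relation annotation counts of a corpus
#'
#' @param corpus List of `annotated_document`s.
#' @return A [training_counts()] vector.
#' @export
counts_from_corpus <- function(corpus) {
  rt <- unlist(lapply(corpus, function(d) d$relations$rtype),
               use.names = FALSE)
  tab <- table(factor(rt, levels = RELATION_TYPES))
  training_counts(stats::setNames(as.numeric(tab), names(tab)))
}

#' Classify one candidate pair with the multi-class regime
#'
#' Builds the 14-example multi-class prompt, runs one backend call and
#' parses the answer against the 8-label vocabulary.
#'
#' @param instance Candidate-pair row from [enumerate_pairs()].
#' @param bank An [example_bank()].
#' @param backend A backend (see [complete()]).
#' @return A single label from [all_labels()].
#' @export
classify_multiclass <- function(instance, bank, backend) {
  spec <- build_multiclass_prompt(bank, instance)
  raw <- complete(backend, completion_request(
    render_prompt(spec), meta = list(gold = instance_gold(instance))))
  parse_answer(raw, all_labels())$label
}

#' Run all 7 binary classifiers on one candidate pair
#'
#' One independent yes/no prompt per relation type; returns the subset
#' answered positively (in schema order). A failed backend sub-call counts
#' as a negative answer with a warning.
#'
#' @inheritParams classify_multiclass
#' @param zeroshot Use the zero-shot prompt (no examples) instead of the
#'   3-positive/3-NONE few-shot prompt.
#' @return Character vector of positively answered relation types.
#' @export
classify_binary_all <- function(instance, bank, backend,
                                zeroshot = FALSE) {
  gold <- instance_gold(instance)
  positives <- character(0)
  for (r in relation_types()) {
    spec <- if (zeroshot) {
      build_zeroshot_prompt(r, instance)
    } else {
      build_binary_prompt(bank, r, instance)
    }
    raw <- tryCatch(
      complete(backend, completion_request(
        render_prompt(spec), meta = list(gold = gold, relation = r))),
      error = function(e) {
        warning("backend sub-call failed for ", r, " (counted negative): ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(raw) &&
        parse_answer(raw, c(r, NONE_LABEL))$label == r) {
      positives <- c(positives, r)
    }
  }
  positives
}

#' Resolve conflicting binary positives by training-sample rarity
#'
#' Empty set maps to NONE; a singleton to its member; otherwise the member
#' with the smallest training count wins, ties broken deterministically by
#' schema order ([relation_types()]). Permutation-invariant in the input
#' set.
#'
#' @param positives Character vector of positively answered relation types.
#' @param counts A [training_counts()] vector (or coercible).
#' @return A single label.
#' @examples
#' resolve_conflict(c("BEGINS-AT", "SIMULTANEOUS"),
#'                  published_relation_totals())  # "SIMULTANEOUS"
#' @export
resolve_conflict <- function(positives, counts) {
  positives <- unique(positives)
  if (!length(positives)) return(NONE_LABEL)
  if (!all(positives %in% RELATION_TYPES)) {
    stop("positives outside the relation vocabulary: ",
         paste(setdiff(positives, RELATION_TYPES), collapse = ", "),
         call. = FALSE)
  }
  positives <- intersect(RELATION_TYPES, positives)  # canonical order
  if (length(positives) == 1L) return(positives)
  counts <- training_counts(counts)
  positives[which.min(counts[positives])]
}

#' Classify one candidate pair under a chosen regime
#'
#' @inheritParams classify_multiclass
#' @param regime `"multiclass"`, `"binary"` or `"zeroshot"`.
#' @param counts Rarity prior for conflict resolution (binary/zero-shot);
#'   defaults to the bank's `source_counts`, falling back to the published
#'   totals.
#' @return A single label.
#' @export
classify_instance <- function(instance,
                              regime = c("multiclass", "binary",
                                         "zeroshot"),
                              bank = NULL, backend, counts = NULL) {
  regime <- match.arg(regime)
  if (regime == "multiclass") {
    return(classify_multiclass(instance, bank, backend))
  }
  counts <- counts %||% bank$source_counts %||%
    published_relation_totals()
  positives <- classify_binary_all(instance, bank, backend,
                                   zeroshot = regime == "zeroshot")
  resolve_conflict(positives, counts)
}

#' Classify every candidate pair of an instance table
#'
#' @param instances Data frame from [enumerate_pairs()] /
#'   [enumerate_corpus_pairs()].
#' @inheritParams classify_instance
#' @return `instances` with a `pred` column appended.
#' @export
classify_corpus <- function(instances,
                            regime = c("multiclass", "binary", "zeroshot"),
                            bank = NULL, backend, counts = NULL) {
  regime <- match.arg(regime)
  if (regime != "multiclass") {
    counts <- training_counts(counts %||% bank$source_counts %||%
                                published_relation_totals())
  }
  pred <- character(nrow(instances))
  for (i in seq_len(nrow(instances))) {
    inst <- list(snippet = instances$snippet[i], gold = instances$gold[i])
    pred[i] <- classify_instance(inst, regime, bank, backend, counts)
  }
  instances$pred <- pred
  instances
}
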