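# Scoring predictions against gold per relation type, plus pairwise
# inter-annotator agreement as average F1 over relation types.
#
# Matching is exact on (source entity, target entity, label): entities are
# shared givens in this pipeline, so there is no partial-span credit. The
# zero-support convention is F1 := 0 with an explicit `undefined` flag
# (never dropped), so macro averages are reproducible.

f1_of <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

#' Score predictions against gold labels
#'
#' Computes per-relation precision/recall/F1 over (source, target, label)
#' triples on a shared instance set, the 8x8 confusion tally (NONE
#' included), and macro, support-weighted and micro aggregates (NONE
#' excluded from all per-relation rows and aggregates).
#'
#' @param predictions,gold Data frames with columns `doc_id`, `source`,
#'   `target`, `label` (or `pred`/`gold` respectively, as produced by
#'   [classify_corpus()] and [enumerate_pairs()]), covering the same
#'   instance set.
#' @return A `metric_report`: list with `per_relation` (data frame),
#'   `macro_f1`, `weighted_f1`, `micro_f1`, `confusion`, `n_instances`.
#' @export
score_relations <- function(predictions, gold) {
  predictions <- as.data.frame(predictions, stringsAsFactors = FALSE)
  gold <- as.data.frame(gold, stringsAsFactors = FALSE)
  if (is.null(predictions$label)) predictions$label <- predictions$pred
  if (is.null(gold$label)) gold$label <- gold$gold
  for (d in list(predictions, gold)) {
    stopifnot(all(c("doc_id", "source", "target") %in% names(d)))
  }
  kp <- paste(predictions$doc_id, predictions$source, predictions$target,
              sep = "\r")
  kg <- paste(gold$doc_id, gold$source, gold$target, sep = "\r")
  if (anyDuplicated(kp) || anyDuplicated(kg)) {
    stop("duplicated instances in predictions or gold", call. = FALSE)
  }
  if (length(kp) != length(kg) || !setequal(kp, kg)) {
    stop("predictions and gold cover different instance sets",
         call. = FALSE)
  }
  p <- factor(predictions$label[match(kg, kp)], levels = all_labels())
  g <- factor(gold$label, levels = all_labels())
  if (anyNA(p) || anyNA(g)) {
    stop("labels outside the 8-label vocabulary", call. = FALSE)
  }
  conf <- table(gold = g, predicted = p)

  rel <- RELATION_TYPES
  tp <- diag(conf[rel, rel, drop = FALSE])
  n_pred <- colSums(conf)[rel]
  support <- rowSums(conf)[rel]
  precision <- ifelse(n_pred > 0, tp / n_pred, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- mapply(f1_of, precision, recall)
  per <- data.frame(relation = rel, precision = unname(precision),
                    recall = unname(recall), f1 = unname(f1),
                    support = as.integer(unname(support)),
                    n_predicted = as.integer(unname(n_pred)),
                    undefined = unname(support == 0 & n_pred == 0),
                    stringsAsFactors = FALSE)
  micro_p <- if (sum(n_pred) > 0) sum(tp) / sum(n_pred) else 0
  micro_r <- if (sum(support) > 0) sum(tp) / sum(support) else 0
  structure(list(
    per_relation = per,
    macro_f1 = mean(per$f1),
    weighted_f1 = if (sum(per$support) > 0) {
      sum(per$f1 * per$support) / sum(per$support)
    } else {
      NA_real_
    },
    micro_f1 = f1_of(micro_p, micro_r),
    confusion = conf,
    n_instances = length(kg)), class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat(format_metric_table(x, digits = digits), sep = "\n")
  invisible(x)
}

#' Plain-text metric table
#'
#' Renders one or several `metric_report`s as a fixed-width table, one row
#' of per-relation F1 values per report (relation types as columns), the
#' layout commonly used to compare models.
#'
#' @param reports A `metric_report` or a named list of them.
#' @param digits Decimal places.
#' @return Character vector of table lines.
#' @export
format_metric_table <- function(reports, digits = 3) {
  if (inherits(reports, "metric_report")) {
    reports <- list(model = reports)
  }
  header <- c("Model", RELATION_TYPES, "macro", "micro")
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    c(nm, sprintf(paste0("%.", digits, "f"),
                  c(r$per_relation$f1, r$macro_f1, r$micro_f1)))
  })
  m <- rbind(header, do.call(rbind, rows))
  widths <- apply(nchar(m), 2, max)
  apply(m, 1, function(row) {
    paste(mapply(formatC, row, width = widths, flag = "-"),
          collapse = "  ")
  })
}

relation_triples <- function(ann) {
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  if (is.null(ann$rtype)) ann$rtype <- ann$label
  stopifnot(all(c("doc_id", "source", "target", "rtype") %in% names(ann)))
  ann
}

#' Pairwise inter-annotator agreement as average F1
#'
#' Treats one annotation set as reference, scores the other on exact
#' (source, target, type) triples per relation type, and averages F1 over
#' the types present in either set. Symmetric by construction of F1.
#'
#' @param annotations_a,annotations_b Data frames of relation triples
#'   (`doc_id`, `source`, `target`, `rtype`) from the same documents, e.g.
#'   `doc$relations` augmented with `doc_id`.
#' @return The average-F1 agreement (single number in `[0, 1]`), with the
#'   per-type breakdown attached as attribute `"per_type"`.
#' @export
iaa <- function(annotations_a, annotations_b) {
  a <- relation_triples(annotations_a)
  b <- relation_triples(annotations_b)
  if (!length(intersect(unique(a$doc_id), unique(b$doc_id))) &&
      (nrow(a) || nrow(b))) {
    stop("annotation sets cover disjoint document sets", call. = FALSE)
  }
  types <- union(unique(a$rtype), unique(b$rtype))
  if (!length(types)) return(structure(1, per_type = numeric(0)))
  key <- function(d) paste(d$doc_id, d$source, d$target, d$rtype,
                           sep = "\r")
  per <- vapply(types, function(t) {
    ka <- key(a[a$rtype == t, ])
    kb <- key(b[b$rtype == t, ])
    tp <- length(intersect(ka, kb))
    p <- if (length(kb)) tp / length(kb) else 0
    r <- if (length(ka)) tp / length(ka) else 0
    f1_of(p, r)
  }, numeric(1))
  structure(mean(per), per_type = per)
}
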