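# Interval semantics of the relation schema.
#
# Phenotype episodes and time expressions are modeled as closed integer-day
# intervals [start, end]; a time *point* is a span with start == end.
# Unbounded ends are allowed (-Inf / Inf), e.g. an ongoing (chronic)
# phenotype has end = Inf. The labeling function applies the relation
# definitions in a fixed precedence order, most specific first:
#   SIMULTANEOUS > BEGINS-AT > ENDS-AT > CONTAINS > BEFORE-OVERLAP >
#   BEFORE > OVERLAP > NONE
# OVERLAP is residual by definition ("some common time span but no other
# information"); NONE is returned only when the spans are disjoint with the
# phenotype strictly after the time expression.

#' Create a time span
#'
#' A span is a closed interval on an abstract integer day axis. Use `-Inf`
#' for an unbounded left end and `Inf` for an unbounded right end (an
#' ongoing condition). A time point is a span with `start == end`.
#'
#' @param start,end Numeric day indices (may be `-Inf`/`Inf`).
#' @return An object of class `time_span`.
#' @examples
#' span(3, 8)        # an episode lasting from day 3 to day 8
#' span(5, 5)        # a time point
#' span(0, Inf)      # present since birth and ongoing
#' @export
span <- function(start, end) {
  if (length(start) != 1L || length(end) != 1L ||
      is.na(start) || is.na(end)) {
    stop("span bounds must be single non-missing numbers", call. = FALSE)
  }
  if (start > end) stop("invalid span: start > end", call. = FALSE)
  if (is.infinite(start) && start > 0) {
    stop("invalid span: start is +Inf", call. = FALSE)
  }
  if (is.infinite(end) && end < 0) {
    stop("invalid span: end is -Inf", call. = FALSE)
  }
  structure(list(start = as.numeric(start), end = as.numeric(end)),
            class = "time_span")
}

#' @export
print.time_span <- function(x, ...) {
  cat(sprintf("[%s, %s]\n", format(x$start), format(x$end)))
  invisible(x)
}

as_span <- function(x) {
  if (inherits(x, "time_span")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(span(x[1], x[2]))
  stop("not a span: supply span() or a length-2 numeric", call. = FALSE)
}

#' Label the temporal relation between a phenotype and a time expression
#'
#' Deterministic labeling function over a phenotype interval and a
#' time-expression span. Exactly one label is returned for every valid pair
#' (totality), chosen by precedence from most to least specific:
#' SIMULTANEOUS, BEGINS-AT, ENDS-AT, CONTAINS, BEFORE-OVERLAP, BEFORE,
#' OVERLAP, with NONE reserved for disjoint spans where the phenotype lies
#' strictly after the time expression.
#'
#' @param phenotype,timeexp [span()] objects (or length-2 numerics).
#' @return A single label string, one of [all_labels()].
#' @examples
#' label_relation(span(3, 8), span(3, 3))   # "BEGINS-AT"
#' label_relation(span(1, 3), span(5, 5))   # "BEFORE"
#' label_relation(span(4, 6), span(2, 9))   # "CONTAINS"
#' label_relation(span(1, 7), span(4, 9))   # "BEFORE-OVERLAP"
#' @export
label_relation <- function(phenotype, timeexp) {
  p <- as_span(phenotype)
  t <- as_span(timeexp)
  ps <- p$start; pe <- p$end
  ts <- t$start; te <- t$end
  if (ps == ts && pe == te) return("SIMULTANEOUS")
  if (ps == ts) return("BEGINS-AT")
  if (pe == te) return("ENDS-AT")
  if (ts <= ps && pe <= te) return("CONTAINS")
  if (ps < ts && pe >= ts) return("BEFORE-OVERLAP")
  if (pe < ts) return("BEFORE")
  if (ps <= te && pe >= ts) return("OVERLAP")
  NONE_LABEL
}
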