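# Independent brute-force re-implementation of the relation definitions,
# used as the enumeration oracle for label_relation(). Deliberately
# different mechanism: explicit integer day *sets* (with large sentinels
# standing in for unbounded ends), checked in the declared precedence
# order. Keep this free of any call into the package's labeling path.

bf_label <- function(p, t, sentinel = 1000) {
  clamp <- function(x) {
    x[x == Inf] <- sentinel
    x[x == -Inf] <- -sentinel
    x
  }
  p <- clamp(p); t <- clamp(t)
  P <- seq(p[1], p[2])
  T <- seq(t[1], t[2])
  if (length(P) == length(T) && all(P == T)) return("SIMULTANEOUS")
  if (min(P) == min(T)) return("BEGINS-AT")
  if (max(P) == max(T)) return("ENDS-AT")
  if (all(P %in% T)) return("CONTAINS")
  if (min(P) < min(T) && length(intersect(P, T)) > 0) {
    return("BEFORE-OVERLAP")
  }
  if (max(P) < min(T)) return("BEFORE")
  if (length(intersect(P, T)) > 0) return("OVERLAP")
  "NONE"
}

# all spans with bounds in lo..hi, optionally plus unbounded-right ends
all_spans <- function(lo, hi, unbounded_right = FALSE) {
  out <- list()
  for (s in lo:hi) {
    for (e in s:hi) out[[length(out) + 1L]] <- c(s, e)
    if (unbounded_right) out[[length(out) + 1L]] <- c(s, Inf)
  }
  out
}
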