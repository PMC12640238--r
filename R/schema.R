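# Closed vocabularies of the annotation schema. Order matters: the relation
# order below is the canonical "schema order" used for deterministic
# tie-breaking and for stable example ordering in prompts.

RELATION_TYPES <- c("BEGINS-AT", "ENDS-AT", "CONTAINS", "OVERLAP",
                    "BEFORE-OVERLAP", "BEFORE", "SIMULTANEOUS")
NONE_LABEL <- "NONE"
TEMPORAL_TYPES <- c("DOB", "DOR", "DOV", "DOPV", "DOFV", "DOTHER",
                    "Age", "Duration", "Frequency", "Time")
# Date-like entities denote a single time point; the others may denote spans.
POINT_TYPES <- c("DOB", "DOR", "DOV", "DOPV", "DOFV", "DOTHER")
SPAN_TYPES <- c("Age", "Duration", "Frequency", "Time")

#' Relation-type vocabulary
#'
#' The seven temporal relation types linking a time expression to a phenotype,
#' in canonical schema order. This order is the deterministic tie-break used
#' by [resolve_conflict()] and the example ordering used by the prompt
#' builders.
#'
#' @return Character vector of the 7 relation labels.
#' @export
relation_types <- function() RELATION_TYPES

#' All answer labels (relation types plus NONE)
#'
#' @return Character vector of the 8 labels a classifier may emit.
#' @export
all_labels <- function() c(RELATION_TYPES, NONE_LABEL)

#' Entity-type vocabulary
#'
#' `entity_types()` returns the full closed vocabulary (Phenotype plus the 10
#' temporal entity types); `temporal_entity_types()` only the temporal ones:
#' date of birth (DOB), date of report (DOR), date of visit (DOV), date of
#' past visit (DOPV), date of future visit (DOFV), other dates (DOTHER), Age,
#' Duration, Frequency and Time.
#'
#' @return Character vector of entity type names.
#' @export
entity_types <- function() c("Phenotype", TEMPORAL_TYPES)

#' @rdname entity_types
#' @export
temporal_entity_types <- function() TEMPORAL_TYPES

# French definitions of the relation semantics, used verbatim in every prompt
# regime so that instructions stay identical across regimes.
RELATION_DEFINITIONS <- c(
  "BEGINS-AT" = paste0(
    "le phénotype débute au point temporel désigné ",
    "par l'expression de temps."),
  "ENDS-AT" = paste0(
    "le phénotype se termine au point temporel désigné ",
    "par l'expression de temps."),
  "CONTAINS" = paste0(
    "la période désignée par l'expression de temps couvre ",
    "à la fois le début et la fin du phénotype."),
  "OVERLAP" = paste0(
    "le phénotype et l'expression de temps partagent une période ",
    "commune, sans autre information sur leurs bornes."),
  "BEFORE-OVERLAP" = paste0(
    "le phénotype débute avant l'expression de temps et se ",
    "poursuit pendant la période qu'elle désigne."),
  "BEFORE" = paste0(
    "le phénotype se termine avant le point temporel désigné ",
    "par l'expression de temps."),
  "SIMULTANEOUS" = paste0(
    "le phénotype et l'expression de temps couvrent exactement ",
    "la même période."),
  "NONE" = paste0(
    "aucune relation temporelle ne lie le phénotype ",
    "à l'expression de temps.")
)

#' Relation definitions used in prompts
#'
#' French one-line definitions of each relation label (and NONE), as embedded
#' in the prompt instruction blocks.
#'
#' @param rtype Optional label; if omitted all definitions are returned.
#' @return Named character vector (or a single string when `rtype` is given).
#' @export
relation_definition <- function(rtype = NULL) {
  if (is.null(rtype)) return(RELATION_DEFINITIONS)
  if (!rtype %in% names(RELATION_DEFINITIONS)) {
    stop("unknown relation type: ", rtype, call. = FALSE)
  }
  RELATION_DEFINITIONS[[rtype]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# package-local mutable state (prompt render cache, bank uid counter)
.ptrex_env <- new.env(parent = emptyenv())
.ptrex_env$bank_counter <- 0L
.ptrex_env$render_cache <- new.env(parent = emptyenv())
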