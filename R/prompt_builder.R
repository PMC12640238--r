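# Assembly of the three prompt regimes from an example bank.
#
# All regimes share one instruction skeleton (templates under
# inst/templates/, editable without code changes) and one markup dialect.
# The zero-shot prompt is exactly the binary prompt with its example blocks
# removed. Example ordering is deterministic: schema order across relation
# types, bank order within a type.

template_path <- function(name) {
  system.file("templates", paste0(name, ".txt"), package = "ptrex",
              mustWork = TRUE)
}

load_template <- function(name) {
  key <- paste0("template_", name)
  if (is.null(.ptrex_env[[key]])) {
    .ptrex_env[[key]] <- read_utf8(template_path(name))
  }
  .ptrex_env[[key]]
}

fill_template <- function(tpl, values) {
  for (nm in names(values)) {
    tpl <- gsub(paste0("{{", nm, "}}"), values[[nm]], tpl, fixed = TRUE)
  }
  tpl
}

definition_lines <- function(labels) {
  paste(sprintf("- %s : %s", labels, RELATION_DEFINITIONS[labels]),
        collapse = "\n")
}

example_block <- function(snippet, label) {
  sprintf("Texte : %s\nRelation : %s\n\n", snippet, label)
}

#' Render the example section of a prompt
#'
#' @param examples Data frame with `snippet` and `label` columns; zero rows
#'   render to the empty string (the zero-shot case).
#' @return A single string.
#' @export
render_examples <- function(examples) {
  if (!nrow(examples)) return("")
  paste0("### Exemples\n",
         paste(example_block(examples$snippet, examples$label),
               collapse = ""))
}

new_prompt_spec <- function(regime, relation, template, definitions, labels,
                            examples, query, bank_uid = NULL) {
  structure(list(regime = regime, relation = relation, template = template,
                 definitions = definitions, labels = labels,
                 examples = examples, query = query, bank_uid = bank_uid),
            class = "prompt_spec")
}

#' @export
print.prompt_spec <- function(x, ...) {
  cat(sprintf("<prompt_spec %s%s: %d example blocks>\n", x$regime,
              if (!is.na(x$relation)) paste0("/", x$relation) else "",
              nrow(x$examples)))
  invisible(x)
}

query_snippet <- function(instance) {
  snip <- if (is.data.frame(instance)) instance$snippet[1] else
    instance$snippet
  if (is.null(snip) || is.na(snip)) {
    stop("instance has no snippet; run enumerate_pairs()/extract_context()",
         call. = FALSE)
  }
  snip
}

instance_gold <- function(instance) {
  g <- if (is.data.frame(instance)) instance$gold[1] else instance$gold
  if (is.null(g)) NA_character_ else g
}

#' Build a multi-class few-shot prompt
#'
#' Two examples per relation type (14 blocks in total) embedded in the
#' shared instruction block; the instruction lists the 7 relation labels
#' plus NONE; the query snippet comes last.
#'
#' @param bank An [example_bank()] holding at least 2 examples per type.
#' @param instance A candidate-pair row from [enumerate_pairs()] (or any
#'   list with a `snippet`).
#' @return A `prompt_spec`.
#' @export
build_multiclass_prompt <- function(bank, instance) {
  stopifnot(inherits(bank, "example_bank"))
  ex <- do.call(rbind, lapply(relation_types(), function(r) {
    bank_examples_for(bank, r, 2L)
  }))
  rownames(ex) <- NULL
  new_prompt_spec("multiclass", NA_character_, "multiclass",
                  definition_lines(all_labels()),
                  paste(all_labels(), collapse = ", "),
                  ex, query_snippet(instance), bank$uid)
}

#' Build a binary few-shot prompt for one relation type
#'
#' Three positive examples of `relation` plus three NONE examples; the
#' instruction embeds the relation's definition and restricts the answer
#' vocabulary to `{relation, NONE}`.
#'
#' @inheritParams build_multiclass_prompt
#' @param relation One of [relation_types()].
#' @return A `prompt_spec`.
#' @export
build_binary_prompt <- function(bank, relation, instance) {
  stopifnot(inherits(bank, "example_bank"))
  if (!relation %in% relation_types()) {
    stop("unknown relation type: ", relation, call. = FALSE)
  }
  ex <- rbind(bank_examples_for(bank, relation, 3L),
              bank_examples_for(bank, NONE_LABEL, 3L))
  rownames(ex) <- NULL
  new_prompt_spec("binary", relation, "binary",
                  definition_lines(c(relation, NONE_LABEL)),
                  paste(c(relation, NONE_LABEL), collapse = ", "),
                  ex, query_snippet(instance), bank$uid)
}

#' Build a binary zero-shot prompt
#'
#' The binary prompt without any example: definition plus query only.
#'
#' @inheritParams build_binary_prompt
#' @return A `prompt_spec` with zero example blocks.
#' @export
build_zeroshot_prompt <- function(relation, instance) {
  if (!relation %in% relation_types()) {
    stop("unknown relation type: ", relation, call. = FALSE)
  }
  ex <- data.frame(snippet = character(), label = character(),
                   source_doc = character(), stringsAsFactors = FALSE)
  new_prompt_spec("zeroshot", relation, "binary",
                  definition_lines(c(relation, NONE_LABEL)),
                  paste(c(relation, NONE_LABEL), collapse = ", "),
                  ex, query_snippet(instance), "none")
}

# Everything but the query is constant per (regime, relation, bank); cache
# the rendered halves around {{query}} so corpus-scale classification stays
# cheap.
render_halves <- function(spec) {
  key <- paste(spec$regime, spec$relation, spec$bank_uid, sep = "|")
  cached <- .ptrex_env$render_cache[[key]]
  if (!is.null(cached)) return(cached)
  tpl <- load_template(spec$template)
  filled <- fill_template(tpl, list(
    relation = if (is.na(spec$relation)) "" else spec$relation,
    definitions = spec$definitions,
    labels = spec$labels,
    examples = render_examples(spec$examples)))
  halves <- strsplit(filled, "{{query}}", fixed = TRUE)[[1]]
  if (length(halves) != 2L) {
    stop("template must contain {{query}} exactly once", call. = FALSE)
  }
  .ptrex_env$render_cache[[key]] <- halves
  halves
}

#' Render a prompt specification to text
#'
#' @param spec A `prompt_spec`.
#' @return The full prompt string.
#' @export
render_prompt <- function(spec) {
  stopifnot(inherits(spec, "prompt_spec"))
  halves <- render_halves(spec)
  paste0(halves[1], spec$query, halves[2])
}
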