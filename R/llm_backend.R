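# Backend abstraction: a minimal completion contract with a production
# client for a locally served chat-completions endpoint and deterministic
# mocks for tests. Privacy posture: the only network peer is the configured
# base URL, and prompts are never logged unless explicitly opted in.

#' Create a completion request
#'
#' @param prompt The prompt text (non-empty).
#' @param temperature,max_tokens Optional decoding controls overriding the
#'   backend's own (which default to determinism: temperature 0, short
#'   bounded output, since the expected answer is a single label token).
#' @param model Optional model identifier (overrides the backend's).
#' @param meta Optional metadata list (e.g. the instance's gold label and
#'   the queried relation); consumed by mock backends only, never
#'   transmitted by the HTTP client.
#' @return A `completion_request`.
#' @export
completion_request <- function(prompt, temperature = NULL,
                               max_tokens = NULL, model = NULL,
                               meta = NULL) {
  if (!is.character(prompt) || length(prompt) != 1L || !nzchar(prompt)) {
    stop("prompt must be a non-empty string", call. = FALSE)
  }
  structure(list(prompt = prompt, temperature = temperature,
                 max_tokens = max_tokens, model = model, meta = meta),
            class = "completion_request")
}

#' Run a completion request against a backend
#'
#' @param backend A backend object ([mock_backend()], [oracle_backend()],
#'   [noisy_oracle_backend()] or [http_backend()]).
#' @param request A [completion_request()].
#' @return The raw model text (single string).
#' @export
complete <- function(backend, request) UseMethod("complete")

#' Deterministic mock backend
#'
#' Wraps an arbitrary `respond(request) -> text` function and counts calls
#' (see [backend_calls()]).
#'
#' @param respond Function of one `completion_request` returning a string.
#' @param name Display name.
#' @return A `mock_backend`.
#' @export
mock_backend <- function(respond, name = "mock") {
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  structure(list(respond = respond, name = name, env = env),
            class = c("mock_backend", "ptrex_backend"))
}

#' @export
complete.mock_backend <- function(backend, request) {
  backend$env$calls <- backend$env$calls + 1L
  backend$respond(request)
}

#' Number of completions served by a backend
#'
#' @param backend A backend object.
#' @return Integer call count (`reset_backend_calls()` zeroes it and
#'   returns the backend invisibly).
#' @export
backend_calls <- function(backend) backend$env$calls

#' @rdname backend_calls
#' @export
reset_backend_calls <- function(backend) {
  backend$env$calls <- 0L
  invisible(backend)
}

oracle_answer <- function(request) {
  gold <- request$meta$gold %||% NONE_LABEL
  if (is.na(gold)) gold <- NONE_LABEL
  relation <- request$meta$relation
  if (!is.null(relation)) {
    if (identical(gold, relation)) relation else NONE_LABEL
  } else {
    gold
  }
}

#' Gold-oracle mock backend
#'
#' Answers every prompt with the instance's gold label (taken from the
#' request metadata): the end-to-end pipeline becomes an identity map,
#' which is the reference condition for pipeline verification.
#'
#' @return A `mock_backend`.
#' @export
oracle_backend <- function() mock_backend(oracle_answer, name = "oracle")

#' Noisy oracle mock backend
#'
#' Like [oracle_backend()] but flips each answer with probability
#' `flip_rate` to a different allowed label. Deterministic under `seed` and
#' independent of the global RNG state: the k-th call always returns the
#' same answer.
#'
#' @param flip_rate Label-flip probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `mock_backend`.
#' @export
noisy_oracle_backend <- function(flip_rate = 0.3, seed = 1L) {
  stopifnot(flip_rate >= 0, flip_rate <= 1)
  counter <- 0L
  respond <- function(request) {
    truth <- oracle_answer(request)
    counter <<- counter + 1L
    call_seed <- as.integer((as.numeric(seed) * 1000003 + counter) %%
                              2147483647)
    with_preserved_rng({
      set.seed(call_seed, kind = "Mersenne-Twister")
      if (stats::runif(1) >= flip_rate) {
        truth
      } else {
        allowed <- if (!is.null(request$meta$relation)) {
          c(request$meta$relation, NONE_LABEL)
        } else {
          all_labels()
        }
        others <- setdiff(allowed, truth)
        others[sample.int(length(others), 1L)]
      }
    })
  }
  mock_backend(respond, name = sprintf("noisy-oracle(%.2f)", flip_rate))
}

#' Chat-completions HTTP backend
#'
#' Production client for any locally served model speaking the widely
#' adopted chat-completions contract (e.g. an Ollama or vLLM server). Model
#' names are configuration, not code. Requests only ever go to `base_url`;
#' request metadata is never transmitted; prompts are not logged unless
#' `log_prompts = TRUE`.
#'
#' @param base_url Endpoint base, e.g. `"http://localhost:11434/v1"`.
#' @param model Model identifier.
#' @param temperature,max_tokens Default decoding controls.
#' @param timeout Per-request timeout in seconds.
#' @param retries Retries on transport errors before giving up.
#' @param log_prompts Opt-in prompt logging (clinical text: off by default).
#' @return An `http_backend`.
#' @export
http_backend <- function(base_url, model, temperature = 0,
                         max_tokens = 32L, timeout = 60, retries = 2L,
                         log_prompts = FALSE) {
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  structure(list(base_url = sub("/+$", "", base_url), model = model,
                 temperature = temperature, max_tokens = max_tokens,
                 timeout = timeout, retries = retries,
                 log_prompts = log_prompts, env = env),
            class = c("http_backend", "ptrex_backend"))
}

chat_body <- function(backend, request) {
  list(model = request$model %||% backend$model,
       messages = list(list(role = "user", content = request$prompt)),
       temperature = request$temperature %||% backend$temperature,
       max_tokens = request$max_tokens %||% backend$max_tokens)
}

#' @export
complete.http_backend <- function(backend, request) {
  backend$env$calls <- backend$env$calls + 1L
  if (isTRUE(backend$log_prompts)) {
    message("[ptrex prompt] ", request$prompt)
  }
  url <- paste0(backend$base_url, "/chat/completions")
  body <- jsonlite::toJSON(chat_body(backend, request), auto_unbox = TRUE)
  last_err <- NULL
  for (attempt in seq_len(backend$retries + 1L)) {
    resp <- tryCatch(
      httr::POST(url, body = body, encode = "raw",
                 httr::content_type_json(),
                 httr::timeout(backend$timeout)),
      error = function(e) e)
    if (!inherits(resp, "error")) {
      if (httr::status_code(resp) >= 300) {
        stop("endpoint returned HTTP ", httr::status_code(resp),
             call. = FALSE)
      }
      parsed <- jsonlite::fromJSON(
        httr::content(resp, as = "text", encoding = "UTF-8"),
        simplifyVector = FALSE)
      return(parsed$choices[[1]]$message$content %||% "")
    }
    last_err <- resp
  }
  stop("endpoint unreachable after ", backend$retries + 1L,
       " attempt(s): ", conditionMessage(last_err), call. = FALSE)
}

#' Parse free-text model output into a label
#'
#' Total function: an exact (case-insensitive, whitespace-trimmed) match of
#' an allowed label is `clean`; otherwise the longest allowed label
#' occurring as a substring wins (`fuzzy`; so BEFORE-OVERLAP is never
#' mis-parsed as BEFORE); otherwise the answer is NONE with status
#' `unparseable`.
#'
#' @param raw Raw model text.
#' @param allowed Allowed label set (subset of [all_labels()]).
#' @return List with `label`, `raw` and `parse_status` (one of `"clean"`,
#'   `"fuzzy"`, `"unparseable"`).
#' @examples
#' parse_answer("BEGINS-AT", c("BEGINS-AT", "NONE"))$parse_status
#' parse_answer("je pense que la relation est before-overlap.")$label
#' @export
parse_answer <- function(raw, allowed = all_labels()) {
  stopifnot(length(allowed) > 0L, all(allowed %in% all_labels()))
  if (is.null(raw) || is.na(raw)) raw <- ""
  up <- toupper(trimws(raw))
  if (up %in% allowed) {
    return(list(label = up, raw = raw, parse_status = "clean"))
  }
  present <- allowed[vapply(allowed, grepl, logical(1), x = up,
                            fixed = TRUE)]
  if (length(present)) {
    return(list(label = present[which.max(nchar(present))], raw = raw,
                parse_status = "fuzzy"))
  }
  list(label = NONE_LABEL, raw = raw, parse_status = "unparseable")
}
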