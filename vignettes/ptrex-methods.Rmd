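---
title: "Methods: few-shot temporal relation extraction between phenotypes and time expressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: few-shot temporal relation extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptrex)
```

## The task

Clinical reports of pediatric rare-disease patients narrate a medical
history: phenotypes (signs, abnormalities) appear, persist and resolve
relative to dates of visits, ages, and durations. Reconstructing a patient
timeline from such free text requires linking every phenotype mention to
the time expressions that anchor it. `ptrex` implements that link-typing
step: given a report in which phenotypes and ten kinds of temporal
entities (DOB, DOR, DOV, DOPV, DOFV, DOTHER, Age, Duration, Frequency,
Time) are already annotated, classify each (temporal entity, phenotype)
pair into one of seven directed relation types — BEGINS-AT, ENDS-AT,
CONTAINS, OVERLAP, BEFORE, BEFORE-OVERLAP, SIMULTANEOUS — or NONE,
using a few-shot prompted large language model served locally (so no
clinical text leaves the machine).

Named-entity recognition is out of scope by design: documents arrive
pre-annotated, in the BRAT standoff dialect (`read_brat()`).

## Interval semantics of the schema

The seven relation definitions are phrased over time courses, so the
package formalizes them as a deterministic function over two closed
integer-day intervals: a phenotype episode `[ps, pe]` and a
time-expression span `[ts, te]` (`label_relation()`). Prose definitions of
this kind are mutually distinguishable only with an explicit precedence,
which we fix from most to least specific:

SIMULTANEOUS (`ps = ts, pe = te`) >
BEGINS-AT (`ps = ts`) >
ENDS-AT (`pe = te`) >
CONTAINS (`ts <= ps, pe <= te`) >
BEFORE-OVERLAP (`ps < ts, pe >= ts`) >
BEFORE (`pe < ts`) >
OVERLAP (any remaining non-empty intersection) >
NONE (disjoint, phenotype strictly after the time expression).

OVERLAP is residual by its own definition ("some common time span but no
other information"), which anchors the rest of the ordering. The function
is total: every valid pair maps to exactly one label, verified in the
tests by exhaustive enumeration against an independent brute-force
re-implementation over integer day *sets*.

Modeling choices:

* **Points vs spans.** Date-like entities (DOB, DOR, DOV, DOPV, DOFV,
  DOTHER) are time points (`start == end`); Age, Duration, Frequency and
  Time may be proper spans. BEGINS-AT / ENDS-AT / BEFORE are phrased
  against time points, CONTAINS / SIMULTANEOUS need spans.
* **Unbounded ends.** A chronic, still-ongoing phenotype has `pe = Inf`;
  BEFORE-OVERLAP is derivable with an unbounded right end, which is the
  dominant real-world configuration for that relation.
* **Degenerate corners.** Two co-extensive spans are SIMULTANEOUS even
  when both are points; a shared start beats containment (BEGINS-AT over
  CONTAINS) by the precedence above.
* **Time–time pairs are not modeled**: the relation inventory is used
  entity→phenotype only, and nothing downstream ever scores a pair of two
  temporal entities.

## The synthetic world

The corpora this method targets are private, so the package generates its
own (`generate_corpus()`): French-flavored reports with a latent patient
timeline on an abstract day axis (day 0 = birth; calendar dates are
rendering only). Defaults state the emulated world and are not tuning
knobs:

* 25 documents with on average 28 phenotype mentions each — matching the
  706 annotated relations over 25 reports of the reference corpus the
  schema comes from;
* relation mix proportional to that corpus's published totals
  (202, 7, 22, 80, 357, 24, 14)/706 (`published_relation_totals()`);
* for each relation, the temporal entity type is drawn with weights from
  the published per-entity count matrix (`published_relation_counts()`),
  restricted to semantically compatible types: CONTAINS, OVERLAP and
  SIMULTANEOUS require span-valued entities, so the point-date mass those
  columns carry in the reference counts is reassigned within the
  span-valued types;
* each relation becomes one sentence built from a small set of French
  templates ("lors de la consultation du …", "à l'âge de …",
  "depuis … mois"), with entity offsets tracked during emission; every
  report carries DOR/DOB/DOV header anchors. BEFORE-OVERLAP with DOB
  yields prenatal onsets (negative day indices), which is deliberate —
  antenatal findings are common in this population;
* gold labels are produced by *construction*: the generator asserts
  `label_relation()` on the latent spans equals the requested type for
  every emitted relation, and all unrelated (temporal, phenotype) pairs
  are gold-NONE.

What the generator does **not** emulate: real narrative variability and
discourse structure, negation/uncertainty, annotation disagreement,
nested or overlapping entity spans, discontinuous spans, and any
correlation between distance in text and relatedness. A green end-to-end
test therefore establishes that the *pipeline machinery* (I/O, pairing,
snippets, prompts, parsing, conflict resolution, scoring) is correct — it
says nothing about how well any actual LLM understands French clinical
temporality. Report lengths are configurable, not calibrated: only the
markup path needs exercising.

Tests that need many documents scale the per-document density down
(e.g. 200 documents at 4–6 relations each instead of 28) purely to stay
inside CPU budgets; the mix and all thresholds stay fixed.

## Prompt regimes

All three regimes share one instruction skeleton (templates under
`inst/templates/`, editable without code changes) and one markup dialect:
`<phenotype>…</phenotype>` and `<time type="DOV">…</time>`. The exact tag
names are a package-level convention, used identically in examples and
queries. Instructions are French; label tokens stay in English uppercase
exactly as the schema spells them, because answers are parsed against
those tokens.

* **Multi-class** (`build_multiclass_prompt()`): 2 examples for each of
  the 7 types, 14 in total, then the query; the answer vocabulary is the
  7 labels plus NONE. No NONE exemplars are included — 2 × 7 = 14 covers
  the full example budget, and the NONE option lives in the instruction.
* **Binary** (`build_binary_prompt()`): one prompt per relation type with
  3 positive and 3 NONE examples; the instruction embeds that relation's
  definition and restricts answers to {relation, NONE}. NONE examples come
  from a dedicated NONE pool, never from other relations' positives, to
  avoid leaking cross-label cues.
* **Zero-shot** (`build_zeroshot_prompt()`): the binary prompt with zero
  example blocks — definition plus query, nothing else (byte-identical
  otherwise, which the tests check by string difference).

Example selection is deterministic: banks are curated, so the first *k*
examples per label in bank order are used; there is no RNG anywhere in
prompt assembly. Context snippets cover up to 1000 whitespace tokens on
each side of each of the two entities ("token" is deliberately the
simplest reproducible unit; pass a precomputed tokenization to change it).
The two per-entity windows merge into one contiguous snippet when they
meet, and are joined with an ellipsis line when disjoint; entities are
never truncated mid-span.

## Backend and answer parsing

The backend contract is a single `complete(backend, request)` call.
Production use targets any locally served chat-completions endpoint
(`http_backend()`); decoding defaults are temperature 0 and a short
output budget, preferring determinism since the expected answer is one
label token. Tests use mocks: `oracle_backend()` answers with the gold
label carried in request metadata (making the pipeline an identity map),
and `noisy_oracle_backend()` flips answers at a configured rate,
deterministically under its own seed and without touching the global RNG.

Free-text answers are parsed totally (`parse_answer()`): exact
case-insensitive match is `clean`; otherwise the *longest* allowed label
occurring as a substring wins (`fuzzy` — so "before-overlap" can never be
read as BEFORE); otherwise the prediction is NONE with status
`unparseable`. Malformed model output therefore scores as a NONE
prediction, which is the conservative choice for precision/recall
accounting.

## Binary conflict resolution

The binary regime asks 7 independent yes/no questions per pair, so
several may come back positive. Resolution keeps the relation with the
smallest training-sample count, on the rarity-prior assumption that rare
types are less likely to be predicted spuriously. Two count sources are
supported: the example bank's source-corpus annotation counts (default —
the bank knows where it came from) and the published totals of the
reference corpus (`published_relation_totals()`), selectable via
`counts = `/`--counts`. Ties are broken deterministically by schema
declaration order (BEGINS-AT, ENDS-AT, CONTAINS, OVERLAP, BEFORE-OVERLAP,
BEFORE, SIMULTANEOUS); any fixed order would do, this one is the
package-wide canonical order used everywhere labels are enumerated.
Zero-shot classification reuses the same resolution path, since it is the
same decomposition minus the examples.

## Evaluation

`score_relations()` matches predictions to gold exactly on
(source entity, target entity, label) — entities are shared givens, so
there is no partial-span credit. Per-relation precision/recall/F1 are
reported for the 7 types; NONE appears only in the 8×8 confusion tally.
Conventions:

* zero-support and zero-prediction labels get F1 := 0 with an explicit
  `undefined` flag rather than being dropped, so macro averages are
  reproducible across corpora;
* macro-F1 weights all 7 types equally; a support-weighted average is
  also emitted (model rankings are often implicitly weighted); micro-F1
  aggregates the 7 relation classes and excludes NONE.

Inter-annotator agreement (`iaa()`) follows the pairwise protocol:
treat one annotator as reference, score the other on exact triples per
relation type, average F1 over the types present in either set. F1 is
symmetric in precision/recall, so the measure is symmetric in its
arguments (property-tested over randomized annotation pairs).

## Known limitations

* The generator's French is template-bound; it exercises offsets, markup
  and distributions, not linguistic realism.
* The HTTP client is untestable offline and is covered only by
  request-construction unit tests.
* Candidate pairing defaults to *all* cross-document pairs
  (`max_token_distance = Inf`); on long reports this is quadratic in
  entity counts, and real deployments may want a distance cap — the
  reference annotation's empty rows for DOFV/DOTHER suggest annotators,
  not pairing, produced those zeros, so the reader accepts relations on
  any non-Phenotype entity type.
* No chain-of-thought, retrieval, ensembling or fine-tuning: the scope is
  the few-shot prompting framework itself.
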