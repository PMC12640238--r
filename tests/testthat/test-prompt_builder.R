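sample_instance <- function() {
  list(snippet = paste0(
    "Apparition d'une <phenotype>fièvre</phenotype> lors de la ",
    "consultation du <time type=\"DOV\">01/02/2021</time>."),
    gold = "BEGINS-AT")
}

test_that("the multi-class prompt embeds 2 examples per type, 14 in total", {
  spec <- build_multiclass_prompt(fixture_bank(), sample_instance())
  expect_equal(nrow(spec$examples), 14L)
  expect_true(all(table(spec$examples$label)[relation_types()] == 2L))
  rendered <- render_prompt(spec)
  # 14 labeled example blocks ("Relation : <LABEL>") plus the open query
  # line ("Relation :" with no answer)
  expect_equal(lengths(regmatches(rendered,
                                  gregexpr("Relation : ", rendered))), 14L)
  expect_true(endsWith(rendered, "Relation :\n"))
  # all 8 answer labels listed in the instruction
  for (lbl in all_labels()) expect_match(rendered, lbl, fixed = TRUE)
})

test_that("a bank missing a type is refused by name", {
  ex <- fixture_bank()$examples
  crippled <- example_bank(ex[ex$label != "ENDS-AT", ])
  expect_error(build_multiclass_prompt(crippled, sample_instance()),
               "ENDS-AT")
  expect_error(build_binary_prompt(crippled, "ENDS-AT", sample_instance()),
               "ENDS-AT")
})

test_that("the binary prompt has 3 positive and 3 NONE blocks", {
  spec <- build_binary_prompt(fixture_bank(), "BEGINS-AT",
                              sample_instance())
  expect_equal(nrow(spec$examples), 6L)
  expect_equal(sum(spec$examples$label == "BEGINS-AT"), 3L)
  expect_equal(sum(spec$examples$label == "NONE"), 3L)
  expect_true(all(spec$examples$label %in% c("BEGINS-AT", "NONE")))
  expect_error(build_binary_prompt(fixture_bank(), "AFTER",
                                   sample_instance()),
               "unknown relation")
})

test_that("the zero-shot prompt is the binary prompt minus its examples", {
  inst <- sample_instance()
  zs <- build_zeroshot_prompt("BEFORE", inst)
  expect_equal(nrow(zs$examples), 0L)
  rendered_zs <- render_prompt(zs)
  expect_match(rendered_zs, relation_definition("BEFORE"), fixed = TRUE)

  bin <- build_binary_prompt(fixture_bank(), "BEFORE", inst)
  rendered_bin <- render_prompt(bin)
  without_examples <- sub(render_examples(bin$examples), "", rendered_bin,
                          fixed = TRUE)
  expect_identical(without_examples, rendered_zs)
  expect_error(build_zeroshot_prompt("AFTER", inst), "unknown relation")
})

test_that("all regimes share one instruction skeleton and markup dialect", {
  inst <- sample_instance()
  rendered <- list(
    multiclass = render_prompt(build_multiclass_prompt(fixture_bank(),
                                                       inst)),
    binary = render_prompt(build_binary_prompt(fixture_bank(), "CONTAINS",
                                               inst)),
    zeroshot = render_prompt(build_zeroshot_prompt("CONTAINS", inst)))
  first_lines <- vapply(rendered, function(x) {
    strsplit(x, "\n")[[1]][1]
  }, character(1))
  expect_length(unique(first_lines), 1L)
  for (r in rendered) {
    expect_match(r, "### Texte à analyser", fixed = TRUE)
    expect_match(r, "<phenotype>", fixed = TRUE)
    expect_match(r, "<time type=", fixed = TRUE)
    expect_true(endsWith(r, "Relation :\n"))
  }
})

test_that("example ordering is deterministic given the bank", {
  inst <- sample_instance()
  a <- build_multiclass_prompt(fixture_bank(), inst)
  b <- build_multiclass_prompt(fixture_bank(), inst)
  expect_identical(a$examples, b$examples)
  expect_identical(render_prompt(a), render_prompt(b))
  # schema order across types
  expect_identical(unique(a$examples$label), relation_types())
})

test_that("banks validate labels and marker integrity", {
  expect_error(example_bank(data.frame(snippet = "x", label = "BEGINS-AT")),
               "marker integrity")
  expect_error(
    example_bank(data.frame(
      snippet = sample_instance()$snippet, label = "WHENEVER")),
    "outside vocabulary")
})

test_that("example banks round-trip through JSON lines", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  bank <- fixture_bank()
  write_example_bank(bank, path)
  back <- read_example_bank(path)
  expect_identical(back$examples, bank$examples)
})
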