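test_that("read_conll parses the token-per-line dialect", {
  f <- withr::local_tempfile()
  writeLines(c("sleep\tB-ADR", "paralysis\tI-ADR", ""), f)
  corp <- read_conll(f)
  expect_length(corp$sequences, 1L)
  expect_equal(corp$sequences[[1L]]$tokens, c("sleep", "paralysis"))
  expect_equal(corp$sequences[[1L]]$labels, c("B-ADR", "I-ADR"))
  expect_equal(corp$alphabet$classes, "ADR")

  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_length(read_conll(empty)$sequences, 0L)
})

test_that("malformed input is rejected with a line number", {
  f <- withr::local_tempfile()
  writeLines(c("ok\tO", "token without tab"), f)
  expect_error(read_conll(f), "line 2")
  writeLines(c("tok\tNOT_A_TAG"), f)
  expect_error(read_conll(f), "tag shape")
})

test_that("write_conll emits the exact dialect, trailing blank included", {
  f <- withr::local_tempfile()
  corp <- wcrf_corpus(list(labeled_sequence(c("a", "b"), c("O", "B-ADR"))))
  write_conll(corp, f)
  expect_equal(readLines(f), c("a\tO", "b\tB-ADR", ""))
  write_conll(wcrf_corpus(list(), label_alphabet("ADR")), f)
  expect_equal(readLines(f), character())
})

test_that("read/write round-trips generated corpora exactly", {
  for (seed in c(3L, 17L, 92L)) {
    corp <- generate_corpus(generator_config(n_sentences = 12L,
                                             seed = seed))$corpus
    f <- withr::local_tempfile()
    write_conll(corp, f)
    back <- read_conll(f)
    expect_length(back$sequences, length(corp$sequences))
    for (i in seq_along(corp$sequences)) {
      expect_identical(back$sequences[[i]]$tokens, corp$sequences[[i]]$tokens)
      expect_identical(back$sequences[[i]]$labels, corp$sequences[[i]]$labels)
    }
  }
})

test_that("alphabet dimensions follow the tag inventory", {
  ab <- label_alphabet(c("ADR", "Indication"))
  expect_equal(ab$K, 5L)                  # O + B/I per class
  expect_equal(ab$tags[[1L]], "O")
  expect_equal(ab$start_index, 6L)
  expect_equal(ab$end_index, 7L)
  expect_false(ab$start_index %in% seq_len(ab$K))
})

test_that("validate_boi flags illegal I- continuations", {
  ab <- label_alphabet(c("ADR", "Indication"))
  v <- validate_boi(c("B-Indication", "I-ADR"), ab)
  expect_equal(v$position, 2L)
  expect_match(v$rule, "I-ADR cannot follow B-Indication")
  expect_equal(nrow(validate_boi(c("O", "O", "O"), ab)), 0L)
  v2 <- validate_boi(c("I-ADR", "O"), ab)
  expect_equal(v2$position, 1L)
  expect_match(v2$rule, "sentence start")
  expect_equal(nrow(validate_boi(c("B-ADR", "I-ADR", "I-ADR"), ab)), 0L)
  expect_error(validate_boi(c("B-Drug"), ab), "not in alphabet")
})

test_that("extract_spans materializes maximal B/I runs", {
  sp <- extract_spans(c("O", "B-ADR", "I-ADR", "O"))
  expect_equal(sp, data.frame(class = "ADR", start = 1L, end = 3L))
  expect_equal(nrow(extract_spans(rep("O", 4L))), 0L)
  two <- extract_spans(c("B-ADR", "B-ADR"))
  expect_equal(nrow(two), 2L)
  expect_equal(two$end - two$start, c(1L, 1L))
  # orphan I- is repaired as a fresh span start
  rep_sp <- extract_spans(c("O", "I-ADR", "I-ADR"))
  expect_equal(rep_sp, data.frame(class = "ADR", start = 1L, end = 3L))
  # class switch inside a run splits the span
  sw <- extract_spans(c("B-ADR", "I-Indication"))
  expect_equal(sw$class, c("ADR", "Indication"))
})

test_that("span extraction and BIO serialization are inverse on valid input", {
  ab <- label_alphabet(c("ADR", "Indication"))
  for (seed in 1:5) {
    corp <- generate_corpus(generator_config(n_sentences = 8L,
                                             seed = seed))$corpus
    for (s in corp$sequences) {
      expect_equal(nrow(validate_boi(s$labels, corp$alphabet)), 0L)
      sp <- extract_spans(s$labels)
      expect_identical(wcrf:::spans_to_labels(sp, length(s$tokens)),
                       s$labels)
    }
  }
})

test_that("class_token_counts pools B/I and conserves the token total", {
  corp <- wcrf_corpus(list(labeled_sequence(c("x", "y"), c("O", "B-ADR"))))
  expect_equal(class_token_counts(corp), c(O = 1L, ADR = 1L))
  gen <- generate_corpus(generator_config(n_sentences = 30L, seed = 8L))
  counts <- class_token_counts(gen$corpus)
  expect_equal(sum(counts),
               sum(vapply(gen$corpus$sequences, length, 1L)))
  expect_equal(counts[names(gen$ground_truth$class_counts)],
               gen$ground_truth$class_counts)
  expect_error(class_token_counts(wcrf_corpus(list(), label_alphabet("ADR"))),
               "empty")
})

test_that("adr_token_ratio reproduces the worked sentence ratios", {
  # 12-token sentence with a single B-ADR ('depression')
  ex2 <- labeled_sequence(
    c("When", "the", "depression", "is", "coming", "out", "caused", "by",
      "this", "damn", "levofloxacin", ":)"),
    c("O", "O", "B-ADR", rep("O", 9L)))
  expect_equal(round(adr_token_ratio(ex2), 1L), 8.3)
  # 16-token sentence with a single B-ADR ('sleep')
  ex1 <- labeled_sequence(paste0("t", 1:16),
                          c(rep("O", 13L), "B-ADR", "O", "O"))
  expect_equal(adr_token_ratio(ex1), 6.25)
  none <- labeled_sequence(c("a", "b"), c("O", "O"))
  expect_equal(adr_token_ratio(none), 0)
  expect_error(adr_token_ratio(labeled_sequence(character(), character())),
               "empty")
})
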