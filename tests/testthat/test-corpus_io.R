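test_that("annotated documents validate span offsets and surfaces", {
  d <- annotated_document("r1", "Bowel preparation was fair",
                          data.frame(start = 22, end = 26,
                                     label = "PREPARATION"))
  expect_equal(d$spans$text, "fair")
  expect_error(annotated_document("r2", "short",
                                  data.frame(start = 5, end = 3,
                                             label = "LESION")),
               "invalid span")
  expect_error(annotated_document("r3", "short",
                                  data.frame(start = 0, end = 99,
                                             label = "LESION")),
               "invalid span")
  expect_error(annotated_document("r4", "abcdef",
                                  data.frame(start = c(0, 2), end = c(3, 5),
                                             label = c("LESION", "SIZE"))),
               "overlapping")
  expect_error(annotated_document("r5", "abc def",
                                  data.frame(start = 0, end = 3,
                                             label = "LESION", text = "xyz")),
               "does not match")
})

test_that("read_annotations parses the JSON Lines dialects", {
  p <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id":"a","text":"Bowel preparation was fair","labels":[[22,26,"PREPARATION"]]}',
    '{"doc_id":"b","text":"no lesion","entities":[{"start_offset":0,"end_offset":9,"label":"NEGATION"}]}'
  ), p)
  docs <- read_annotations(p)
  expect_length(docs, 2L)
  expect_equal(docs[[1]]$spans$text, "fair")
  expect_equal(docs[[1]]$spans$label, "PREPARATION")
  expect_equal(docs[[2]]$doc_id, "b")
  expect_equal(docs[[2]]$spans$label, "NEGATION")

  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), empty)
  expect_length(read_annotations(empty), 0L)

  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"text": "x", "labels": [[5, 3, "LESION"]]}', bad)
  expect_error(read_annotations(bad), "line 1")
  writeLines('{not json', bad)
  expect_error(read_annotations(bad), "line 1.*malformed")
  writeLines('{"text":"abc","labels":[[0,3,"WRONG"]]}', bad)
  expect_error(read_annotations(bad), "unknown label")
})

test_that("annotations round-trip through JSON Lines", {
  docs <- small_corpus(n = 5)$documents
  p <- withr::local_tempfile(fileext = ".jsonl")
  write_annotations(docs, p)
  back <- read_annotations(p)
  for (i in seq_along(docs)) {
    expect_identical(back[[i]]$text, docs[[i]]$text)
    expect_identical(back[[i]]$spans, docs[[i]]$spans)
  }
})

test_that("spans_to_iob2 applies the B/I/O rule", {
  d <- annotated_document("r1", "on the ascending colon",
                          data.frame(start = 7, end = 22, label = "LOCATION"))
  s <- spans_to_iob2(d)
  expect_length(s, 1L)
  expect_equal(s[[1]]$tags, c("O", "O", "B-LOCATION", "I-LOCATION"))

  d2 <- annotated_document("r2", "nothing to see here")
  expect_true(all(spans_to_iob2(d2)[[1]]$tags == "O"))

  d3 <- annotated_document("r3", "about 0.5 cm",
                           data.frame(start = 6, end = 12, label = "SIZE"))
  expect_equal(spans_to_iob2(d3)[[1]]$tags, c("O", "B-SIZE", "I-SIZE"))
})

test_that("a span crossing a sentence boundary is a data defect", {
  txt <- "first line\nsecond line"
  d <- annotated_document("r1", txt,
                          data.frame(start = 6, end = 17, label = "LESION"))
  expect_error(spans_to_iob2(d), "crosses a sentence boundary")
})

test_that("iob2_to_spans inverts the encoding", {
  txt <- "on the ascending colon"
  sent <- tagged_sentence(c("on", "the", "ascending", "colon"),
                          c(0L, 3L, 7L, 17L), c(2L, 6L, 16L, 22L),
                          c("O", "O", "B-LOCATION", "I-LOCATION"))
  sp <- iob2_to_spans(sent, text = txt)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$text, "ascending colon")
  expect_equal(sp$label, "LOCATION")

  allo <- tagged_sentence(c("a", "b"), c(0L, 2L), c(1L, 3L))
  expect_equal(nrow(iob2_to_spans(allo)), 0L)

  # B opens a new entity even immediately after another B
  two <- tagged_sentence(c("polyp", "ulcer"), c(0L, 6L), c(5L, 11L),
                         c("B-LESION", "B-LESION"))
  expect_equal(nrow(iob2_to_spans(two)), 2L)
})

test_that("invalid IOB2 input errors in strict mode and repairs in lenient", {
  sent <- structure(list(tokens = c("a", "b"), starts = c(0L, 2L),
                         ends = c(1L, 3L), tags = c("O", "I-LESION"),
                         doc_id = "x", sentence_index = 1L),
                    class = "tagged_sentence")
  expect_error(iob2_to_spans(sent), "invalid IOB2")
  sp <- iob2_to_spans(sent, mode = "lenient")
  expect_equal(sp$label, "LESION")
  expect_equal(sp$start, 2L)
})

test_that("CoNLL files round-trip bit-exactly", {
  docs <- small_corpus(n = 4)$documents
  sents <- unlist(lapply(docs, spans_to_iob2), recursive = FALSE)
  p <- withr::local_tempfile(fileext = ".conll")
  write_conll(sents, p)
  back <- read_conll(p)
  expect_length(back, length(sents))
  for (i in seq_along(sents)) expect_identical(back[[i]], sents[[i]])

  one <- withr::local_tempfile(fileext = ".conll")
  writeLines(c("# doc_id = d1 sentence = 1",
               "on\tO", "the\tO", "ascending\tB-LOCATION",
               "colon\tI-LOCATION", ""), one)
  s <- read_conll(one)
  expect_length(s, 1L)
  expect_length(s[[1]]$tokens, 4L)

  padded <- tagged_sentence(c("a", "b"), c(0L, 2L), c(1L, 3L),
                            c("O", "PAD"))
  expect_error(write_conll(list(padded), p), "PAD is internal")

  bad <- withr::local_tempfile(fileext = ".conll")
  writeLines(c("onlytoken"), bad)
  expect_error(read_conll(bad), "tag column|at least token and tag")
})

test_that("span -> IOB2 -> span is the identity on generated documents", {
  docs <- small_corpus(n = 40, seed = 99, typo_rate = 0.05)$documents
  for (d in docs) {
    sents <- spans_to_iob2(d)
    for (s in sents) expect_true(is_valid_iob2(s$tags))
    back <- do.call(rbind, lapply(sents, iob2_to_spans, text = d$text))
    expect_identical(back[order(back$start), c("start", "end", "label")],
                     d$spans[, c("start", "end", "label")],
                     label = d$doc_id)
  }
})
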