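test_that("generation is deterministic and respects n_documents", {
  cfg <- generator_config(n_documents = 6, n_unlabeled = 10, seed = 3)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_length(c1$documents, 6L)
  expect_length(c1$unlabeled, 10L)
  for (i in 1:6) {
    expect_identical(c1$documents[[i]]$text, c2$documents[[i]]$text)
    expect_identical(c1$documents[[i]]$spans, c2$documents[[i]]$spans)
  }
  expect_identical(c1$unlabeled, c2$unlabeled)
  # the unlabeled corpus is a superset of the annotated texts
  expect_identical(c1$unlabeled[1:6],
                   vapply(c1$documents, `[[`, character(1), "text"))
  # a different seed changes the corpus
  c3 <- generate_corpus(generator_config(n_documents = 6, n_unlabeled = 10,
                                         seed = 4))
  expect_false(identical(c1$unlabeled, c3$unlabeled))

  empty <- generate_corpus(generator_config(n_documents = 0, n_unlabeled = 0))
  expect_length(empty$documents, 0L)
  expect_length(empty$unlabeled, 0L)
})

test_that("reports have the two-part anatomy and valid gold spans", {
  docs <- small_corpus(n = 30, seed = 8, typo_rate = 0.02)$documents
  for (d in docs) {
    expect_match(d$text, "Procedure Note")
    expect_match(d$text, "Colonoscopic finding")
    # spans validated on construction; round-trip identity
    sents <- spans_to_iob2(d)
    back <- do.call(rbind, lapply(sents, iob2_to_spans, text = d$text))
    back <- back[order(back$start), c("start", "end", "label")]
    rownames(back) <- NULL
    expect_identical(back, d$spans[, c("start", "end", "label")])
  }
})

test_that("negation rate 1 renders a negation span in every document", {
  cfg <- generator_config(n_documents = 25, n_unlabeled = 0, seed = 5,
                          negation_rate = 1)
  docs <- generate_corpus(cfg)$documents
  for (d in docs) {
    neg <- d$spans[d$spans$label == "NEGATION", ]
    expect_gte(nrow(neg), 1L)
    expect_match(neg$text[1], "^no ") # full-scope convention, cue included
  }
})

test_that("location concepts are realized by multiple surface variants", {
  docs <- small_corpus(n = 500, seed = 12, typo_rate = 0)$documents
  surfaces <- unlist(lapply(docs, function(d)
    d$spans$text[d$spans$label == "LOCATION"]))
  # variant sets documented for this report genre
  variant_sets <- list(
    descending = c("D-colon", "D colon", "Desc. colon", "DC", "mid-d-colon",
                   "proximal-d-colon", "descending colon"),
    terminal_ileum = c("T-ileum", "T ileum", "TI", "T.I.", "terminal ileum"),
    hepatic_flexure = c("H-flexure", "H flexure", "H-Fx", "HF",
                        "hepatic flexure"),
    ascending = c("a-colon", "a colon", "a. colon", "ac", "a. c.", "a-c",
                  "ascending colon"))
  for (nm in names(variant_sets)) {
    realized <- intersect(unique(surfaces), variant_sets[[nm]])
    expect_gte(length(realized), 2L)
  }
})

test_that("both discontinuous-location phrasings occur with their policies", {
  docs <- small_corpus(n = 500, seed = 12, typo_rate = 0)$documents
  two_span <- 0L
  one_span <- 0L
  for (d in docs) {
    loc <- d$spans[d$spans$label == "LOCATION", ]
    # "X colon and Y colon": two adjacent location spans joined by " and "
    if (nrow(loc) >= 2) {
      gap <- mapply(function(e, s) substr(d$text, e + 1, s),
                    head(loc$end, -1), tail(loc$start, -1) )
      two_span <- two_span + sum(trimws(gap) %in% c("and", ","))
    }
    # "X and Y colon": one span containing the conjunction
    one_span <- one_span + sum(grepl(" and ", loc$text, fixed = TRUE))
  }
  expect_gt(two_span, 0L)
  expect_gt(one_span, 0L)
})

test_that("corpus statistics track the configured label frequencies", {
  cfg <- generator_config(n_documents = 500, n_unlabeled = 0, seed = 2)
  docs <- generate_corpus(cfg)$documents
  st <- corpus_statistics(docs)
  expect_equal(st$documents, 500L)
  expect_gt(st$sentences, 0L)
  # rare vs abundant finding labels keep their ordering
  expect_lt(st$label_counts[["COLOR"]], st$label_counts[["LOCATION"]])
  expect_lt(st$label_counts[["NUMBER"]], st$label_counts[["LESION"]])
  # realized share within 20% relative of the configured weight
  for (lab in names(cfg$label_weights)) {
    expect_lt(abs(st$label_per_document[[lab]] / cfg$label_weights[[lab]] - 1),
              0.2, label = lab)
  }
  zero <- corpus_statistics(list())
  expect_equal(zero$documents, 0L)
  expect_true(all(zero$label_counts == 0L))
})

test_that("typo injection preserves the document contract", {
  docs <- small_corpus(n = 10, seed = 44, typo_rate = 0)$documents
  for (d in docs) {
    expect_identical(inject_noise(d, 0, seed = 1), d) # rate 0 is identity
    noisy <- inject_noise(d, 0.5, seed = 7)
    expect_s3_class(noisy, "annotated_doc") # revalidated on construction
    expect_identical(noisy$spans$label, d$spans$label)
    # token counts unchanged sentence by sentence
    s0 <- tokenize_document(d$text)
    s1 <- tokenize_document(noisy$text)
    expect_equal(lengths(lapply(s1, `[[`, "tokens")),
                 lengths(lapply(s0, `[[`, "tokens")))
    # round trip still exact after noise
    back <- do.call(rbind, lapply(spans_to_iob2(noisy), iob2_to_spans,
                                  text = noisy$text))
    expect_equal(nrow(back), nrow(noisy$spans))
  }
  expect_error(inject_noise(docs[[1]], 1.5), "typo_rate")
})

test_that("the transposition class reaches the documented typo", {
  # "bleeding" -> "bleeingd" is reachable by composing adjacent
  # transpositions (breadth-first search to depth 3)
  swaps <- function(w) {
    vapply(seq_len(nchar(w) - 1L), function(p)
      endoner:::.typo_transpose(w, p), character(1))
  }
  frontier <- "bleeding"
  seen <- character()
  for (depth in 1:3) {
    frontier <- unique(unlist(lapply(frontier, swaps)))
    seen <- unique(c(seen, frontier))
  }
  expect_true("bleeingd" %in% seen)
  # and single perturbations: transposition keeps length, doubling adds one
  expect_equal(nchar(endoner:::.typo_transpose("polyp", 2)), 5L)
  expect_equal(endoner:::.typo_double("polyp", 2), "poolyp")
})
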