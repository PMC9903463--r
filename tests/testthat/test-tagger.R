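# Toy configurations keep these tests fast; correctness of the underlying
# CRF is established in test-crf.R, so the focus here is the training loop,
# the embedding-seeding contract, determinism, and the predict pipeline.

toy_cfg <- function(...) {
  args <- list(embedding_dim = 16L, hidden_dim = 24L, epochs = 6L,
               batch_size = 8L, learning_rate = 5e-3)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(tagger_config, args)
}

train_sents <- function(n_docs = 12, seed = 77) {
  docs <- small_corpus(n = n_docs, seed = seed)$documents
  list(docs = docs,
       sents = unlist(lapply(docs, spans_to_iob2), recursive = FALSE))
}

test_that("configuration is validated", {
  expect_equal(tagger_config()$loss, "crf")
  expect_equal(tagger_config(architecture = "bilstm", loss = "kl")$loss, "kl")
  expect_error(tagger_config(optimizer = "sgd"))
  expect_error(tagger_config(architecture = "transformer"))
  expect_error(tagger_config(epochs = 0))
  expect_error(tagger_config(hidden_dim = -1))
})

test_that("training fails cleanly on bad inputs", {
  expect_error(train_tagger(list(), config = toy_cfg()), "empty")
})

test_that("epoch-mean training loss decreases on a separable toy set", {
  ts <- train_sents()
  sents <- ts$sents[1:50]
  m <- train_tagger(sents, config = toy_cfg())
  expect_length(m$epoch_loss, 6L)
  # non-increasing over the first epochs of a learnable problem
  expect_true(all(diff(m$epoch_loss[1:3]) <= 0))
  expect_lt(tail(m$epoch_loss, 1), m$epoch_loss[1])
})

test_that("training is deterministic for a fixed seed", {
  ts <- train_sents(8)
  m1 <- train_tagger(ts$sents, config = toy_cfg(seed = 9))
  m2 <- train_tagger(ts$sents, config = toy_cfg(seed = 9))
  expect_identical(m1$weights$wo, m2$weights$wo)
  expect_identical(m1$epoch_loss, m2$epoch_loss)
  p1 <- predict_tagger(m1, ts$docs)
  p2 <- predict_tagger(m2, ts$docs)
  for (i in seq_along(p1)) expect_identical(p1[[i]]$spans, p2[[i]]$spans)
})

test_that("the embedding layer honors the seeding and freeze contracts", {
  ts <- train_sents(6)
  vocab <- build_vocabulary(lapply(ts$sents, function(s) tolower(s$tokens)))
  emb <- one_hot_matrix(vocab)
  cfg <- toy_cfg(epochs = 1L, train_embedding = FALSE)
  m <- train_tagger(ts$sents, vocab, cfg, embedding = emb)
  # frozen: after a full epoch the matrix is bit-identical to its seed
  expect_identical(as.vector(m$weights$emb), as.vector(unclass(emb)))
  cfg2 <- toy_cfg(epochs = 1L, train_embedding = TRUE)
  m2 <- train_tagger(ts$sents, vocab, cfg2, embedding = emb)
  expect_false(identical(as.vector(m2$weights$emb), as.vector(unclass(emb))))
  # PAD row stays zero even when the layer is trainable
  expect_equal(unname(m2$weights$emb[1, ]), rep(0, ncol(emb)))
})

test_that("a converged toy model memorizes its training documents", {
  ts <- train_sents(10, seed = 31)
  cfg <- toy_cfg(epochs = 25L, learning_rate = 1e-2)
  m <- train_tagger(ts$sents, config = cfg)
  preds <- predict_tagger(m, ts$docs)
  met <- compute_metrics(score_documents(ts$docs, preds, mode = "exact"))
  expect_gte(met$f1[met$label == "micro"], 0.99)
})

test_that("predicted documents carry valid non-overlapping spans", {
  ts <- train_sents(8)
  m <- train_tagger(ts$sents, config = toy_cfg(epochs = 2L))
  preds <- predict_tagger(m, ts$docs)
  for (i in seq_along(preds)) {
    p <- preds[[i]]
    expect_s3_class(p, "annotated_doc")
    expect_identical(p$origin, "predicted")
    expect_identical(p$text, ts$docs[[i]]$text)  # text unchanged
    if (nrow(p$spans) > 1)
      expect_true(all(p$spans$start[-1] >= p$spans$end[-nrow(p$spans)]))
    # re-tagging the predictions round-trips, i.e. spans align to tokens
    expect_silent(spans_to_iob2(p))
  }
  # whitespace-only document yields zero spans
  blank <- predict_tagger(m, "   \n  ")
  expect_equal(nrow(blank[[1]]$spans), 0L)
})

test_that("emission scores expose the pluggable scorer interface", {
  ts <- train_sents(6)
  m <- train_tagger(ts$sents, config = toy_cfg(epochs = 1L))
  em <- tagger_emissions(m, c("bowel", "preparation", "was", "fair"))
  expect_equal(dim(em), c(4L, 35L))
  expect_true(all(is.finite(em)))
  expect_identical(colnames(em)[1], "O")
  # decoding those emissions with the model's CRF reproduces predict_tagger
  v <- viterbi_decode(em, tagger_crf(m), constrained = TRUE)
  expect_true(is_valid_iob2(v$tags))
})

test_that("no-CRF architectures train with each configured loss", {
  ts <- train_sents(6)
  for (loss in c("cce", "kl", "poisson")) {
    cfg <- toy_cfg(architecture = "bilstm", loss = loss, epochs = 2L)
    m <- train_tagger(ts$sents, config = cfg)
    expect_true(all(is.finite(m$epoch_loss)))
    expect_lt(m$epoch_loss[2], m$epoch_loss[1])
  }
  cfg <- toy_cfg(architecture = "lstm", epochs = 2L)
  expect_length(train_tagger(ts$sents, config = cfg)$epoch_loss, 2L)
})

test_that("model bundles reload and predict identically", {
  ts <- train_sents(6)
  m <- train_tagger(ts$sents, config = toy_cfg(epochs = 2L))
  dir <- withr::local_tempdir()
  save_tagger(m, dir)
  expect_true(all(file.exists(file.path(dir, c("weights.rds",
                                               "vocabulary.txt",
                                               "schema.txt",
                                               "config.json")))))
  m2 <- load_tagger(dir)
  p1 <- predict_tagger(m, ts$docs)
  p2 <- predict_tagger(m2, ts$docs)
  for (i in seq_along(p1)) expect_identical(p1[[i]]$spans, p2[[i]]$spans)
})
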