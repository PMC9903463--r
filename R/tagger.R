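#' Tagger configuration
#'
#' Hyperparameters of the sequence labeler. Defaults mirror the reference
#' configuration: embedding dimension 128, bidirectional hidden dimension
#' 256, 10 epochs, rmsprop. The `bilstm-crf` architecture always trains with
#' the CRF sequence negative log-likelihood; the `loss` field applies only
#' to the no-CRF variants (`lstm`, `bilstm`), where targets are one-hot so
#' KL divergence coincides with categorical cross-entropy.
#'
#' @param embedding_dim Embedding dimension used when no seeding matrix is
#'   supplied.
#' @param hidden_dim LSTM hidden dimension per direction.
#' @param epochs Training epochs.
#' @param optimizer `"rmsprop"`, `"adam"` or `"nadam"`.
#' @param loss `"cce"`, `"kl"` or `"poisson"` (no-CRF architectures only).
#' @param architecture `"lstm"`, `"bilstm"` or `"bilstm-crf"`.
#' @param seed Integer seed for initialization and batch shuffling.
#' @param batch_size Mini-batch size.
#' @param learning_rate Optimizer step size.
#' @param clip Global gradient-norm clip (0 disables).
#' @param train_embedding Fine-tune the embedding layer during training.
#' @param max_len Hard cap on sentence length in tokens.
#' @return A `tagger_config` object.
#' @export
tagger_config <- function(embedding_dim = 128L, hidden_dim = 256L,
                          epochs = 10L, optimizer = "rmsprop", loss = "cce",
                          architecture = "bilstm-crf", seed = 1L,
                          batch_size = 32L, learning_rate = 1e-3, clip = 5,
                          train_embedding = TRUE, max_len = 128L) {
  architecture <- match.arg(architecture, c("bilstm-crf", "bilstm", "lstm"))
  optimizer <- match.arg(optimizer, c("rmsprop", "adam", "nadam"))
  loss <- match.arg(loss, c("cce", "kl", "poisson"))
  stopifnot(embedding_dim > 0, hidden_dim > 0, epochs > 0, batch_size > 0,
            learning_rate > 0, max_len > 0)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 hidden_dim = as.integer(hidden_dim),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 loss = if (architecture == "bilstm-crf") "crf" else loss,
                 architecture = architecture, seed = as.integer(seed),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, clip = clip,
                 train_embedding = isTRUE(train_embedding),
                 max_len = as.integer(max_len)),
            class = "tagger_config")
}

#' @export
print.tagger_config <- function(x, ...) {
  cat(sprintf("<tagger_config> %s, embed %d, hidden %d, %d epochs, %s (loss %s)\n",
              x$architecture, x$embedding_dim, x$hidden_dim, x$epochs,
              x$optimizer, x$loss))
  invisible(x)
}

# The CRF operates over the non-PAD tags; O has index 0 so that decoding
# ties break toward the outside tag.
crf_tagset <- function(vocab = tag_vocabulary()) vocab$tags[-1L]

#' Linear-chain CRF parameters
#'
#' Transition, start and stop scores over an ordered tag set, plus the hard
#' IOB2 mask applied at decode time.
#'
#' @param trans K x K matrix of tag-to-tag scores.
#' @param start,stop Length-K vectors scoring opening/closing tags.
#' @param tags Character vector naming the K tags (default: the 35 non-PAD
#'   IOB2 tags of the 17-label schema).
#' @return A `crf_params` object.
#' @export
crf_parameters <- function(trans, start, stop, tags = crf_tagset()) {
  K <- length(tags)
  stopifnot(is.matrix(trans), nrow(trans) == K, ncol(trans) == K,
            length(start) == K, length(stop) == K)
  structure(list(trans = trans, start = as.numeric(start),
                 stop = as.numeric(stop), tags = tags),
            class = "crf_params")
}

# 0/1 decode masks derived from the IOB2 transition mask, restricted to the
# non-PAD tag set.
crf_decode_masks <- function(tags, vocab = tag_vocabulary()) {
  tm <- transition_mask(vocab)
  list(allowed = matrix(as.integer(tm[tags, tags]), length(tags),
                        length(tags)),
       allowed_start = as.integer(tm["<start>", tags]))
}

.check_emissions <- function(emissions, params) {
  stopifnot(is.matrix(emissions), ncol(emissions) == length(params$tags))
  if (nrow(emissions) == 0) stop("emissions must contain at least one token")
}

#' CRF log-partition function
#'
#' The log-sum-exp over all tag sequences of the total path score
#' (start + emissions + transitions + stop), computed by the forward
#' recursion in log space.
#'
#' @param emissions T x K matrix of per-token tag scores.
#' @param params A `crf_params`.
#' @return Scalar log Z.
#' @export
crf_log_partition <- function(emissions, params) {
  .check_emissions(emissions, params)
  cpp_crf_log_partition(emissions, params$trans, params$start, params$stop)
}

#' CRF negative log-likelihood of a gold path
#'
#' `log Z - score(gold path)`; non-negative, zero only when the gold path
#' carries all probability mass.
#'
#' @param emissions T x K matrix of per-token tag scores.
#' @param tags Gold path: tag names or 0-based indices into `params$tags`.
#' @param params A `crf_params`.
#' @return Scalar loss.
#' @export
crf_negative_log_likelihood <- function(emissions, tags, params) {
  .check_emissions(emissions, params)
  idx <- if (is.numeric(tags)) as.integer(tags)
         else match(tags, params$tags) - 1L
  if (anyNA(idx) || length(idx) != nrow(emissions))
    stop("gold tags must align with emissions and belong to the tag set")
  cpp_crf_nll(emissions, idx, params$trans, params$start, params$stop)
}

#' Viterbi decoding
#'
#' Returns an argmax-scoring tag sequence. With `constrained = TRUE`
#' (default) transitions violating IOB2 are masked to -Inf, so the output
#' always satisfies [is_valid_iob2()]. Ties break deterministically toward
#' the lowest tag index (with all-zero scores, the all-`O` path).
#'
#' @param emissions T x K matrix of per-token tag scores.
#' @param params A `crf_params`.
#' @param constrained Apply the hard IOB2 mask.
#' @param vocab `tag_vocab` used to build the mask.
#' @return List with `tags` (character), `path` (0-based indices), `score`.
#' @export
viterbi_decode <- function(emissions, params, constrained = TRUE,
                           vocab = tag_vocabulary()) {
  .check_emissions(emissions, params)
  if (constrained) {
    msk <- crf_decode_masks(params$tags, vocab)
    r <- cpp_crf_viterbi(emissions, params$trans, params$start, params$stop,
                         msk$allowed, msk$allowed_start)
  } else {
    r <- cpp_crf_viterbi(emissions, params$trans, params$start, params$stop)
  }
  list(tags = params$tags[r$path + 1L], path = r$path, score = r$score)
}

#' Train the sequence tagger
#'
#' Encodes the training sentences, seeds the embedding layer, and runs the
#' configured architecture: a (bi)directional LSTM producing per-token
#' emission scores, topped either by a linear-chain CRF trained with the
#' forward-algorithm negative log-likelihood (`bilstm-crf`) or by a
#' token-wise softmax loss (`lstm`, `bilstm`).
#'
#' @param sentences List of `tagged_sentence` with gold IOB2 tags.
#' @param vocab A `vocabulary`; built from the training sentences
#'   (min_count 1) when `NULL`.
#' @param config A [tagger_config()].
#' @param embedding Optional `embedding_matrix` seeding the embedding layer
#'   (rows aligned to `vocab`; see [embedding_for_vocab()] and
#'   [one_hot_matrix()]). `NULL` draws a small-variance random matrix of
#'   dimension `config$embedding_dim`.
#' @param tagvocab `tag_vocab`.
#' @return A `trained_tagger`: weights, vocabulary, config, schema and the
#'   per-epoch mean loss per token.
#' @export
train_tagger <- function(sentences, vocab = NULL, config = tagger_config(),
                         embedding = NULL, tagvocab = tag_vocabulary()) {
  if (!length(sentences)) stop("training set is empty")
  if (is.null(vocab))
    vocab <- build_vocabulary(lapply(sentences, function(s) tolower(s$tokens)))
  if (is.null(embedding)) {
    emb <- with_seed(config$seed, matrix(
      stats::rnorm(length(vocab$words) * config$embedding_dim, sd = 0.05),
      length(vocab$words), config$embedding_dim))
    emb[1L, ] <- 0
    provenance <- "random-init"
  } else {
    if (nrow(embedding) != length(vocab$words))
      stop("embedding rows must match the vocabulary size")
    emb <- unclass(embedding)
    provenance <- attr(embedding, "provenance") %||% "supplied"
  }
  enc <- encode_and_pad(sentences, vocab, config$max_len, tagvocab)
  toks <- lapply(seq_along(sentences), function(i)
    enc$tokens[i, seq_len(enc$lengths[i])])
  # CRF tag indices: tag-vocabulary index minus one (PAD dropped, O = 0)
  tags <- lapply(seq_along(sentences), function(i)
    enc$tags[i, seq_len(enc$lengths[i])] - 1L)
  K <- length(crf_tagset(tagvocab))
  fit <- cpp_train_tagger(toks, tags, emb, config$hidden_dim, K,
                          config$architecture, config$loss, config$optimizer,
                          config$learning_rate, config$epochs,
                          config$batch_size, config$train_embedding,
                          config$seed, config$clip)
  structure(list(weights = fit$weights, epoch_loss = as.numeric(fit$epoch_loss),
                 vocab = vocab, tagvocab = tagvocab,
                 schema = tagvocab$schema, config = config,
                 embedding_provenance = provenance),
            class = "trained_tagger")
}

#' @export
print.trained_tagger <- function(x, ...) {
  cat(sprintf("<trained_tagger> %s (%s embedding), %d-word vocabulary\n",
              x$config$architecture, x$embedding_provenance,
              length(x$vocab$words)))
  cat("  epoch loss:", paste(sprintf("%.4f", x$epoch_loss), collapse = " "),
      "\n")
  invisible(x)
}

#' CRF parameters of a trained tagger
#' @param model A `trained_tagger` with architecture `"bilstm-crf"`.
#' @return A `crf_params`.
#' @export
tagger_crf <- function(model) {
  if (model$config$architecture != "bilstm-crf")
    stop("model has no CRF layer")
  crf_parameters(model$weights$trans, model$weights$start,
                 model$weights$stop, crf_tagset(model$tagvocab))
}

#' Emission scores for one tokenized sentence
#'
#' Exposes the pluggable emission-scorer interface: per-token unnormalized
#' tag scores from the recurrent encoder. At initialization the embedding
#' layer reproduces its seeding matrix exactly.
#'
#' @param model A `trained_tagger`.
#' @param tokens Character vector of tokens.
#' @return T x K matrix with the CRF tag set as columns.
#' @export
tagger_emissions <- function(model, tokens) {
  idx <- vocab_lookup(model$vocab, tokens)
  em <- cpp_tagger_emissions(model$weights, idx, model$config$hidden_dim,
                             model$config$architecture)
  colnames(em) <- crf_tagset(model$tagvocab)
  em
}

#' Predict entity spans for documents
#'
#' Runs the full pipeline: sentence splitting, tokenization, encoding,
#' decoding (constrained Viterbi for the CRF architecture, token-wise argmax
#' otherwise) and span recovery. Output documents keep the input text
#' unchanged and carry valid, non-overlapping predicted spans.
#'
#' @param model A `trained_tagger`.
#' @param docs List of `annotated_doc` (gold spans ignored) or a character
#'   vector of report texts.
#' @param constrained Apply the hard IOB2 decode mask (CRF architecture).
#' @return List of `annotated_doc` with `origin = "predicted"`.
#' @export
predict_tagger <- function(model, docs, constrained = TRUE) {
  if (is.character(docs))
    docs <- lapply(seq_along(docs), function(i)
      annotated_document(sprintf("text%05d", i), docs[i],
                         schema = model$schema))
  sent_by_doc <- lapply(docs, function(d) tokenize_document(d$text, d$doc_id))
  all_sents <- unlist(sent_by_doc, recursive = FALSE)
  preds <- vector("list", length(all_sents))
  if (length(all_sents)) {
    toks <- lapply(all_sents, function(s) vocab_lookup(model$vocab, s$tokens))
    crf <- model$config$architecture == "bilstm-crf"
    msk <- if (crf && constrained)
      crf_decode_masks(crf_tagset(model$tagvocab), model$tagvocab)
    paths <- cpp_predict_tagger(model$weights, toks, model$config$hidden_dim,
                                model$config$architecture,
                                model$config$batch_size,
                                crf && constrained,
                                if (!is.null(msk)) msk$allowed,
                                if (!is.null(msk)) msk$allowed_start)
    tags_k <- crf_tagset(model$tagvocab)
    preds <- lapply(paths, function(p) tags_k[p + 1L])
  }
  out <- vector("list", length(docs))
  pos <- 0L
  for (di in seq_along(docs)) {
    spans <- list()
    for (s in sent_by_doc[[di]]) {
      pos <- pos + 1L
      sent <- s
      sent$tags <- preds[[pos]]
      spans[[length(spans) + 1L]] <-
        iob2_to_spans(sent, text = docs[[di]]$text, mode = "lenient",
                      vocab = model$tagvocab)
    }
    spans <- if (length(spans)) do.call(rbind, spans) else NULL
    out[[di]] <- annotated_document(docs[[di]]$doc_id, docs[[di]]$text, spans,
                                    origin = "predicted",
                                    schema = model$schema)
  }
  out
}

#' Save and reload a trained tagger bundle
#'
#' Writes a model directory: backend-native weights, the vocabulary and
#' schema as plain text, the configuration snapshot as JSON, and the
#' training loss log — sufficient to reload and predict reproducibly.
#'
#' @param model A `trained_tagger`.
#' @param dir Bundle directory (created if missing).
#' @return `save_tagger()`: `dir`, invisibly; `load_tagger()`: a
#'   `trained_tagger`.
#' @export
save_tagger <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$weights, file.path(dir, "weights.rds"))
  write_vocabulary(model$vocab, file.path(dir, "vocabulary.txt"))
  write_schema(model$schema, file.path(dir, "schema.txt"))
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(sprintf("epoch %d loss %.6f", seq_along(model$epoch_loss),
                     model$epoch_loss), file.path(dir, "training_log.txt"))
  writeLines(model$embedding_provenance,
             file.path(dir, "embedding_provenance.txt"))
  invisible(dir)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- do.call(tagger_config, cfg[setdiff(names(cfg), "loss")])
  schema <- read_schema(file.path(dir, "schema.txt"))
  log <- readLines(file.path(dir, "training_log.txt"), warn = FALSE)
  structure(list(weights = readRDS(file.path(dir, "weights.rds")),
                 epoch_loss = as.numeric(sub(".*loss ", "", log)),
                 vocab = read_vocabulary(file.path(dir, "vocabulary.txt")),
                 tagvocab = tag_vocabulary(schema), schema = schema,
                 config = config,
                 embedding_provenance = readLines(
                   file.path(dir, "embedding_provenance.txt"), warn = FALSE)),
            class = "trained_tagger")
}
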