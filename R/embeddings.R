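# Word-representation backends: CBOW embeddings pretrained on an unlabeled
# report corpus, and a one-hot basis matrix as the no-pretraining baseline.
# Both seed the tagger's embedding layer through the same matrix contract:
# rows indexed by the vocabulary, PAD row identically zero.

new_embedding_matrix <- function(mat, words, provenance, meta = list()) {
  rownames(mat) <- words
  structure(mat, provenance = provenance, meta = meta,
            class = c("embedding_matrix", "matrix", "array"))
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d words x %d dims (%s)\n",
              nrow(x), ncol(x), attr(x, "provenance")))
  invisible(x)
}

#' Pretrain CBOW word embeddings on an unlabeled corpus
#'
#' Trains continuous bag-of-words word2vec with negative sampling, single
#' threaded and deterministic for a given seed. Words below `min_count` are
#' dropped from the training stream (the word2vec convention, so context
#' windows close over them). The returned matrix is aligned to a
#' [build_vocabulary()] vocabulary built at the same threshold; the `PAD`
#' row is zero and the `UNK` row is drawn from a small-variance seeded
#' normal, since no unlabeled text trains it.
#'
#' @param corpus Character vector of sentences, or a list of token vectors
#'   (already normalized).
#' @param dim Embedding dimension (default 128).
#' @param window Context window half-width (default 5).
#' @param min_count Minimum word frequency (default 3).
#' @param epochs Training passes over the corpus (default 5).
#' @param negative Negative samples per target (default 5).
#' @param alpha Initial learning rate (linearly decayed).
#' @param seed Integer seed.
#' @return An `embedding_matrix` (vocabulary size x `dim`) with the
#'   training metadata attached, and the vocabulary as attribute `vocab`.
#' @export
train_cbow <- function(corpus, dim = 128L, window = 5L, min_count = 3L,
                       epochs = 5L, negative = 5L, alpha = 0.025, seed = 1L) {
  if (dim < 1L) stop("dim must be positive")
  toks <- if (is.character(corpus)) lapply(corpus, function(s) tokenize(s)$norm)
          else corpus
  vocab <- build_vocabulary(toks, min_count = min_count)
  if (length(vocab$words) <= 2L)
    stop("corpus too small: no word reaches min_count = ", min_count)
  # encode, dropping sub-threshold words from the stream
  enc <- lapply(toks, function(tk) {
    idx <- vocab$index[tk]
    as.integer(idx[!is.na(idx)])
  })
  enc <- enc[lengths(enc) > 0L]
  counts <- as.numeric(vocab$freq)
  mat <- cpp_train_cbow(enc, length(vocab$words), as.integer(dim),
                        as.integer(window), as.integer(negative),
                        as.integer(epochs), alpha, counts, as.integer(seed))
  mat[1L, ] <- 0 # PAD
  set.seed(seed)
  mat[2L, ] <- stats::rnorm(dim, sd = 0.01) # UNK: untrained, small random
  meta <- list(dim = dim, window = window, min_count = min_count,
               epochs = epochs, negative = negative, seed = seed,
               corpus_fingerprint = sprintf("%d sentences / %d tokens",
                                            length(enc),
                                            sum(lengths(enc))))
  out <- new_embedding_matrix(mat, vocab$words, "cbow-pretrained", meta)
  attr(out, "vocab") <- vocab
  out
}

#' One-hot word representation matrix
#'
#' The identity-like basis matrix of vocabulary dimension: every word is its
#' own unit basis vector (including `UNK`), except `PAD`, whose row is zero.
#'
#' @param vocab A `vocabulary`.
#' @return An `embedding_matrix` with `provenance = "one-hot"`.
#' @export
one_hot_matrix <- function(vocab) {
  V <- length(vocab$words)
  m <- diag(1, V, V)
  m[1L, 1L] <- 0 # PAD row is all zeros
  new_embedding_matrix(m, vocab$words, "one-hot", list(dim = V))
}

#' Align an embedding matrix onto a tagger vocabulary
#'
#' Builds the matrix that seeds the tagger's embedding layer: for each word
#' of `vocab`, its pretrained vector if present, otherwise a small-variance
#' seeded random vector (out-of-vocabulary-at-seeding initialization). The
#' `PAD` row is zero.
#'
#' @param embedding An `embedding_matrix` (e.g. from [train_cbow()]).
#' @param vocab The tagger's `vocabulary`.
#' @param seed Seed for the random rows.
#' @return An `embedding_matrix` with one row per `vocab` word.
#' @export
embedding_for_vocab <- function(embedding, vocab, seed = 1L) {
  d <- ncol(embedding)
  V <- length(vocab$words)
  set.seed(seed)
  m <- matrix(stats::rnorm(V * d, sd = 0.01), V, d)
  hit <- match(vocab$words, rownames(embedding))
  ok <- which(!is.na(hit))
  m[ok, ] <- embedding[hit[ok], , drop = FALSE]
  m[1L, ] <- 0
  new_embedding_matrix(m, vocab$words, "random-init",
                       list(seeded_from = attr(embedding, "provenance"),
                            n_pretrained = length(ok), seed = seed))
}

#' Read and write embeddings in word2vec text format
#'
#' Header line `"<vocab size> <dim>"`, then one `word v1 v2 ...` line per
#' word.
#'
#' @param embedding An `embedding_matrix`.
#' @param path File path.
#' @return `read_word2vec()`: an `embedding_matrix`;
#'   `write_word2vec()`: the path, invisibly.
#' @export
write_word2vec <- function(embedding, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(embedding), ncol(embedding)), con)
  rows <- vapply(seq_len(nrow(embedding)), function(i)
    paste(rownames(embedding)[i],
          paste(sprintf("%.8g", embedding[i, ]), collapse = " ")),
    character(1))
  writeLines(rows, con)
  invisible(path)
}

#' @rdname write_word2vec
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  words <- vapply(parts, `[`, character(1), 1L)
  m <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(hdr[2])))
  new_embedding_matrix(m, words, "loaded", list(path = path))
}

#' Cosine similarity between embedding rows
#' @param embedding An `embedding_matrix`.
#' @param w1,w2 Words (rows must exist).
#' @return Cosine similarity in `[-1, 1]`.
#' @export
embedding_cosine <- function(embedding, w1, w2) {
  a <- embedding[w1, ]
  b <- embedding[w2, ]
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}
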