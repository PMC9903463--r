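# Entity-level scoring. An entity consisting of several tokens rarely gets
# every boundary token right, so the primary mode is partial matching: a
# prediction matches a gold entity when the labels agree and the character
# ranges overlap by at least one character. Matching is greedy left-to-right
# and one-to-one. Micro metrics are always recomputed from pooled counts,
# never averaged from per-label metrics.

.check_span_frame <- function(spans, what) {
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  if (nrow(spans) > 1L && any(spans$start[-1L] < spans$end[-nrow(spans)]))
    stop(sprintf("%s spans overlap within one document", what))
  spans
}

#' Match predicted against gold entity spans
#'
#' @param gold,predicted Span data frames (`start`, `end`, `label`) for one
#'   document; non-overlapping within each list.
#' @param mode `"partial"`: labels equal and character ranges overlap by at
#'   least one character; `"exact"`: labels equal and ranges identical. Each
#'   gold and each predicted span is used at most once (greedy
#'   left-to-right).
#' @param labels Label universe for the count table (default: the 17-label
#'   schema).
#' @return A `match_counts` data frame: per-label `tp`, `fp`, `fn`.
#' @export
#' @examples
#' g <- data.frame(start = c(10, 20), end = c(15, 35),
#'                 label = c("LESION", "LOCATION"))
#' p <- data.frame(start = c(12, 20), end = c(15, 35),
#'                 label = c("LESION", "SHAPE"))
#' colSums(match_entities(g, p)[, c("tp", "fp", "fn")])  # 1, 1, 1
match_entities <- function(gold, predicted, mode = c("partial", "exact"),
                           labels = schema_labels(default_schema())) {
  mode <- match.arg(mode)
  gold <- .check_span_frame(as.data.frame(gold), "gold")
  predicted <- .check_span_frame(as.data.frame(predicted), "predicted")
  tp <- setNames(integer(length(labels)), labels)
  fp <- tp; fn <- tp
  used_gold <- rep(FALSE, nrow(gold))
  matched_pred <- rep(FALSE, nrow(predicted))
  for (i in seq_len(nrow(predicted))) {
    p <- predicted[i, ]
    cand <- which(!used_gold & gold$label == p$label)
    hit <- if (mode == "partial")
      cand[gold$start[cand] < p$end & p$start < gold$end[cand]]
    else
      cand[gold$start[cand] == p$start & gold$end[cand] == p$end]
    if (length(hit)) {
      used_gold[hit[1]] <- TRUE
      matched_pred[i] <- TRUE
    }
  }
  for (lab in labels) {
    gl <- gold$label == lab
    pl <- predicted$label == lab
    tp[lab] <- sum(pl & matched_pred)
    fp[lab] <- sum(pl & !matched_pred)
    fn[lab] <- sum(gl & !used_gold)
  }
  extra_g <- setdiff(unique(gold$label), labels)
  extra_p <- setdiff(unique(predicted$label), labels)
  if (length(extra_g) || length(extra_p))
    stop("labels outside the schema: ",
         paste(unique(c(extra_g, extra_p)), collapse = ", "))
  structure(data.frame(label = labels, tp = unname(tp), fp = unname(fp),
                       fn = unname(fn), stringsAsFactors = FALSE),
            mode = mode, class = c("match_counts", "data.frame"))
}

#' Sum match counts across documents or folds
#' @param ... `match_counts` data frames over the same label universe.
#' @return A pooled `match_counts`.
#' @export
pool_counts <- function(...) {
  lst <- list(...)
  if (length(lst) == 1L && is.list(lst[[1]]) && !is.data.frame(lst[[1]]))
    lst <- lst[[1]]
  out <- lst[[1]]
  for (m in lst[-1L]) {
    stopifnot(identical(m$label, out$label))
    out$tp <- out$tp + m$tp
    out$fp <- out$fp + m$fp
    out$fn <- out$fn + m$fn
  }
  out
}

#' Precision, recall and F1 from match counts
#'
#' Per-label metrics plus a micro-averaged row recomputed from the summed
#' counts. Conventions: `P = TP/(TP+FP)` and `R = TP/(TP+FN)` are 0 when
#' their denominator is 0; `F1 = 2PR/(P+R)`, 0 when `P + R = 0`.
#'
#' @param counts A `match_counts` data frame.
#' @return An `eval_metrics` data frame: one row per label plus a
#'   `"micro"` row, columns `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `no_entities` (flag for labels with no gold or predicted entities).
#' @export
compute_metrics <- function(counts) {
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }
  rows <- t(mapply(function(tp, fp, fn) prf(tp, fp, fn),
                   counts$tp, counts$fp, counts$fn))
  mic <- prf(sum(counts$tp), sum(counts$fp), sum(counts$fn))
  out <- data.frame(
    label = c(counts$label, "micro"),
    tp = c(counts$tp, sum(counts$tp)),
    fp = c(counts$fp, sum(counts$fp)),
    fn = c(counts$fn, sum(counts$fn)),
    precision = c(rows[, 1], mic[1]),
    recall = c(rows[, 2], mic[2]),
    f1 = c(rows[, 3], mic[3]),
    stringsAsFactors = FALSE)
  out$no_entities <- out$tp + out$fp + out$fn == 0
  structure(out, class = c("eval_metrics", "data.frame"))
}

#' Score predicted documents against gold documents
#'
#' @param gold,predicted Aligned lists of `annotated_doc`.
#' @param mode Matching mode, see [match_entities()].
#' @param labels Label universe.
#' @return Pooled `match_counts` over all documents.
#' @export
score_documents <- function(gold, predicted, mode = "partial",
                            labels = schema_labels(default_schema())) {
  stopifnot(length(gold) == length(predicted))
  pool_counts(lapply(seq_along(gold), function(i)
    match_entities(gold[[i]]$spans, predicted[[i]]$spans, mode = mode,
                   labels = labels)))
}

#' Fivefold cross-validation of the tagging pipeline
#'
#' Documents (not sentences) are partitioned into `k` near-equal folds by a
#' seeded shuffle, so sentences of one report never straddle the
#' train/test boundary. For each fold, the vocabulary is built from the
#' training documents only; a pretrained embedding matrix — trained on a
#' separate unlabeled corpus, hence non-leaking — may seed the embedding
#' layer. The aggregate is the micro metric over counts pooled across all
#' folds.
#'
#' @param docs List of gold `annotated_doc`.
#' @param k Number of folds (>= 2).
#' @param config A [tagger_config()].
#' @param representation `"pretrained"` (requires `embedding`), `"one-hot"`,
#'   or `"random"` (seeded random embedding layer).
#' @param embedding An `embedding_matrix` from [train_cbow()] used when
#'   `representation = "pretrained"`.
#' @param seed Seed controlling the fold assignment.
#' @param mode Span matching mode.
#' @return An `eval_report`: `metrics` (pooled), `folds` (per-fold metrics),
#'   `fold_assignment`, and metadata.
#' @export
crossvalidate <- function(docs, k = 5L, config = tagger_config(),
                          representation = c("pretrained", "one-hot", "random"),
                          embedding = NULL, seed = 1L, mode = "partial") {
  representation <- match.arg(representation)
  n <- length(docs)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("dataset smaller than the number of folds")
  if (representation == "pretrained" && is.null(embedding))
    stop("representation = 'pretrained' requires an embedding matrix")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  labels <- schema_labels(default_schema())
  fold_counts <- vector("list", k)
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    train_docs <- docs[fold != f]
    test_docs <- docs[fold == f]
    train_sents <- unlist(lapply(train_docs, spans_to_iob2),
                          recursive = FALSE)
    vocab <- build_vocabulary(lapply(train_sents,
                                     function(s) tolower(s$tokens)))
    emb <- switch(representation,
                  "one-hot" = one_hot_matrix(vocab),
                  "pretrained" = embedding_for_vocab(embedding, vocab,
                                                     seed = config$seed),
                  "random" = NULL)
    model <- train_tagger(train_sents, vocab, config, embedding = emb)
    preds <- predict_tagger(model, test_docs)
    fold_counts[[f]] <- score_documents(test_docs, preds, mode = mode,
                                        labels = labels)
    fold_metrics[[f]] <- compute_metrics(fold_counts[[f]])
  }
  pooled <- pool_counts(fold_counts)
  structure(list(metrics = compute_metrics(pooled), counts = pooled,
                 folds = fold_metrics, fold_assignment = fold,
                 meta = list(k = k, n_documents = n, seed = seed,
                             representation = representation,
                             mode = mode, config = config)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics[x$metrics$label == "micro", ]
  cat(sprintf("<eval_report> %d docs, %d-fold CV (%s, %s matching)\n",
              x$meta$n_documents, x$meta$k, x$meta$representation,
              x$meta$mode))
  cat(sprintf("  micro P %.4f / R %.4f / F1 %.4f\n",
              m$precision, m$recall, m$f1))
  invisible(x)
}

#' Write an evaluation report
#'
#' Human-readable header plus a machine-readable tab-separated table, one
#' row per label and a micro row.
#'
#' @param report An `eval_report`.
#' @param path File path.
#' @export
write_eval_report <- function(report, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# documents=%d folds=%d representation=%s mode=%s seed=%d",
                     report$meta$n_documents, report$meta$k,
                     report$meta$representation, report$meta$mode,
                     report$meta$seed), con)
  writeLines("label\ttp\tfp\tfn\tprecision\trecall\tf1", con)
  m <- report$metrics
  writeLines(sprintf("%s\t%d\t%d\t%d\t%.4f\t%.4f\t%.4f", m$label, m$tp, m$fp,
                     m$fn, m$precision, m$recall, m$f1), con)
  invisible(path)
}

#' Run a grid of cross-validation experiments
#'
#' One evaluation per (dataset, representation, configuration) cell, with
#' identical fold seeds across cells so representation comparisons are
#' controlled.
#'
#' @param datasets Named list of document lists (e.g. increasing sizes).
#' @param representations Character vector of representations.
#' @param configs Named list of [tagger_config()] objects.
#' @param embedding `embedding_matrix` for the pretrained representation.
#' @param k Folds.
#' @param seed Fold seed shared by all cells.
#' @return A data frame with one row per cell (micro P/R/F1) and the
#'   reports as attribute `"reports"`.
#' @export
run_experiment_grid <- function(datasets, representations = "random",
                                configs = list(default = tagger_config()),
                                embedding = NULL, k = 5L, seed = 1L) {
  rows <- list()
  reports <- list()
  for (dn in names(datasets)) for (rep in representations)
    for (cn in names(configs)) {
      r <- crossvalidate(datasets[[dn]], k = k, config = configs[[cn]],
                         representation = rep, embedding = embedding,
                         seed = seed)
      mic <- r$metrics[r$metrics$label == "micro", ]
      key <- paste(dn, rep, cn, sep = "/")
      reports[[key]] <- r
      rows[[key]] <- data.frame(dataset = dn, representation = rep,
                                config = cn, n_documents = length(datasets[[dn]]),
                                precision = mic$precision, recall = mic$recall,
                                f1 = mic$f1, stringsAsFactors = FALSE)
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}
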