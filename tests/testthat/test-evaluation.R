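span_df <- function(...) {
  if (...length() == 0)
    return(data.frame(start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE))
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             label = m[, 3], stringsAsFactors = FALSE)
}

test_that("partial matching credits same-label overlaps one-to-one", {
  g <- span_df(10, 15, "LESION", 20, 35, "LOCATION")
  p <- span_df(12, 15, "LESION", 20, 35, "SHAPE")
  cnt <- match_entities(g, p)
  expect_equal(sum(cnt$tp), 1L)
  expect_equal(sum(cnt$fp), 1L)
  expect_equal(sum(cnt$fn), 1L)

  # identity
  cnt2 <- match_entities(g, g)
  expect_equal(sum(cnt2$tp), 2L)
  expect_equal(sum(cnt2$fp) + sum(cnt2$fn), 0L)

  # empty predictions: all gold becomes FN
  cnt3 <- match_entities(g, span_df())
  expect_equal(sum(cnt3$fn), 2L)
  expect_equal(sum(cnt3$tp) + sum(cnt3$fp), 0L)

  # each gold used at most once: two predictions over one gold
  g1 <- span_df(0, 10, "LESION")
  p2 <- span_df(0, 4, "LESION", 5, 10, "LESION")
  cnt4 <- match_entities(g1, p2)
  expect_equal(cnt4$tp[cnt4$label == "LESION"], 1L)
  expect_equal(cnt4$fp[cnt4$label == "LESION"], 1L)

  # label mismatch never matches even with full overlap
  cnt5 <- match_entities(span_df(0, 5, "SIZE"), span_df(0, 5, "COLOR"))
  expect_equal(sum(cnt5$tp), 0L)

  expect_error(match_entities(span_df(0, 5, "SIZE", 3, 8, "SIZE"),
                              span_df()), "overlap")
})

test_that("exact mode requires identical ranges; partial dominates exact", {
  g <- span_df(10, 15, "LESION")
  p <- span_df(12, 15, "LESION")
  expect_equal(sum(match_entities(g, p, mode = "exact")$tp), 0L)
  expect_equal(sum(match_entities(g, p, mode = "partial")$tp), 1L)

  # relaxation monotonicity on random span sets
  set.seed(13)
  labs <- c("LESION", "SIZE", "LOCATION")
  rand_spans <- function() {
    k <- sample(0:5, 1)
    if (k == 0) return(span_df())
    starts <- sort(sample(seq(0, 100, by = 4), k))
    data.frame(start = starts, end = starts + sample(1:3, k, replace = TRUE),
               label = sample(labs, k, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  for (i in 1:200) {
    g <- rand_spans(); p <- rand_spans()
    expect_gte(sum(match_entities(g, p, mode = "partial")$tp),
               sum(match_entities(g, p, mode = "exact")$tp))
  }
})

test_that("metrics follow the P/R/F1 conventions", {
  cnt <- match_entities(span_df(10, 15, "LESION", 20, 35, "LOCATION"),
                        span_df(12, 15, "LESION", 20, 35, "SHAPE"))
  m <- compute_metrics(cnt)
  mic <- m[m$label == "micro", ]
  expect_equal(mic$precision, 0.5, tolerance = 1e-12)
  expect_equal(mic$recall, 0.5, tolerance = 1e-12)
  expect_equal(mic$f1, 0.5, tolerance = 1e-12)

  # degenerate no-entity case: all zero by convention, flagged
  zero <- compute_metrics(match_entities(span_df(), span_df()))
  expect_true(all(zero$precision == 0 & zero$recall == 0 & zero$f1 == 0))
  expect_true(all(zero$no_entities))
})

test_that("micro metrics come from summed counts, never averaged", {
  cnt <- structure(data.frame(label = c("LESION", "SIZE"),
                              tp = c(2L, 0L), fp = c(0L, 1L), fn = c(0L, 1L)),
                   class = c("match_counts", "data.frame"))
  m <- compute_metrics(cnt)
  mic <- m[m$label == "micro", ]
  expect_equal(mic$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(mic$recall, 2 / 3, tolerance = 1e-12)
  # mean of per-label metrics would be 0.5 -- assert we did NOT do that
  expect_false(isTRUE(all.equal(mic$precision, 0.5)))
})

test_that("compute_metrics agrees with independent arithmetic to 1e-12", {
  set.seed(29)
  for (i in 1:50) {
    tp <- sample(0:20, 3); fp <- sample(0:20, 3); fn <- sample(0:20, 3)
    cnt <- structure(data.frame(label = c("A1", "A2", "A3"), tp = tp,
                                fp = fp, fn = fn),
                     class = c("match_counts", "data.frame"))
    m <- compute_metrics(cnt)
    for (j in 1:3) {
      p_ref <- if (tp[j] + fp[j] > 0) tp[j] / (tp[j] + fp[j]) else 0
      r_ref <- if (tp[j] + fn[j] > 0) tp[j] / (tp[j] + fn[j]) else 0
      f_ref <- if (p_ref + r_ref > 0) 2 * p_ref * r_ref / (p_ref + r_ref) else 0
      expect_equal(m$precision[j], p_ref, tolerance = 1e-12)
      expect_equal(m$recall[j], r_ref, tolerance = 1e-12)
      expect_equal(m$f1[j], f_ref, tolerance = 1e-12)
    }
  }
})

test_that("fold assignment is document-level, near-equal and seeded", {
  docs <- small_corpus(n = 20)$documents
  cfg <- tagger_config(embedding_dim = 8L, hidden_dim = 8L, epochs = 1L,
                       batch_size = 8L)
  r1 <- crossvalidate(docs, k = 5, config = cfg, representation = "random",
                      seed = 42)
  expect_equal(as.integer(table(r1$fold_assignment)), rep(4L, 5))
  r2 <- crossvalidate(docs, k = 5, config = cfg, representation = "random",
                      seed = 42)
  expect_identical(r1$fold_assignment, r2$fold_assignment)
  expect_identical(r1$metrics, r2$metrics)
  expect_length(r1$folds, 5L)
  expect_equal(nrow(r1$metrics), 18L) # 17 labels + micro

  # micro from pooled counts equals metrics on the pooled counts directly
  expect_equal(r1$metrics[r1$metrics$label == "micro", "f1"],
               compute_metrics(r1$counts)[18, "f1"], tolerance = 1e-12)

  expect_error(crossvalidate(docs[1:3], k = 5, config = cfg), "smaller")
  expect_error(crossvalidate(docs, k = 1, config = cfg), "k must be")
  expect_error(crossvalidate(docs, k = 5, config = cfg,
                             representation = "pretrained"),
               "requires an embedding")
})

test_that("k = 2 on 2 documents tests each document exactly once", {
  docs <- small_corpus(n = 2)$documents
  cfg <- tagger_config(embedding_dim = 8L, hidden_dim = 8L, epochs = 1L)
  r <- crossvalidate(docs, k = 2, config = cfg, representation = "random")
  expect_identical(sort(unique(r$fold_assignment)), 1:2)
  # every gold span appears exactly once in the pooled counts (as TP or FN)
  n_gold <- sum(vapply(docs, function(d) nrow(d$spans), integer(1)))
  expect_equal(sum(r$counts$tp) + sum(r$counts$fn), n_gold)
})

test_that("the experiment grid yields one report per cell", {
  sizes <- c(3L, 4L, 5L, 6L, 7L)
  datasets <- lapply(sizes, function(n) small_corpus(n = n, seed = n)$documents)
  names(datasets) <- paste0("S", sizes)
  cfg <- tagger_config(embedding_dim = 8L, hidden_dim = 8L, epochs = 1L)
  tbl <- run_experiment_grid(datasets, representations = "random",
                             configs = list(default = cfg), k = 2, seed = 1)
  expect_equal(nrow(tbl), 5L)
  expect_length(attr(tbl, "reports"), 5L)
  expect_identical(tbl$n_documents, sizes)
})

test_that("evaluation reports serialize with 17 label rows plus micro", {
  docs <- small_corpus(n = 6)$documents
  cfg <- tagger_config(embedding_dim = 8L, hidden_dim = 8L, epochs = 1L)
  r <- crossvalidate(docs, k = 2, config = cfg, representation = "random")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(r, p)
  lines <- readLines(p)
  expect_equal(length(lines), 2L + 17L + 1L) # header comment + colnames + rows
  tab <- utils::read.delim(p, skip = 1)
  expect_equal(nrow(tab), 18L)
  expect_identical(tab$label[18], "micro")
})
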