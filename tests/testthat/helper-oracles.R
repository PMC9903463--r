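# Independent oracles used across tests. These deliberately avoid the
# package's own CRF code paths: log-partition and best-path values are
# computed by exhaustive enumeration over all K^T tag sequences.

enum_paths <- function(T, K) as.matrix(expand.grid(rep(list(seq_len(K)), T)))

enum_path_score <- function(path, em, trans, start, stop) {
  s <- start[path[1]] + em[1, path[1]]
  if (length(path) > 1)
    for (t in 2:length(path))
      s <- s + trans[path[t - 1], path[t]] + em[t, path[t]]
  s + stop[path[length(path)]]
}

enum_all_scores <- function(em, trans, start, stop) {
  paths <- enum_paths(nrow(em), ncol(em))
  apply(paths, 1L, enum_path_score, em = em, trans = trans,
        start = start, stop = stop)
}

enum_logZ <- function(em, trans, start, stop) {
  s <- enum_all_scores(em, trans, start, stop)
  m <- max(s)
  m + log(sum(exp(s - m)))
}

random_crf_instance <- function(T, K, scale = 2) {
  list(em = matrix(stats::rnorm(T * K, sd = scale), T, K),
       trans = matrix(stats::rnorm(K * K, sd = scale), K, K),
       start = stats::rnorm(K, sd = scale),
       stop = stats::rnorm(K, sd = scale),
       params = crf_parameters(matrix(0, K, K), numeric(K), numeric(K),
                               tags = paste0("T", seq_len(K))))
}

as_params <- function(inst) {
  crf_parameters(inst$trans, inst$start, inst$stop,
                 tags = paste0("T", seq_len(ncol(inst$em))))
}

# A tiny 2-label schema used for exhaustive transition-mask checks.
toy_schema <- function() endo_schema(c("AA", "BB"), c("PROCEDURE", "FINDINGS"))

# A small deterministic synthetic corpus shared by several tests.
small_corpus <- function(n = 20, seed = 123, typo_rate = 0) {
  generate_corpus(generator_config(n_documents = n, n_unlabeled = 0,
                                   seed = seed, typo_rate = typo_rate))
}
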