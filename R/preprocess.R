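# Sentence splitting and tokenization under one hard constraint: cleaning
# must never change the number of sentences or the number/position of words.
# Punctuation is only stripped from token edges; whole tokens are never
# deleted, merged, or split.

# Abbreviations that do not end a sentence (lowercase, with trailing period).
.abbrev_no_boundary <- c("desc.", "no.", "dr.", "fig.", "approx.", "vs.",
                         "prof.", "inc.", "e.g.", "i.e.")

#' Split a report into sentences with character offsets
#'
#' Newlines always end a sentence. Within a line, a period followed by
#' whitespace and a capital letter ends a sentence unless the preceding word
#' is a known abbreviation or a single letter (protecting spellings like
#' `"Desc. colon"`, `"T.I."` and `"a. colon"`); decimal numbers like `0.5`
#' never match because the period is not followed by whitespace.
#'
#' @param text Report text.
#' @return Data frame with columns `start`, `end` (0-based half-open offsets
#'   into `text`) and `text`, one row per sentence, in document order.
#' @export
#' @examples
#' split_sentences("Bowel preparation was fair")
split_sentences <- function(text) {
  empty <- data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (is.null(text) || !nzchar(text)) return(empty)
  # line boundaries first
  line_starts <- c(0L, gregexpr("\n", text, fixed = TRUE)[[1]])
  if (line_starts[2] == -1L) line_starts <- 0L
  nl <- c(line_starts[-1] - 1L, nchar(text)) # 0-based end (exclusive) per line
  starts <- integer(); ends <- integer()
  for (k in seq_along(line_starts)) {
    ls <- line_starts[k] # 0-based first char of the line (gregexpr is 1-based,
    le <- nl[k]          # so the newline's 1-based pos is the next char's 0-based)
    if (le <= ls) next
    line <- substr(text, ls + 1L, le)
    # candidate boundaries: ". " followed by a capital
    cand <- gregexpr("\\.(?=\\s+[A-Z0-9])", line, perl = TRUE)[[1]]
    cuts <- integer()
    if (cand[1] != -1L) {
      for (p in cand) {
        before <- substr(line, 1L, p)
        word <- sub(".*\\s", "", before)
        core <- tolower(word)
        stem <- sub("\\.$", "", core)
        if (core %in% .abbrev_no_boundary) next
        if (nchar(stem) <= 1L) next            # "a.", "T." style abbreviations
        if (grepl("\\.", stem)) next           # "T.I." style
        cuts <- c(cuts, p)
      }
    }
    seg_start <- 0L # relative to line, 0-based
    for (cut in c(cuts, nchar(line))) {
      seg <- substr(line, seg_start + 1L, cut)
      # trim whitespace but keep offsets exact
      lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
      trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
      if (nchar(trimws(seg))) {
        starts <- c(starts, ls + seg_start + lead)
        ends <- c(ends, ls + cut - trail)
      }
      seg_start <- cut
    }
  }
  if (!length(starts)) return(empty)
  data.frame(start = starts, end = ends,
             text = substr(rep(text, length(starts)), starts + 1L, ends),
             stringsAsFactors = FALSE)
}

# Edge punctuation stripped from tokens; internal hyphens/periods are kept so
# "D-colon" and "T.I." stay single tokens.
.open_punct <- c("(", "[", "{", "\"", "'")
.close_punct <- c(",", ";", ":", "!", "?", ")", "]", "}", "\"", "'")

#' Tokenize a sentence with character offsets
#'
#' Tokens are whitespace-delimited words with edge punctuation stripped as a
#' separate normalization step: a token is never deleted, merged, or split,
#' so the token count always equals the whitespace word count. A trailing
#' period is removed only when the token contains no other period and at
#' least two word characters (keeping `"T.I."`, `"a."`, `"0.5"` intact while
#' normalizing `"noticed."`). Offsets address the stripped core in the
#' original text.
#'
#' @param sentence Sentence text.
#' @param offset 0-based offset of `sentence` within its document.
#' @return Data frame with columns `token` (surface), `norm` (lowercased
#'   form used for vocabulary lookup), `start`, `end`.
#' @export
#' @examples
#' tokenize("about 0.5 cm sized Is polyp was noticed.")$token
tokenize <- function(sentence, offset = 0L) {
  empty <- data.frame(token = character(), norm = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(sentence) || !nzchar(trimws(sentence))) return(empty)
  m <- gregexpr("\\S+", sentence)[[1]]
  raw <- regmatches(sentence, gregexpr("\\S+", sentence))[[1]]
  starts <- as.integer(m) - 1L
  toks <- character(length(raw))
  tstart <- integer(length(raw)); tend <- integer(length(raw))
  for (i in seq_along(raw)) {
    tok <- raw[i]
    s <- starts[i]
    e <- s + nchar(tok)
    repeat {
      first <- substr(tok, 1L, 1L)
      if (nchar(tok) > 1L && first %in% .open_punct) {
        tok <- substring(tok, 2L); s <- s + 1L
      } else break
    }
    repeat {
      lastc <- substr(tok, nchar(tok), nchar(tok))
      if (nchar(tok) > 1L && lastc %in% .close_punct) {
        tok <- substr(tok, 1L, nchar(tok) - 1L); e <- e - 1L
      } else if (nchar(tok) > 1L && lastc == ".") {
        core <- substr(tok, 1L, nchar(tok) - 1L)
        nword <- nchar(gsub("[^[:alnum:]]", "", core))
        if (!grepl(".", core, fixed = TRUE) && nword >= 2L) {
          tok <- core; e <- e - 1L
        } else if (endsWith(core, ".")) {
          # abbreviation followed by the sentence period ("T.I.."):
          # strip exactly the outer one
          tok <- core; e <- e - 1L
        } else break
      } else break
    }
    toks[i] <- tok
    tstart[i] <- s
    tend[i] <- e
  }
  data.frame(token = toks, norm = tolower(toks),
             start = tstart + as.integer(offset),
             end = tend + as.integer(offset), stringsAsFactors = FALSE)
}

#' Split and tokenize a whole document
#'
#' @param text Document text.
#' @param doc_id Identifier carried on the resulting sentences.
#' @return List of `tagged_sentence` skeletons (all tags `"O"`), with
#'   offsets into `text`.
#' @export
tokenize_document <- function(text, doc_id = NA_character_) {
  sents <- split_sentences(text)
  out <- list()
  for (i in seq_len(nrow(sents))) {
    tk <- tokenize(sents$text[i], offset = sents$start[i])
    if (!nrow(tk)) next
    out[[length(out) + 1L]] <-
      tagged_sentence(tk$token, tk$start, tk$end,
                      doc_id = doc_id, sentence_index = length(out) + 1L)
  }
  out
}

#' Build a word vocabulary
#'
#' Indices are contiguous from 0 with reserved entries `PAD = 0` and
#' `UNK = 1`; the remaining words are ordered by frequency (descending) then
#' lexicographically, so two runs on the same corpus always assign identical
#' indices.
#'
#' @param tokens Character vector of (normalized) tokens, or a list of such
#'   vectors.
#' @param min_count Keep words occurring at least this often (>= 1).
#' @return A `vocabulary` object: `words` (index order), `index` (named,
#'   0-based), `freq`, `case_policy`.
#' @export
build_vocabulary <- function(tokens, min_count = 1L) {
  if (min_count < 1L) stop("min_count must be >= 1")
  if (is.list(tokens)) tokens <- unlist(tokens, use.names = FALSE)
  tab <- table(tokens)
  tab <- tab[tab >= min_count]
  ord <- order(-as.integer(tab), names(tab))
  words <- c("<pad>", "<unk>", names(tab)[ord])
  freq <- c(0L, 0L, as.integer(tab)[ord])
  structure(list(words = words,
                 index = stats::setNames(seq_along(words) - 1L, words),
                 freq = stats::setNames(freq, words),
                 min_count = as.integer(min_count),
                 case_policy = "lower"),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d entries (incl. <pad>, <unk>), min_count = %d\n",
              length(x$words), x$min_count))
  invisible(x)
}

#' Look up 0-based vocabulary indices (UNK fallback)
#' @param vocab A `vocabulary`.
#' @param tokens Character vector of tokens (lowercased per the case policy).
#' @return Integer vector of indices; unknown words map to `UNK = 1`.
#' @export
vocab_lookup <- function(vocab, tokens) {
  idx <- vocab$index[tolower(tokens)]
  idx[is.na(idx)] <- 1L
  unname(idx)
}

#' Serialize a vocabulary as a two-column text file
#' @param vocab A `vocabulary`.
#' @param path File path.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(sprintf("%s\t%d", vocab$words, vocab$index), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  f <- strsplit(lines, "\t", fixed = TRUE)
  words <- vapply(f, `[`, character(1), 1L)
  structure(list(words = words,
                 index = stats::setNames(seq_along(words) - 1L, words),
                 freq = stats::setNames(rep(NA_integer_, length(words)), words),
                 min_count = NA_integer_,
                 case_policy = "lower"),
            class = "vocabulary")
}

#' Integer-encode and pad tagged sentences
#'
#' Tokens are mapped through the vocabulary (out-of-vocabulary words to
#' `UNK`), tags to their 0-based tag-vocabulary indices, and both matrices
#' are padded with `PAD = 0` to the batch maximum length (capped at
#' `max_len`; longer sentences are truncated with a warning, never
#' silently).
#'
#' @param sentences List of `tagged_sentence`.
#' @param vocab A `vocabulary`.
#' @param max_len Hard cap on sentence length (default 128 tokens).
#' @param tagvocab `tag_vocab` for tag encoding.
#' @return An `encoded_batch`: `tokens` and `tags` integer matrices
#'   (sentences x max length, 0-based indices), `lengths`, `mask`.
#' @export
encode_and_pad <- function(sentences, vocab, max_len = 128L,
                           tagvocab = tag_vocabulary()) {
  n <- length(sentences)
  lens <- vapply(sentences, function(s) length(s$tokens), integer(1))
  if (any(lens > max_len)) {
    warning(sprintf("%d sentence(s) longer than max_len = %d were truncated",
                    sum(lens > max_len), max_len))
    lens <- pmin(lens, max_len)
  }
  Tm <- max(lens, 1L)
  tokm <- matrix(0L, n, Tm)
  tagm <- matrix(0L, n, Tm)
  for (i in seq_len(n)) {
    L <- lens[i]
    s <- sentences[[i]]
    tokm[i, seq_len(L)] <- vocab_lookup(vocab, s$tokens[seq_len(L)])
    tagm[i, seq_len(L)] <- tag_index(tagvocab, s$tags[seq_len(L)])
  }
  mask <- matrix(0L, n, Tm)
  for (i in seq_len(n)) mask[i, seq_len(lens[i])] <- 1L
  structure(list(tokens = tokm, tags = tagm, lengths = lens, mask = mask),
            class = "encoded_batch")
}

#' Decode an encoded batch back to tokens
#'
#' Inverse of [encode_and_pad()] up to UNK substitution and the lowercase
#' policy.
#'
#' @param batch An `encoded_batch`.
#' @param vocab The `vocabulary` used for encoding.
#' @return List of character vectors.
#' @export
decode_tokens <- function(batch, vocab) {
  lapply(seq_len(nrow(batch$tokens)), function(i) {
    idx <- batch$tokens[i, seq_len(batch$lengths[i])]
    vocab$words[idx + 1L]
  })
}
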