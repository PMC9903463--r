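#' Construct an annotated document
#'
#' A report text plus character-offset entity spans (gold or predicted).
#' Offsets are 0-based, half-open: a span `[start, end)` covers
#' `substr(text, start + 1, end)`. Spans must be non-overlapping; they are
#' stored sorted by start offset.
#'
#' @param doc_id Document identifier.
#' @param text Full report text.
#' @param spans Data frame with columns `start`, `end`, `label` and
#'   optionally `text` (the surface string, validated against the document).
#' @param origin `"gold"` or `"predicted"`.
#' @param schema An `endo_schema` used to validate labels.
#' @return An `annotated_doc` object.
#' @export
#' @examples
#' annotated_document("r1", "Bowel preparation was fair",
#'                    data.frame(start = 22, end = 26, label = "PREPARATION"))
annotated_document <- function(doc_id, text, spans = NULL,
                               origin = c("gold", "predicted"),
                               schema = default_schema()) {
  origin <- match.arg(origin)
  if (is.null(spans) || nrow(spans) == 0) {
    spans <- data.frame(start = integer(), end = integer(),
                        label = character(), text = character(),
                        stringsAsFactors = FALSE)
  } else {
    spans <- as.data.frame(spans, stringsAsFactors = FALSE)
    spans$start <- as.integer(spans$start)
    spans$end <- as.integer(spans$end)
    spans$label <- normalize_label(as.character(spans$label), schema)
    n <- nchar(text)
    bad <- spans$start < 0L | spans$start >= spans$end | spans$end > n
    if (any(bad))
      stop(sprintf("document '%s': invalid span offsets (start=%d, end=%d, text length %d)",
                   doc_id, spans$start[which(bad)[1]], spans$end[which(bad)[1]], n))
    surf <- substr(rep(text, nrow(spans)), spans$start + 1L, spans$end)
    if (is.null(spans$text)) {
      spans$text <- surf
    } else {
      spans$text <- as.character(spans$text)
      mism <- !is.na(spans$text) & spans$text != surf
      if (any(mism))
        stop(sprintf("document '%s': span text '%s' does not match document text '%s'",
                     doc_id, spans$text[which(mism)[1]], surf[which(mism)[1]]))
      spans$text[is.na(spans$text)] <- surf[is.na(spans$text)]
    }
    spans <- spans[order(spans$start, spans$end), , drop = FALSE]
    rownames(spans) <- NULL
    if (nrow(spans) > 1L && any(spans$start[-1L] < spans$end[-nrow(spans)]))
      stop(sprintf("document '%s': overlapping spans", doc_id))
    spans <- spans[, c("start", "end", "label", "text")]
  }
  structure(list(doc_id = as.character(doc_id), text = text, spans = spans,
                 origin = origin),
            class = "annotated_doc")
}

#' @export
print.annotated_doc <- function(x, ...) {
  cat(sprintf("<annotated_doc> %s (%s): %d chars, %d spans\n",
              x$doc_id, x$origin, nchar(x$text), nrow(x$spans)))
  invisible(x)
}

#' Construct a tagged sentence
#'
#' A tokenized sentence with 0-based half-open character offsets into the
#' source document and an aligned IOB2 tag sequence.
#'
#' @param tokens Character vector of token surfaces.
#' @param starts,ends Integer vectors of per-token character offsets.
#' @param tags IOB2 tag sequence (default all-`"O"`); must be valid IOB2.
#' @param doc_id,sentence_index Provenance of the sentence.
#' @param vocab `tag_vocab` used for validation.
#' @return A `tagged_sentence` object.
#' @export
tagged_sentence <- function(tokens, starts, ends, tags = NULL,
                            doc_id = NA_character_, sentence_index = NA_integer_,
                            vocab = tag_vocabulary()) {
  if (is.null(tags)) tags <- rep("O", length(tokens))
  tags <- normalize_tags(tags, vocab)
  stopifnot(length(tokens) == length(tags),
            length(tokens) == length(starts),
            length(tokens) == length(ends))
  if (!is_valid_iob2(tags, vocab))
    stop("tags are not a valid IOB2 sequence")
  structure(list(tokens = as.character(tokens),
                 starts = as.integer(starts), ends = as.integer(ends),
                 tags = tags, doc_id = as.character(doc_id),
                 sentence_index = as.integer(sentence_index)),
            class = "tagged_sentence")
}

#' @export
print.tagged_sentence <- function(x, ...) {
  cat("<tagged_sentence>", paste0(x$tokens, "/", x$tags, collapse = " "), "\n")
  invisible(x)
}

# Field-name dialects accepted in annotation JSON Lines exports. Spans come
# either as arrays [start, end, label] (field "labels" or "label") or as
# objects with {start|start_offset, end|end_offset, label|type} (field
# "entities" or "annotations").
.jsonl_span_fields <- c("labels", "label", "entities", "annotations")

#' Read an annotation export in JSON Lines format
#'
#' One document per line: a JSON object carrying the report text and its
#' labeled spans with character offsets (the dialect of common web annotation
#' tools). Lines that fail validation raise an error naming the line number.
#'
#' @param path Path to a JSON Lines file.
#' @param schema Schema used to validate labels.
#' @param origin Span origin recorded on the documents.
#' @return List of `annotated_doc`.
#' @export
read_annotations <- function(path, schema = default_schema(), origin = "gold") {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop(sprintf("line %d: malformed JSON (%s)",
                                   i, conditionMessage(e)), call. = FALSE))
    if (is.null(obj$text))
      stop(sprintf("line %d: missing 'text' field", i))
    id <- obj$id %||% obj$doc_id %||% sprintf("line%05d", i)
    field <- intersect(.jsonl_span_fields, names(obj))
    raw <- if (length(field)) obj[[field[1]]] else list()
    spans <- .parse_span_list(raw, i)
    out[[i]] <- tryCatch(
      annotated_document(id, obj$text, spans, origin = origin, schema = schema),
      error = function(e)
        stop(sprintf("line %d: %s", i, conditionMessage(e)), call. = FALSE))
  }
  out
}

.parse_span_list <- function(raw, line) {
  if (!length(raw))
    return(NULL)
  rows <- lapply(raw, function(sp) {
    if (!is.null(names(sp))) {
      start <- sp$start %||% sp$start_offset
      end <- sp$end %||% sp$end_offset
      label <- sp$label %||% sp$type
    } else {
      if (length(sp) < 3)
        stop(sprintf("line %d: span entry needs (start, end, label)", line),
             call. = FALSE)
      start <- sp[[1]]; end <- sp[[2]]; label <- sp[[3]]
    }
    if (is.null(start) || is.null(end) || is.null(label))
      stop(sprintf("line %d: span entry needs (start, end, label)", line),
           call. = FALSE)
    data.frame(start = as.integer(start), end = as.integer(end),
               label = as.character(label), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write annotated documents as JSON Lines
#'
#' @param docs List of `annotated_doc`.
#' @param path Output file.
#' @export
write_annotations <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    labels <- lapply(seq_len(nrow(d$spans)), function(k)
      list(d$spans$start[k], d$spans$end[k], d$spans$label[k]))
    jsonlite::toJSON(list(id = d$doc_id, text = d$text,
                          labels = if (length(labels)) labels else list(),
                          origin = d$origin),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Convert character-offset spans to token-level IOB2 tags
#'
#' The first token overlapping a span receives `B-label`, subsequent
#' overlapping tokens `I-label`, all other tokens `O`. A span whose tokens
#' fall in more than one sentence is a data defect and raises an error.
#'
#' @param doc An `annotated_doc`.
#' @param sentences Tokenized sentences of `doc$text` (list of
#'   `tagged_sentence` skeletons); defaults to the pipeline's own splitter
#'   and tokenizer.
#' @param vocab `tag_vocab`.
#' @return List of `tagged_sentence` with tags filled in.
#' @export
#' @examples
#' d <- annotated_document("r1", "on the ascending colon",
#'                         data.frame(start = 7, end = 22, label = "LOCATION"))
#' spans_to_iob2(d)[[1]]$tags  # O O B-LOCATION I-LOCATION
spans_to_iob2 <- function(doc, sentences = NULL, vocab = tag_vocabulary()) {
  if (is.null(sentences)) sentences <- tokenize_document(doc$text, doc$doc_id)
  spans <- doc$spans
  hit_sent <- rep(NA_integer_, nrow(spans))
  out <- vector("list", length(sentences))
  for (si in seq_along(sentences)) {
    s <- sentences[[si]]
    tags <- rep("O", length(s$tokens))
    if (nrow(spans)) {
      for (k in seq_len(nrow(spans))) {
        ov <- which(s$starts < spans$end[k] & spans$start[k] < s$ends)
        if (!length(ov)) next
        if (!is.na(hit_sent[k]) && hit_sent[k] != si)
          stop(sprintf("document '%s': span %d-%d ('%s') crosses a sentence boundary",
                       doc$doc_id, spans$start[k], spans$end[k], spans$text[k]))
        hit_sent[k] <- si
        tags[ov[1]] <- paste0("B-", spans$label[k])
        if (length(ov) > 1) tags[ov[-1]] <- paste0("I-", spans$label[k])
      }
    }
    out[[si]] <- tagged_sentence(s$tokens, s$starts, s$ends, tags,
                                 doc_id = doc$doc_id, sentence_index = si,
                                 vocab = vocab)
  }
  out
}

#' Recover entity spans from an IOB2 tag sequence
#'
#' One span per maximal `B-X (I-X)*` run; the character range extends from
#' the first token's start to the last token's end.
#'
#' @param sent A `tagged_sentence`.
#' @param text Optional document text used to fill the span surface strings.
#' @param mode `"strict"` errors on invalid IOB2 input; `"lenient"` repairs
#'   orphan `I-X` tags by promoting them to `B-X` (useful for models without
#'   a structural decoder).
#' @param vocab `tag_vocab`.
#' @return Data frame of spans (`start`, `end`, `label`, `text`).
#' @export
iob2_to_spans <- function(sent, text = NULL, mode = c("strict", "lenient"),
                          vocab = tag_vocabulary()) {
  mode <- match.arg(mode)
  tags <- normalize_tags(sent$tags, vocab)
  if (!is_valid_iob2(tags, vocab)) {
    if (mode == "strict")
      stop("invalid IOB2 sequence; use mode = 'lenient' to repair")
    prev_lab <- ""
    for (i in seq_along(tags)) {
      if (startsWith(tags[i], "I-") && prev_lab != substring(tags[i], 3L))
        tags[i] <- paste0("B-", substring(tags[i], 3L))
      prev_lab <- if (grepl("^[BI]-", tags[i])) substring(tags[i], 3L) else ""
    }
  }
  starts <- integer(); ends <- integer(); labels <- character()
  open <- FALSE
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (startsWith(t, "B-")) {
      starts <- c(starts, sent$starts[i]); ends <- c(ends, sent$ends[i])
      labels <- c(labels, substring(t, 3L)); open <- TRUE
    } else if (startsWith(t, "I-") && open) {
      ends[length(ends)] <- sent$ends[i]
    } else {
      open <- FALSE
    }
  }
  surf <- if (!is.null(text)) substr(rep(text, length(starts)), starts + 1L, ends)
          else rep(NA_character_, length(starts))
  data.frame(start = starts, end = ends, label = labels, text = surf,
             stringsAsFactors = FALSE)
}

#' Read and write tagged sentences in CoNLL-style format
#'
#' Tab-separated columns `token  tag  start  end`, one token per line, blank
#' line between sentences, and a `# doc_id = ...` comment opening each
#' sentence. Readers also accept plain two-column `token  tag` files (offsets
#' are then reconstructed by cumulative position). `PAD` is an internal
#' symbol and may not be written.
#'
#' @param sentences List of `tagged_sentence`.
#' @param path File path.
#' @param vocab `tag_vocab`.
#' @return `read_conll()`: list of `tagged_sentence`; `write_conll()`: the
#'   path, invisibly.
#' @export
write_conll <- function(sentences, path, vocab = tag_vocabulary()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in sentences) {
    if (any(s$tags == "PAD"))
      stop("PAD is internal only and cannot be written to CoNLL files")
    writeLines(sprintf("# doc_id = %s sentence = %d", s$doc_id,
                       s$sentence_index), con)
    writeLines(sprintf("%s\t%s\t%d\t%d", s$tokens, s$tags, s$starts, s$ends),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_conll
#' @export
read_conll <- function(path, vocab = tag_vocabulary()) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sentences <- list()
  tok <- character(); tg <- character(); st <- integer(); en <- integer()
  doc_id <- NA_character_; sidx <- NA_integer_; off <- 0L
  flush <- function() {
    if (length(tok)) {
      sentences[[length(sentences) + 1L]] <<-
        tagged_sentence(tok, st, en, tg, doc_id, sidx, vocab)
      tok <<- character(); tg <<- character(); st <<- integer(); en <<- integer()
      off <<- 0L
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { flush(); next }
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("doc_id = (\\S+)(?: sentence = (\\d+))?", ln))[[1]]
      if (length(m) >= 2) doc_id <- m[2]
      if (length(m) >= 3 && nzchar(m[3])) sidx <- as.integer(m[3])
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2)
      stop(sprintf("line %d: expected at least token and tag columns", i))
    tok <- c(tok, f[1]); tg <- c(tg, f[2])
    if (length(f) >= 4) {
      st <- c(st, as.integer(f[3])); en <- c(en, as.integer(f[4]))
    } else {
      st <- c(st, off); en <- c(en, off + nchar(f[1]))
      off <- off + nchar(f[1]) + 1L
    }
  }
  flush()
  sentences
}
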