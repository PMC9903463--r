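#' The default colonoscopy-report label schema
#'
#' Seventeen entity labels covering the two halves of a colonoscopy report:
#' the semi-structured procedure note (sedation, drugs, rectal exam, bowel
#' preparation, endoscope and extent of examination) and the free-text
#' colonoscopic findings (lesions and their attributes, sampling, and negated
#' statements of absence such as "no evidence of tumor recurrence").
#'
#' @return An `endo_schema` object: the 17 labels in canonical order, each
#'   mapped to its report section (`PROCEDURE` or `FINDINGS`).
#' @export
#' @examples
#' sch <- default_schema()
#' table(schema_sections(sch))
default_schema <- function() {
  labels <- c(
    SEDATION       = "PROCEDURE",
    SEDATIONLEVEL  = "PROCEDURE",
    MEDICATION     = "PROCEDURE",
    DOSAGE         = "PROCEDURE",
    ANTISPASMODICS = "PROCEDURE",
    DRE            = "PROCEDURE",
    PREPARATION    = "PROCEDURE",
    DEVICE         = "PROCEDURE",
    EXTENT         = "PROCEDURE",
    LESION         = "FINDINGS",
    LOCATION       = "FINDINGS",
    SHAPE          = "FINDINGS",
    COLOR          = "FINDINGS",
    SIZE           = "FINDINGS",
    NUMBER         = "FINDINGS",
    BIOPSY         = "FINDINGS",
    NEGATION       = "FINDINGS"
  )
  endo_schema(names(labels), unname(labels))
}

#' Construct an annotation schema
#'
#' @param labels Character vector of distinct entity label names.
#' @param sections Character vector the same length as `labels`; each element
#'   `"PROCEDURE"` or `"FINDINGS"`.
#' @return An `endo_schema` object.
#' @export
endo_schema <- function(labels, sections) {
  stopifnot(is.character(labels), is.character(sections),
            length(labels) == length(sections))
  if (anyDuplicated(labels))
    stop("schema labels must be distinct")
  if (!all(sections %in% c("PROCEDURE", "FINDINGS")))
    stop("sections must be 'PROCEDURE' or 'FINDINGS'")
  structure(list(labels = labels, sections = stats::setNames(sections, labels)),
            class = "endo_schema")
}

#' @export
print.endo_schema <- function(x, ...) {
  cat("<endo_schema> ", length(x$labels), " labels\n", sep = "")
  for (sec in unique(unname(x$sections))) {
    cat("  ", sec, ": ",
        paste(x$labels[x$sections[x$labels] == sec], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Labels and sections of a schema
#' @param schema An `endo_schema`.
#' @return `schema_labels()`: character vector of label names;
#'   `schema_sections()`: named character vector mapping label to section.
#' @export
schema_labels <- function(schema) schema$labels

#' @rdname schema_labels
#' @export
schema_sections <- function(schema) schema$sections

# Display abbreviations accepted on input (the annotation example style
# "B-LOC"); canonical tags always use the full label name.
.label_aliases <- c(
  LOC = "LOCATION", NEG = "NEGATION", MED = "MEDICATION", DOS = "DOSAGE",
  SED = "SEDATION", SEDLEVEL = "SEDATIONLEVEL", ANTISPASM = "ANTISPASMODICS",
  PREP = "PREPARATION", DEV = "DEVICE", EXT = "EXTENT", LES = "LESION",
  NUM = "NUMBER", BIO = "BIOPSY"
)

#' Normalize a label name, accepting display abbreviations
#'
#' Maps abbreviated display spellings (e.g. `"LOC"`) onto the canonical
#' schema label (`"LOCATION"`). Canonical names pass through unchanged.
#'
#' @param label Character vector of label names or abbreviations.
#' @param schema An `endo_schema` (default: [default_schema()]).
#' @return Character vector of canonical label names.
#' @export
normalize_label <- function(label, schema = default_schema()) {
  out <- toupper(label)
  hit <- out %in% names(.label_aliases)
  out[hit] <- .label_aliases[out[hit]]
  bad <- setdiff(unique(out), schema$labels)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  out
}

#' IOB2 tag vocabulary for a schema
#'
#' The tag inventory is `[PAD, O, B-X, I-X, ...]` for every label `X`,
#' indexed from 0 with `PAD = 0`. `O` is the first non-PAD tag so that
#' deterministic tie-breaking in decoding prefers the outside tag.
#'
#' @param schema An `endo_schema`.
#' @return A `tag_vocab` object with fields `tags` (character, in index
#'   order) and `index` (named integer, 0-based, `PAD = 0`).
#' @export
#' @examples
#' v <- tag_vocabulary(default_schema())
#' length(v$tags)  # 2 + 2 * 17
tag_vocabulary <- function(schema = default_schema()) {
  tags <- c("PAD", "O",
            as.vector(rbind(paste0("B-", schema$labels),
                            paste0("I-", schema$labels))))
  structure(list(tags = tags,
                 index = stats::setNames(seq_along(tags) - 1L, tags),
                 schema = schema),
            class = "tag_vocab")
}

#' @export
print.tag_vocab <- function(x, ...) {
  cat("<tag_vocab> ", length(x$tags), " tags (PAD=0, O=1, B-/I- pairs)\n",
      sep = "")
  invisible(x)
}

#' Convert tags to 0-based integer indices and back
#' @param vocab A `tag_vocab`.
#' @param tags Character vector of tag strings (abbreviated label spellings
#'   accepted).
#' @param idx Integer vector of 0-based tag indices.
#' @return `tag_index()`: integer indices; `index_tag()`: tag strings.
#' @export
tag_index <- function(vocab, tags) {
  tags <- normalize_tags(tags, vocab)
  unname(vocab$index[tags])
}

#' @rdname tag_index
#' @export
index_tag <- function(vocab, idx) {
  stopifnot(all(idx >= 0L), all(idx < length(vocab$tags)))
  vocab$tags[idx + 1L]
}

# Canonicalize tag spellings ("B-LOC" -> "B-LOCATION"); error on unknown tags.
normalize_tags <- function(tags, vocab) {
  plain <- tags %in% c("PAD", "O")
  ent <- !plain
  if (any(ent)) {
    pre <- substr(tags[ent], 1L, 2L)
    lab <- substring(tags[ent], 3L)
    if (!all(pre %in% c("B-", "I-")))
      stop("unknown tag(s): ",
           paste(unique(tags[ent][!pre %in% c("B-", "I-")]), collapse = ", "))
    lab <- normalize_label(lab, vocab$schema)
    tags[ent] <- paste0(pre, lab)
  }
  bad <- setdiff(unique(tags), vocab$tags)
  if (length(bad))
    stop("unknown tag(s): ", paste(bad, collapse = ", "))
  tags
}

#' Validate a tag sequence against the IOB2 constraints
#'
#' A sequence is valid when every `I-X` is immediately preceded by `B-X` or
#' `I-X` of the same label (so `O -> I` never occurs and `I` never opens a
#' sequence), and `PAD` appears only as a trailing run.
#'
#' @param tags Character vector of tags.
#' @param vocab A `tag_vocab` (default: the 17-label vocabulary).
#' @return `TRUE` or `FALSE`. Unknown tag strings are an error, not `FALSE`.
#' @export
#' @examples
#' is_valid_iob2(c("O", "O", "B-LOCATION", "I-LOCATION"))  # TRUE
#' is_valid_iob2(c("O", "I-LOCATION"))                     # FALSE
is_valid_iob2 <- function(tags, vocab = tag_vocabulary()) {
  tags <- normalize_tags(tags, vocab)
  if (!length(tags)) return(TRUE)
  prev <- "<start>"
  seen_pad <- FALSE
  for (t in tags) {
    if (seen_pad && t != "PAD") return(FALSE)
    if (t == "PAD") seen_pad <- TRUE
    if (startsWith(t, "I-")) {
      lab <- substring(t, 3L)
      if (!(prev %in% paste0(c("B-", "I-"), lab))) return(FALSE)
    }
    prev <- t
  }
  TRUE
}

#' IOB2 transition mask
#'
#' Boolean matrix saying which tag-to-tag transitions are structurally legal
#' under IOB2, including a virtual `<start>` row and `<stop>` column. An
#' entry is `FALSE` exactly when the transition violates IOB2: anything to
#' `I-X` unless coming from `B-X`/`I-X` (including `<start>` to `I-X`), and
#' any tag after `PAD` other than `PAD` itself. Used for constrained Viterbi
#' decoding, which then cannot emit an invalid sequence.
#'
#' @param vocab A `tag_vocab`.
#' @return Logical matrix with rows `c("<start>", tags)` and columns
#'   `c(tags, "<stop>")`.
#' @export
transition_mask <- function(vocab = tag_vocabulary()) {
  tags <- vocab$tags
  from <- c("<start>", tags)
  to <- c(tags, "<stop>")
  m <- matrix(TRUE, nrow = length(from), ncol = length(to),
              dimnames = list(from = from, to = to))
  is_i <- startsWith(to, "I-")
  for (j in which(is_i)) {
    lab <- substring(to[j], 3L)
    ok_from <- paste0(c("B-", "I-"), lab)
    m[!from %in% ok_from, j] <- FALSE
  }
  # PAD is an absorbing trailing state: once in PAD, only PAD or <stop>.
  m["PAD", ] <- FALSE
  m["PAD", "PAD"] <- TRUE
  m["PAD", "<stop>"] <- TRUE
  m
}

#' Read and write a schema as a plain-text config block
#'
#' Two tab-separated columns, `label` and `section`, one label per line.
#' Lines starting with `#` are comments. This lets alternative schemas be
#' loaded; the package ships the 17-label colonoscopy schema as default.
#'
#' @param schema An `endo_schema`.
#' @param path File path.
#' @return `read_schema()`: an `endo_schema`; `write_schema()`: the path,
#'   invisibly.
#' @export
write_schema <- function(schema, path) {
  writeLines(c("# label\tsection",
               sprintf("%s\t%s", schema$labels,
                       unname(schema$sections[schema$labels]))),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  endo_schema(vapply(f, `[`, character(1), 1L),
              vapply(f, `[`, character(1), 2L))
}
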