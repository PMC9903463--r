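# Synthetic colonoscopy-report generator. Emulates the two-part report
# anatomy — a semi-structured "Procedure Note" and a free-text "Colonoscopic
# finding" section — with per-label frequencies proportioned to the reference
# corpus distribution, the documented synonym/acronym variation of anatomical
# sites ("D-colon"/"DC"/"Desc. colon", "T-ileum"/"T.I.", ...), both
# discontinuous-location phrasings, negation sentences, and optional
# character-level typo noise. Every filled slot yields a gold span with
# exact character offsets.

# Lexicons. Entries marked provenance "paper" are surface forms documented
# for this report genre; "invented" entries are clearly-marked fillers that
# widen the lexicons to usable sizes.
.lex <- local({
  lex <- list(
    location_concepts = list(
      descending_colon = list(paper = c("D-colon", "D colon", "Desc. colon",
                                        "DC", "mid-d-colon", "proximal-d-colon",
                                        "descending colon",
                                        "distal descending colon"),
                              invented = character()),
      terminal_ileum = list(paper = c("T-ileum", "T ileum", "TI", "T.I.",
                                      "terminal ileum"),
                            invented = character()),
      hepatic_flexure = list(paper = c("H-flexure", "H flexure", "H-Fx", "HF",
                                       "hepatic flexure"),
                             invented = character()),
      ascending_colon = list(paper = c("a-colon", "a colon", "a. colon", "ac",
                                       "a. c.", "a-c", "ascending colon"),
                             invented = character()),
      rectum = list(paper = c("rectum"), invented = c("distal rectum")),
      sigmoid_colon = list(paper = character(),
                           invented = c("S-colon", "sigmoid colon", "SC",
                                        "proximal s-colon")),
      transverse_colon = list(paper = character(),
                              invented = c("T-colon", "transverse colon",
                                           "TC", "mid-t-colon")),
      cecum = list(paper = c("cecum"), invented = c("cecal base", "IC valve area"))
    ),
    lesion = list(paper = c("polyp", "erosions", "ulcer", "outpouching lesions",
                            "stenosis", "erythema", "edema", "hyperemia",
                            "hemorrhage", "diverticulum"),
                  invented = c("mass", "nodularity", "mucosal lesion")),
    shape = list(paper = c("Is", "shallow"),
                 invented = c("Ip", "IIa", "flat", "sessile", "pedunculated",
                              "semipedunculated")),
    size = list(paper = c("0.5 cm", "0.3 cm"),
                invented = c("0.4 cm", "0.6 cm", "0.8 cm", "1.0 cm", "1.2 cm",
                             "1.5 cm", "2.0 cm", "3 mm", "5 mm", "7 mm")),
    number = list(paper = c("several"),
                  invented = c("two", "three", "multiple", "a few", "some")),
    color = list(paper = character(),
                 invented = c("reddish", "pale", "whitish", "yellowish",
                              "hyperemic")),
    medication = list(paper = c("midazolam", "pethidine"),
                      invented = c("propofol", "fentanyl")),
    dosage = list(paper = c("3 mg", "50 mg"),
                  invented = c("1 mg", "2 mg", "5 mg", "25 mg", "100 mg")),
    sedationlevel = list(paper = c("moderate"),
                         invented = c("minimal", "deep", "light")),
    preparation = list(paper = c("fair"),
                       invented = c("good", "poor", "excellent", "inadequate")),
    device = list(paper = c("CF 260AI"),
                  invented = c("CF-H290I", "PCF-Q260AZI", "CF-HQ290L",
                               "CF-Q160L")),
    extent = list(paper = c("terminal ileum"),
                  invented = c("cecum", "T.I.", "splenic flexure", "IC valve")),
    dre = list(paper = c("normal"),
               invented = c("unremarkable", "no palpable mass")),
    negation = list(paper = c("no evidence of tumor recurrence",
                              "no mucosal lesion",
                              "no other mucosal abnormality",
                              "no definite mass lesion"),
                    invented = c("no residual polyp", "no active bleeding")),
    biopsy = list(paper = c("biopsy"),
                  invented = c("cold biopsy", "hot biopsy", "polypectomy",
                               "cold forcep biopsy"))
  )
  lex
})

.lex_values <- function(entry) c(entry$paper, entry$invented)

#' Generator configuration
#'
#' Defaults reproduce the reference corpus conditions at desk scale:
#' per-document label expectations proportioned to the 1,000-document
#' reference distribution (e.g. LOCATION about 1.12 spans per document,
#' COLOR a rare 0.20), the documented negation patterns, and a small typo
#' rate emulating real report noise.
#'
#' @param n_documents Number of gold-annotated documents.
#' @param n_unlabeled Size of the unlabeled pretraining corpus; it is a
#'   superset of the annotated documents' texts.
#' @param seed Integer seed; the whole corpus is a deterministic function of
#'   the configuration.
#' @param label_weights Named vector of expected spans per document for each
#'   of the 17 labels.
#' @param negation_rate Probability of a negation sentence per document
#'   (default: the NEGATION label weight).
#' @param typo_rate Per-token probability of a character-level typo
#'   (transposition or doubling); see [inject_noise()].
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_documents = 1000L, n_unlabeled = 10000L,
                             seed = 1L,
                             label_weights = c(
                               SEDATION = 0.860, SEDATIONLEVEL = 0.679,
                               MEDICATION = 0.871, DOSAGE = 0.872,
                               ANTISPASMODICS = 0.799, DRE = 0.995,
                               PREPARATION = 0.996, DEVICE = 0.999,
                               EXTENT = 1.000, LESION = 1.043,
                               LOCATION = 1.118, SHAPE = 0.719,
                               COLOR = 0.197, SIZE = 0.726, NUMBER = 0.219,
                               BIOPSY = 0.995, NEGATION = 0.651),
                             negation_rate = NULL, typo_rate = 0.01) {
  stopifnot(n_documents >= 0, n_unlabeled >= 0,
            all(label_weights >= 0),
            setequal(names(label_weights), schema_labels(default_schema())))
  if (is.null(negation_rate))
    negation_rate <- min(1, label_weights[["NEGATION"]])
  stopifnot(negation_rate >= 0, negation_rate <= 1,
            typo_rate >= 0, typo_rate <= 1)
  structure(list(n_documents = as.integer(n_documents),
                 n_unlabeled = as.integer(n_unlabeled),
                 seed = as.integer(seed), label_weights = label_weights,
                 negation_rate = negation_rate, typo_rate = typo_rate),
            class = "generator_config")
}

# Translate per-label expectations into template rates. Findings sentences:
# A = lesion with size/shape/color attributes, B = counted lesions,
# D = double lesion ("several erosions and shallow ulcer").
.derive_rates <- function(cfg) {
  w <- cfg$label_weights
  clamp <- function(x) max(0, min(1, x))
  a <- clamp(w[["SIZE"]])
  d <- clamp(w[["LESION"]] - a - w[["NUMBER"]])
  b <- clamp(w[["NUMBER"]] - d)
  eps <- 1e-9
  p_shape <- clamp((w[["SHAPE"]] - d) / max(a, eps))
  p_color <- clamp(w[["COLOR"]] / max(a, eps))
  base_loc <- a + b + d
  p_twospan <- clamp((w[["LOCATION"]] - base_loc) / max(base_loc, eps))
  p_sed <- clamp(w[["SEDATION"]])
  p_sed_yes <- 0.9
  p_med2 <- clamp(w[["MEDICATION"]] / max(p_sed * p_sed_yes, eps) - 1)
  p_level <- clamp(w[["SEDATIONLEVEL"]] / max(p_sed * p_sed_yes, eps))
  list(a = a, b = b, d = d, p_shape = p_shape, p_color = p_color,
       p_twospan = p_twospan, p_onespan = 0.06,
       p_sed = p_sed, p_sed_yes = p_sed_yes, p_med2 = p_med2,
       p_level = p_level,
       p_anti = clamp(w[["ANTISPASMODICS"]]), p_dre = clamp(w[["DRE"]]),
       p_prep = clamp(w[["PREPARATION"]]), p_extent = clamp(w[["EXTENT"]]),
       p_device = clamp(w[["DEVICE"]] / max(w[["EXTENT"]], eps)),
       p_biopsy = clamp(w[["BIOPSY"]]), p_neg = cfg$negation_rate)
}

# ---- piece-based rendering -------------------------------------------------

.pc <- function(text, label = NA_character_) list(text = text, label = label)

# Concatenate pieces into a line, recording a span for each labeled piece.
.render_line <- function(pieces) {
  text <- ""
  spans <- list()
  for (p in pieces) {
    if (!is.na(p$label))
      spans[[length(spans) + 1L]] <-
        data.frame(start = nchar(text), end = nchar(text) + nchar(p$text),
                   label = p$label, stringsAsFactors = FALSE)
    text <- paste0(text, p$text)
  }
  list(text = text,
       spans = if (length(spans)) do.call(rbind, spans) else NULL)
}

.pick <- function(x) x[[sample.int(length(x), 1L)]]

# A location slot: usually one concept variant; sometimes the discontinuous
# phrasings — "ascending colon and descending colon" (two entities) or
# "ascending and descending colon" (one entity).
.location_pieces <- function(rates) {
  u <- runif(1)
  if (u < rates$p_twospan) {
    if (runif(1) < 0.3)
      return(list(.pc("rectum", "LOCATION"), .pc(", "),
                  .pc("AV 10 cm", "LOCATION")))
    pair <- .pick(list(c("ascending colon", "descending colon"),
                       c("sigmoid colon", "descending colon"),
                       c("transverse colon", "ascending colon")))
    return(list(.pc(pair[1], "LOCATION"), .pc(" and "),
                .pc(pair[2], "LOCATION")))
  }
  if (u < rates$p_twospan + rates$p_onespan) {
    one <- .pick(list("ascending and descending colon",
                      "sigmoid and descending colon"))
    return(list(.pc(one, "LOCATION")))
  }
  concept <- .pick(.lex$location_concepts)
  list(.pc(.pick(.lex_values(concept)), "LOCATION"))
}

.sentence_A <- function(rates) {
  ps <- list(.pc("On the "))
  ps <- c(ps, .location_pieces(rates))
  ps <- c(ps, list(.pc(", about "), .pc(.pick(.lex_values(.lex$size)), "SIZE"),
                   .pc(" sized ")))
  if (runif(1) < rates$p_color)
    ps <- c(ps, list(.pc(.pick(.lex_values(.lex$color)), "COLOR"), .pc(" ")))
  if (runif(1) < rates$p_shape)
    ps <- c(ps, list(.pc(.pick(.lex_values(.lex$shape)), "SHAPE"), .pc(" ")))
  ps <- c(ps, list(.pc(.pick(.lex_values(.lex$lesion)), "LESION"),
                   .pc(.pick(list(" was noticed.", " was seen.",
                                  " was observed.")))))
  ps
}

.sentence_B <- function(rates) {
  c(list(.pc("There were "), .pc(.pick(.lex_values(.lex$number)), "NUMBER"),
         .pc(" "), .pc(.pick(.lex_values(.lex$lesion)), "LESION"),
         .pc(" on the ")),
    .location_pieces(rates), list(.pc(".")))
}

.sentence_D <- function(rates) {
  c(list(.pc("On the ")), .location_pieces(rates),
    list(.pc(", "), .pc(.pick(.lex_values(.lex$number)), "NUMBER"),
         .pc(" "), .pc(.pick(.lex_values(.lex$lesion)), "LESION"),
         .pc(" and "), .pc(.pick(.lex_values(.lex$shape)), "SHAPE"),
         .pc(" "), .pc(.pick(.lex_values(.lex$lesion)), "LESION"),
         .pc(" were noticed.")))
}

.sentence_biopsy <- function() {
  if (runif(1) < 0.7)
    list(.pc("It was removed by "), .pc(.pick(.lex_values(.lex$biopsy)),
                                        "BIOPSY"), .pc("."))
  else
    list(.pc(.pick(list("Random ", "Targeted "))),
         .pc(.pick(.lex_values(.lex$biopsy)), "BIOPSY"),
         .pc(" was done."))
}

.sentence_negation <- function() {
  list(.pc("There was "), .pc(.pick(.lex_values(.lex$negation)), "NEGATION"),
       .pc("."))
}

# One synthetic report: returns list(text, spans).
.generate_report <- function(rates) {
  lines <- list()
  add <- function(pieces) lines[[length(lines) + 1L]] <<- .render_line(pieces)
  # clinical information (unannotated)
  add(list(.pc("Clinical information")))
  add(list(.pc(.pick(list("Past medical Hx: none", "Past medical Hx: HTN",
                          "Antithrombotics: No", "Past Hx: DM")))))
  add(list(.pc(.pick(list("Indication: Checkup", "Indication: Screening",
                          "Indication: Surveillance")))))
  # procedure note (semi-structured)
  add(list(.pc("Procedure Note")))
  sed_yes <- FALSE
  if (runif(1) < rates$p_sed) {
    sed_yes <- runif(1) < rates$p_sed_yes
    if (sed_yes) {
      ps <- list(.pc("Sedation: "), .pc("Yes", "SEDATION"), .pc(" : "),
                 .pc(.pick(.lex_values(.lex$medication)), "MEDICATION"),
                 .pc(" "), .pc(.pick(.lex_values(.lex$dosage)), "DOSAGE"))
      if (runif(1) < rates$p_med2)
        ps <- c(ps, list(.pc(" "),
                         .pc(.pick(.lex_values(.lex$medication)), "MEDICATION"),
                         .pc(" "), .pc(.pick(.lex_values(.lex$dosage)),
                                       "DOSAGE")))
      add(ps)
    } else {
      add(list(.pc("Sedation: "), .pc("No", "SEDATION")))
    }
  }
  if (sed_yes && runif(1) < rates$p_level)
    add(list(.pc("Level of sedation: "),
             .pc(.pick(.lex_values(.lex$sedationlevel)), "SEDATIONLEVEL"),
             .pc(" (paradoxical response: no)")))
  if (runif(1) < rates$p_anti)
    add(list(.pc("Antispasmodics (cimetropium 5 mg): "),
             .pc(.pick(list("Yes", "No")), "ANTISPASMODICS")))
  if (runif(1) < rates$p_dre)
    add(list(.pc("Digital rectal examination was "),
             .pc(.pick(.lex_values(.lex$dre)), "DRE")))
  if (runif(1) < rates$p_prep)
    add(list(.pc("Bowel preparation was "),
             .pc(.pick(.lex_values(.lex$preparation)), "PREPARATION")))
  if (runif(1) < rates$p_extent) {
    if (runif(1) < rates$p_device)
      add(list(.pc("The "), .pc(.pick(.lex_values(.lex$device)), "DEVICE"),
               .pc(" was inserted up to the "),
               .pc(.pick(.lex_values(.lex$extent)), "EXTENT")))
    else
      add(list(.pc("The scope was inserted up to the "),
               .pc(.pick(.lex_values(.lex$extent)), "EXTENT")))
  }
  # colonoscopic findings (free text)
  add(list(.pc("Colonoscopic finding")))
  lesion_sent <- list()
  if (runif(1) < rates$a) lesion_sent <- c(lesion_sent, list(.sentence_A(rates)))
  if (runif(1) < rates$b) lesion_sent <- c(lesion_sent, list(.sentence_B(rates)))
  if (runif(1) < rates$d) lesion_sent <- c(lesion_sent, list(.sentence_D(rates)))
  has_biopsy <- runif(1) < rates$p_biopsy
  if (length(lesion_sent)) {
    # lesion sentence + optional biopsy clause share one line, exercising
    # the mid-line sentence splitter
    first <- lesion_sent[[1]]
    if (has_biopsy) first <- c(first, list(.pc(" ")), .sentence_biopsy())
    add(first)
    for (s in lesion_sent[-1L]) add(s)
  } else if (has_biopsy) {
    add(.sentence_biopsy())
  }
  if (runif(1) < rates$p_neg) add(.sentence_negation())
  if (!length(lesion_sent) && !has_biopsy)
    add(list(.pc("Otherwise, the examination was unremarkable.")))
  # conclusion (unannotated)
  add(list(.pc("Conclusion")))
  add(list(.pc(.pick(list("1. Colon polyp, removed", "1. Colonoscopy, checkup",
                          "1. No specific abnormality",
                          "1. Rectal polyp, removed")))))
  # assemble with newlines, shifting span offsets
  text <- ""
  spans <- list()
  for (ln in lines) {
    if (nzchar(text)) text <- paste0(text, "\n")
    off <- nchar(text)
    if (!is.null(ln$spans)) {
      sp <- ln$spans
      sp$start <- sp$start + off
      sp$end <- sp$end + off
      spans[[length(spans) + 1L]] <- sp
    }
    text <- paste0(text, ln$text)
  }
  list(text = text,
       spans = if (length(spans)) do.call(rbind, spans) else NULL)
}

#' Generate a synthetic annotated corpus
#'
#' Produces `n_documents` gold-annotated reports and an unlabeled text
#' corpus of `n_unlabeled` reports (a superset: the annotated texts plus
#' additional unannotated reports drawn from the same templates). The output
#' is a deterministic function of the configuration, including its seed.
#'
#' @param config A [generator_config()].
#' @return List with `documents` (list of `annotated_doc`) and `unlabeled`
#'   (character vector of report texts).
#' @export
#' @examples
#' corp <- generate_corpus(generator_config(n_documents = 3, n_unlabeled = 5))
#' length(corp$documents)
generate_corpus <- function(config = generator_config()) {
  rates <- .derive_rates(config)
  with_seed(config$seed, {
    docs <- vector("list", config$n_documents)
    texts <- character(max(config$n_unlabeled, config$n_documents))
    total <- max(config$n_unlabeled, config$n_documents)
    for (i in seq_len(total)) {
      rep <- .generate_report(rates)
      if (i <= config$n_documents) {
        d <- annotated_document(sprintf("synth%05d", i), rep$text, rep$spans)
        if (config$typo_rate > 0)
          d <- inject_noise(d, config$typo_rate, seed = config$seed + i)
        docs[[i]] <- d
        texts[i] <- d$text
      } else {
        texts[i] <- rep$text
      }
    }
    list(documents = docs, unlabeled = texts[seq_len(config$n_unlabeled)])
  })
}

# ---- noise injection -------------------------------------------------------

# Adjacent-character transposition; position is 1-based index of the left
# character.
.typo_transpose <- function(tok, pos) {
  paste0(substr(tok, 1, pos - 1L), substr(tok, pos + 1L, pos + 1L),
         substr(tok, pos, pos), substring(tok, pos + 2L))
}

.typo_double <- function(tok, pos) {
  paste0(substr(tok, 1, pos), substr(tok, pos, pos), substring(tok, pos + 1L))
}

#' Inject character-level typo noise into a document
#'
#' Applies transpositions and character doublings — the typo classes seen in
#' real reports (e.g. "bleeding" mistyped as "bleeingd") — only to tokens
#' that lie wholly outside any span or strictly inside one (never the first
#' or last token of a span), so every span keeps aligned, valid offsets.
#' Only lowercase alphabetic tokens of four or more characters are
#' perturbed, which protects structural anchors such as section headers.
#' The token count is never changed.
#'
#' @param doc An `annotated_doc`.
#' @param typo_rate Per-eligible-token perturbation probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A perturbed `annotated_doc` that still passes validation.
#' @export
inject_noise <- function(doc, typo_rate, seed = 1L) {
  stopifnot(typo_rate >= 0, typo_rate <= 1)
  if (typo_rate == 0) return(doc)
  sents <- tokenize_document(doc$text, doc$doc_id)
  toks <- do.call(rbind, lapply(sents, function(s)
    data.frame(start = s$starts, end = s$ends, token = s$tokens,
               stringsAsFactors = FALSE)))
  if (is.null(toks)) return(doc)
  with_seed(seed, {
    text <- doc$text
    spans <- doc$spans
    shift <- 0L
    for (r in seq_len(nrow(toks))) {
      ts <- toks$start[r] + shift
      te <- toks$end[r] + shift
      tok <- toks$token[r]
      if (nchar(tok) < 4L || !grepl("^[[:lower:]]+$", tok)) next
      inside <- spans$start < te & ts < spans$end
      eligible <- !any(inside) ||
        (sum(inside) == 1L && spans$start[inside] < ts &&
           te < spans$end[inside])
      if (!eligible) next
      if (runif(1) >= typo_rate) next
      pos <- sample.int(nchar(tok) - 2L, 1L) + 1L # interior position
      new_tok <- if (runif(1) < 0.5) .typo_transpose(tok, pos)
                 else .typo_double(tok, pos)
      delta <- nchar(new_tok) - nchar(tok)
      text <- paste0(substr(text, 1, ts), new_tok, substring(text, te + 1L))
      if (delta != 0L && nrow(spans)) {
        after <- spans$start >= te
        spans$start[after] <- spans$start[after] + delta
        spans$end[after] <- spans$end[after] + delta
        containing <- spans$start <= ts & te <= spans$end & !after
        spans$end[containing] <- spans$end[containing] + delta
      }
      shift <- shift + delta
    }
    spans$text <- NULL
    annotated_document(doc$doc_id, text, spans, origin = doc$origin)
  })
}

#' Corpus summary statistics
#'
#' Counts computed with the pipeline's own sentence splitter and tokenizer,
#' so generator output can be validated against its configured label
#' frequencies.
#'
#' @param docs List of `annotated_doc`.
#' @return List: `documents`, `sentences`, `tokens`, `word_types`,
#'   `label_counts` (named vector), `label_per_document`.
#' @export
corpus_statistics <- function(docs) {
  labels <- schema_labels(default_schema())
  zero <- stats::setNames(rep(0L, length(labels)), labels)
  if (!length(docs))
    return(list(documents = 0L, sentences = 0L, tokens = 0L, word_types = 0L,
                label_counts = zero, label_per_document = zero))
  nsent <- 0L
  ntok <- 0L
  types <- character()
  counts <- zero
  for (d in docs) {
    sents <- tokenize_document(d$text, d$doc_id)
    nsent <- nsent + length(sents)
    tk <- unlist(lapply(sents, function(s) tolower(s$tokens)))
    ntok <- ntok + length(tk)
    types <- unique(c(types, tk))
    tab <- table(d$spans$label)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  list(documents = length(docs), sentences = nsent, tokens = ntok,
       word_types = length(types), label_counts = counts,
       label_per_document = counts / length(docs))
}
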