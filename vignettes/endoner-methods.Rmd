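---
title: "Extracting colonoscopic findings from free-text reports: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting colonoscopic findings from free-text reports: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Colonoscopy reports mix two kinds of text. The procedure note is
semi-structured ("Level of sedation: moderate", "Bowel preparation was
fair"), while the colonoscopic findings are free prose ("On the distal
descending colon, about 0.5 cm sized Is polyp was noticed."). The
clinically important content — lesions, their anatomical site, size,
number, shape and color, the sampling performed, and statements of
absence such as "no evidence of tumor recurrence" — has to be recovered
from both. `endoner` treats this as named entity recognition (NER) over a
17-label schema: nine labels for the procedure note (SEDATION,
SEDATIONLEVEL, MEDICATION, DOSAGE, ANTISPASMODICS, DRE, PREPARATION,
DEVICE, EXTENT) and eight for the findings (LESION, LOCATION, SHAPE,
COLOR, SIZE, NUMBER, BIOPSY, NEGATION).

Entity spans are encoded per token in IOB2: `B-X` opens an entity of
label `X`, `I-X` continues it, `O` is outside. Two structural rules
define validity — `I-X` must follow `B-X` or `I-X` of the same label, and
an entity can never open with `I`. A separate `PAD` symbol aligns batch
matrices and is excluded from losses, metrics and predictions.

## Model

The tagger is a bidirectional LSTM with a linear-chain conditional random
field (CRF) output layer.

**Embedding layer.** Each word maps to a row of an embedding matrix. The
matrix can be seeded three ways: small-variance random initialization; a
one-hot basis matrix of vocabulary dimension (the no-pretraining
baseline); or CBOW word2vec vectors pretrained on a large unlabeled
report corpus. Pretraining matters in this genre because anatomical sites
appear under many surface forms — "D-colon", "DC", "Desc. colon" for the
descending colon; "T-ileum", "T.I." for the terminal ileum — and
distributional similarity ties the variants together before any labeled
example is seen. The layer is trainable by default; a freeze flag is
available and honored bit-exactly.

**Encoder.** A forward and a backward LSTM (hidden dimension 256 per
direction by default) read the sentence; their states are concatenated
per token and projected linearly to one unnormalized score per tag
("emissions"). The encoder sits behind a scores-per-token interface, so
the unidirectional and no-CRF variants share all other machinery, and a
different scorer could be plugged in without touching the CRF.

**CRF layer.** A linear-chain CRF scores a whole tag sequence as

$$s(y) = \mathrm{start}_{y_1} + \sum_t e_{t,y_t} + \sum_t T_{y_{t-1},y_t}
+ \mathrm{stop}_{y_T},$$

with learned transition matrix $T$. Training maximizes the sequence
log-likelihood $s(y^{gold}) - \log Z$, where $\log Z$ is computed by the
forward recursion in log space; decoding is Viterbi. Transitions are
learned unconstrained, but at decode time the structurally illegal IOB2
transitions (anything to `I-X` except from `B-X`/`I-X`) are masked to
$-\infty$, so the decoder cannot emit an invalid sequence regardless of
what was learned. Token-wise classifiers have no such mechanism, which is
the main reason the CRF variant dominates the `lstm`/`bilstm` baselines
in the package's own ablation tests.

**Losses and optimizers.** The `bilstm-crf` architecture always trains
with the CRF negative log-likelihood. The no-CRF variants use a token-wise
softmax with categorical cross-entropy, KL divergence (identical to
cross-entropy for one-hot targets, kept for completeness of the
configuration grid) or a Poisson loss. Optimizers: rmsprop (default),
adam, nadam.

All of this — LSTM forward/backward, CRF forward-backward and Viterbi,
the optimizers, and the CBOW trainer — is implemented in
Rcpp/RcppArmadillo inside the package, single-threaded and deterministic
for a fixed seed.

## Numerical choices

* Log-sum-exp with max-subtraction everywhere in the CRF; masked entries
  use a large negative constant rather than `-Inf` so differences never
  produce `NaN`. The forward recursion is exact to ~1e-14 against
  exhaustive enumeration and stable for scores in $[-50, 50]$.
* Viterbi ties break toward the lowest tag index. `O` is deliberately the
  first non-PAD tag, so an all-zero score matrix decodes to all-`O`; this
  makes cross-implementation comparisons reproducible.
* LSTM weights use Glorot-uniform initialization with forget-gate bias 1;
  gradients are clipped to global norm 5 (configurable, `clip = 0`
  disables).
* Sentences are bucketed by length into mini-batches; the backward LSTM
  runs on per-sentence reversed token streams so that padding is always
  trailing in both directions and pad positions can never influence real
  tokens. Pad positions are excluded from the loss by zeroing their
  emission gradients.
* Default learning rate 1e-3 and batch size 32 are package choices
  (documented as such); both are logged in the model bundle.

## Text processing under a no-reposition constraint

Cleaning must never change the number or position of words or sentences,
because gold annotations are character offsets. Concretely:

* Sentence splitting: a newline always ends a sentence; a period followed
  by whitespace and a capital ends one unless the preceding word is a
  known abbreviation ("Desc.", "no."), a single letter ("a."), or itself
  contains a period ("T.I."). Decimal sizes ("0.5 cm") never split
  because the period is not followed by whitespace.
* Tokenization is whitespace splitting followed by edge-punctuation
  stripping — never deleting, merging or splitting a token, so the token
  count equals the whitespace word count (asserted as a property test). A
  trailing period is stripped only when the token contains no other
  period ("noticed." → "noticed", but "T.I." and "a." survive); a token
  ending in a double period ("T.I.." at sentence end) loses exactly the
  outer one. Internal hyphens and periods are kept so "D-colon" and
  "T.I." stay single tokens.
* Words are lowercased for vocabulary and embedding lookup (reports mix
  "A-colon"/"a-colon"); surfaces and offsets keep the original case. The
  exact punctuation tables are package decisions, configurable in source,
  since no canonical list exists for this genre.
* The vocabulary reserves `PAD = 0` and `UNK = 1`; out-of-vocabulary
  tokens (typos, held-out-fold words) map to `UNK`.

## Evaluation

Scoring is entity-level. Because multi-token entities often differ from
the gold standard by one boundary token, the primary mode is **partial
matching**: a prediction matches an unmatched gold entity when the labels
are equal and the character ranges overlap by at least one character;
matching is greedy left-to-right and one-to-one. This is a package
definition — no formal one exists for this report genre — and an exact
mode is provided for sensitivity analysis; partial-match TP is provably
(and property-tested to be) at least exact-match TP. Label-mismatched
overlaps are never credited.

Precision, recall and F1 use the conventions P = TP/(TP+FP) (0 if the
denominator is 0), likewise R, and F1 = 2PR/(P+R) with 0 when P+R = 0.
Micro averages are always recomputed from summed counts, never averaged
from per-label metrics, so frequent labels carry proportional weight.

Cross-validation splits at the **document** level (a seeded shuffle into
near-equal folds), never at the sentence level, so sentences of one
report cannot leak across the train/test boundary. Each fold rebuilds the
vocabulary from its training documents. The pretrained embedding matrix
may be reused across folds because it is trained on the separate
unlabeled corpus, which carries no annotations — a non-leaking input by
construction. Fold aggregation pools counts (micro), matching how single
headline numbers are usually reported.

## The synthetic generator

No public colonoscopy corpus exists, so the package ships a generator
that emulates the report genre: a two-part document (semi-structured
procedure note, free-text findings, plus unannotated clinical-information
and conclusion lines), per-label frequencies proportioned to a reference
1,000-document distribution (LOCATION ≈ 1.12 spans per document down to
COLOR ≈ 0.20), negation sentences covering statements of absence, both
discontinuous-location phrasings ("ascending colon and descending colon"
as two entities versus "ascending and descending colon" as one — the data
model supports only contiguous spans), and character-level typo noise
(transpositions and doublings, the classes that produce real-report typos
like "bleeingd").

Design points worth flagging:

* **NEGATION scope.** The generator renders the full negated phrase ("no
  evidence of tumor recurrence") as the span, cue included. This is a
  package convention — the alternative (cue-only) is equally defensible —
  and is documented rather than asserted as the genre's ground truth.
* **Lexicons** seed from surface forms documented for this report genre
  and are extended with invented fillers; every entry carries a
  provenance flag (`paper`/`invented`) in the lexicon tables.
* **Rates derive from label weights.** Template probabilities are solved
  from the configured per-document label expectations, and
  `corpus_statistics()` recounts the generated corpus with the pipeline's
  own splitter and tokenizer; realized frequencies land within ±20%
  relative (typically ±5%) of the configuration for 500-document corpora.
* The generated English templated prose reproduces the *structure* of the
  genre, not clinical plausibility of lesion co-occurrence, institutional
  formatting, or real lexical sparsity (a real corpus has ~40k word
  types; the generator a few hundred). Consequently, high synthetic
  scores demonstrate that the pipeline recovers entities whose patterns
  it has seen, handles variant vocabularies and survives noise — they do
  not predict institutional-corpus performance, which is why the
  package's checks are property- and trend-based rather than targets on
  published numbers.

## Problem sizes used in the shipped checks

The acceptance checks run a 200-document annotated benchmark (an analog
of the reference 1,000-document dataset) with a 3,000-document unlabeled
corpus for CBOW, fivefold cross-validation at the full model size
(embedding 128, hidden 256, 10 epochs, rmsprop), and trend experiments
(architecture ordering, data-size monotonicity over 50/100/150 training
documents, pretrained-versus-one-hot at 50 documents) at a reduced
encoder (embedding 32, hidden 64, 8 epochs, learning rate 5e-3) averaged
over three seeds. These sizes are the package's choice of a
desk-reproducible experiment; the generator happily produces the full
1,000/10,000 configuration.

## Known limitations

* CBOW determinism is guaranteed only single-threaded; the implementation
  is single-threaded by design.
* The KL and Poisson losses exist for configuration-grid completeness;
  with one-hot targets KL is exactly cross-entropy.
* Subword modeling, nested/overlapping entities, relation extraction
  (e.g. linking a SIZE to its LESION) and transformer encoders are out of
  scope; the emission-scorer interface is the intended extension point
  for the latter.
* `read_annotations()` accepts the common JSON Lines dialects of web
  annotation tools (array triples or offset objects); truly exotic
  exports need a pre-mapping step.
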