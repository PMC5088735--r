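---
title: "Disease NER and normalization: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease NER and normalization: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnerlink)
```

`dnerlink` recognizes disease mentions in PubMed-style titles and abstracts
and links them to controlled-vocabulary concept identifiers (e.g. MeSH-like
IDs). This vignette describes the models the package implements, the
parameters that matter, the synthetic data it ships for end-to-end testing,
and the design decisions taken where more than one reasonable choice
existed.

## Task and data model

A *document* is a title and an abstract; its full text is the title, a
single space, then the abstract, and all annotation offsets are 0-based,
half-open character offsets into that full text (the convention of BC5CDR
PubTator distributions). A *mention* is a character span with an entity type
and a concept ID (`"-1"` when unlinked). Evaluation is

* **mention-level**: a prediction is correct iff a gold mention with the
  same `(document, start, end)` exists; precision/recall/F1 are pooled over
  the corpus;
* **concept-level**: each document contributes its *set* of distinct
  predicted concept IDs (excluding `"-1"`) against its gold ID set.

Sentence splitting and tokenization are rule-based and deterministic: a
terminator followed by whitespace and an uppercase letter or digit opens a
new sentence, except inside parentheses and after common non-breaking
abbreviations; a boundary that would bisect a gold mention is suppressed.
The tokenizer emits alphanumeric runs and single punctuation characters,
splitting hyphens ("ANCA-positive" becomes three tokens). Both are
deliberately simple, pluggable components — the interesting models sit above
them, and deterministic preprocessing keeps every downstream result exactly
reproducible. Mentions that do not land on token boundaries are snapped
outward to the smallest covering token span and reported via a condition,
never dropped silently.

## Base tagger 1: linear-chain CRF

Tokens carry BIO labels (`B`egin/`I`nside/`O`utside). The CRF defines

$$p(y \mid x) \propto \exp\Big(\sum_t \big[ w_{\mathrm{em}}^\top
\phi(x, t, y_t) + A_{y_{t-1}, y_t} \big]\Big)$$

with sparse binary emission features $\phi$ and a $3 \times 3$ transition
matrix $A$. Seven feature families are extracted per token, each with a
context window of radius $n$: the word itself, POS tag, chunk tag, word
shape (character classes mapped to `U`/`L`/`D`/`S`, so "delirium" is
"LLLLLLLL"), orthographic word type (AllDigit, AllUpper, UpperAndDigit, ...),
prefixes/suffixes of lengths 1–4, and two dictionary look-ups against a
disease lexicon: a per-word membership flag, and a BIO annotation produced
by greedy longest contiguous dictionary-term matching over normalized
(lower-cased, Porter-stemmed) tokens.

Window radii default to $n = 2$ for the word/POS/chunk/shape/type families
and $n = 1$ for the affix and dictionary families, each configurable between
1 and 3; positions beyond the sentence edge contribute `__BOS__`/`__EOS__`
sentinel values.

Training maximizes the L2-penalized conditional log-likelihood with L-BFGS
and analytic gradients from forward–backward expected counts (default
strength 1.0, iteration cap 200). Decoding is Viterbi with lexicographic
tie-breaking (B < I < O); per-token *confidence* is the posterior marginal of
the assigned label from forward–backward. All dynamic programming runs in
log space and is stable for weight magnitudes up to about 50. Tests verify
decode and marginals against exhaustive enumeration of all $3^T$ labelings
for short sentences, and gradients against central finite differences.

Two open interpretation points are worth recording. "Longest common
subsequence matching" for the dictionary BIO feature is implemented as
greedy longest *contiguous* term matching: a true LCS would allow gapped
matches, which cannot produce contiguous BIO spans. And "confidence" of a
CRF tagging is not uniquely defined; the per-token posterior marginal was
chosen (a per-sequence probability is the alternative) because the ensemble
consumes per-token features.

## Rule-based post-processing

Two recall boosters apply to CRF output; both only ever *add* mentions and
are idempotent.

1. **Repeated-entity propagation.** If the same surface string is tagged at
   least `min_count` times in one document, every other occurrence of that
   string (case-insensitive, at token boundaries) is also tagged. The
   trigger threshold is 2: the motivating example — "psychosis" tagged twice
   causes all its occurrences to be tagged — triggers at exactly two, so the
   stricter reading ("more than twice" = 3) was set aside; the threshold is
   configurable.
2. **Abbreviation resolution.** `<definition> (<abbreviation>)` patterns are
   detected with the Schwartz–Hearst right-to-left character alignment
   (short form 2–10 characters, at most two words, containing a letter,
   first character alphanumeric; definition at most
   $\min(|A| + 5,\, 2|A|)$ words). If the definition is a lexicon term after
   normalization *or* is itself already tagged, every occurrence of the
   abbreviation becomes a mention. Conversely, an undetected out-of-lexicon
   definition contributes nothing — "Opioid-induced hyperalgesia (OIH)" with
   an untagged definition leaves "OIH" untagged.

## Base tagger 2: bidirectional RNN

Each token is embedded (`D`-dimensional vectors, lower-cased lookup,
dedicated out-of-vocabulary vector). A forward and a backward simple
recurrence run independently until the output layer:

$$\vec h_t = f(U_f x_t + W_f \vec h_{t-1} + b_f), \qquad
\overleftarrow h_t = f(U_b x_t + W_b \overleftarrow h_{t+1} + b_b),$$
$$y_t = \mathrm{softmax}\big(V\,[\vec h_t ; \overleftarrow h_t]\big).$$

Design choices: the activation $f$ defaults to `tanh` (logistic sigmoid
available; gated units are out of scope); the output layer consumes the
*concatenation* of the directional states — concatenation rather than
summation is forced by the ensemble below, which consumes exactly that
$2H$-dimensional "penultimate layer" as a feature; initial states
$\vec h_0$ and $\overleftarrow h_{T+1}$ are zero vectors (a recursive-copy
initialization is sometimes described but is ambiguous, and zero
initialization is standard and testable); weights initialize uniformly on
$(-0.08, 0.08)$ from an explicit seed.

Training is per-sentence Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, learning
rate configurable) on the token-level cross-entropy, with inverted dropout
(rate 0.25) applied to the input embedding sequences in training mode only.
Backpropagation through time is analytic and verified against central
finite differences; training is bit-reproducible given the seed. When a
validation set is supplied, its log-likelihood is recorded every epoch for
convergence monitoring. The label is the argmax of $y_t$ and the confidence
its maximal component.

Embeddings come either from a whitespace-delimited text file (one
`token v1 ... vD` line per word, count header tolerated) or from the bundled
toy skip-gram trainer: skip-gram with negative sampling over the training
corpus, unigram$^{0.75}$ negative distribution, seed-deterministic. It
stands in, at desk scale, for vectors pre-trained on a large literature
corpus; it reproduces the qualitative property that matters here (words with
shared contexts get similar vectors) but not the semantic coverage of real
pre-trained embeddings.

Reference settings are $H = 500$, $D = 300$; the package's test and example
configurations use $H = 32$, $D = 16$, which the synthetic task is
comfortably learnable at.

## Combining the taggers with an SVM

Every token is one classification instance with feature blocks: one-hot
labels of both base taggers (CRF side: *after* post-processing, following
the system's architecture; configurable), both confidences, both base
error rates, one-hot POS tag, the two dictionary look-up features, and the
Bi-RNN penultimate-layer state ($2H$ values). The base error rate is the
k-fold cross-validated token misclassification rate on the training
documents (default k = 5; the pipeline uses k = 3 with reduced fold budgets)
— resubstitution would report a near-zero rate for any memorizing base
model. "Weighted confidence" is realized by including the error-rate block
alongside the raw confidences rather than pre-multiplying them, since the
weighting arithmetic is otherwise unspecified.

The combiner is a multi-class RBF-kernel SVM (C = 1, $\gamma = 1/\dim$,
features standardized, class weights balanced because O dominates),
deterministic given seed and data order. Predicted label sequences get a
BIO repair (orphan `I` becomes `B`) before span extraction.

## Normalization

Each concept's preferred name plus all synonyms form one *concept
document*; mentions are queries. Both sides are tokenized, lower-cased and
Porter-stemmed. Weighting is raw term frequency times
$\mathrm{idf}(t) = \ln(N/\mathrm{df}(t))$ ($N$ = number of concepts); no
smoothing is needed since every indexed term occurs in at least one
document; query terms unseen in the index contribute zero. Candidates are
ranked by cosine similarity; a top score of exactly 0 yields `"-1"`
(unlinked). Exact ties are resolved by ascending concept ID — a
deterministic deviation from random tie-picking, chosen because
reproducibility matters more here; a seeded random mode is provided.
log-tf and L2-normalized tf variants were considered and rejected in favor
of the simplest variant consistent with the description. Composite IDs for
coordinated mentions ("vision and hearing loss") are out of scope.

## Synthetic data: what it emulates and what it does not

The generator builds, from a fixed seed, a lexicon of 2–3-word disease
names over a modifier/site/head morpheme inventory with a *unique head word
per concept*, synonym variants (word reordering, "syndrome"/"disorder"
suffixes) and the abbreviation formed from the name's initials
(uniqueness enforced on the stemmed form so normalization can never
conflate two concepts). Documents are template sentences with injected
mentions carrying gold offsets and concept IDs, plus:

* "long form (ABBR)" definitions followed by bare "ABBR" mentions
  (probability 0.5 per document), exercising abbreviation resolution;
* concepts repeated at least twice within one abstract (probability 0.5),
  exercising propagation;
* pseudo-drug distractor tokens and "trap" tokens (modifier words occurring
  both inside and outside entities), so that single-word dictionary hits do
  not identify entities;
* with probability 0.25, a mention rendered with a leading intensifier
  ("marked", "persistent", ...) that belongs to the gold span but to no
  lexicon term — the dominant boundary-error mode of gazetteer matching on
  real abstracts, and the reason the trained CRF beats the raw dictionary
  baseline here.

A `label_noise` option (default 0) drops a fraction of gold annotations for
robustness experiments.

By construction every gold surface still retrieves its own concept at
rank 1, so concept-level scores track mention-level quality. That is the
headline caveat: the synthetic task has a closed vocabulary, unambiguous
concepts and templated syntax. Passing the end-to-end recovery test shows
the machinery is correct and the ensemble does not damage good base output;
it does not estimate performance on real abstracts, where reported
mention-level F1 for systems of this architecture is in the low-to-mid
80s rather than the high 90s seen here.

## Pipeline, problem sizes and reproducibility

`run_pipeline()` executes: generate/split, featurize, CRF train/tag,
post-process, embeddings + Bi-RNN train/tag, error-rate estimation,
combiner training (on the base taggers' training-corpus output), combining,
normalization, both evaluations, and a JSON report carrying every setting
and seed. Every stage derives its own sub-seed from the master seed, so
equal configurations reproduce byte-identical corpora, models, tags and
reports. The report asserts internally that post-processing never lowered
mention-level recall.

The standard study configuration used by the acceptance checks is 300
documents (200 train / 100 test), a 30-concept lexicon, and desk-scale
model sizes ($H = 32$, $D = 16$, CRF iteration cap 100, 25 Bi-RNN epochs,
k = 3 error-rate folds with reduced fold budgets of 40 L-BFGS iterations /
8 epochs). At these sizes a full run takes a few minutes on one CPU.

## Known limitations

* The POS/chunk tagger is a small rule-based stand-in behind a pluggable
  interface; its tags are coarse.
* Overlapping or discontinuous mentions are out of scope, as are composite
  concept IDs and abbreviation disambiguation across documents.
* The Bi-RNN has one hidden layer per direction and no gated units; the
  simple recurrence limits very long-range dependencies (sentences here are
  short).
* Dictionary matching and normalization share one normalizer (lower-case +
  Porter); terms that stem together are indistinguishable to both.
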