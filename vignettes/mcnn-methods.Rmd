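---
title: "Window-based convolutional disease NER with a multiple label strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based convolutional disease NER with a multiple label strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcnn)
```

## The model

Disease named entity recognition (DNER) locates disease mention spans in
biomedical abstracts; spans are encoded per token with the BIO scheme
(`B`egin, `I`nside, `O`utside) and evaluated at the mention level by exact
character-span match. Most sequence taggers treat this as a sentence-level
decoding problem and add a CRF layer. The model implemented here takes the
opposite view: the label of a token is a *word-level classification* decided
from a fixed window of context, and label-transition structure is injected
purely through the training objective.

For a centre token with window $w = 13$, each window position is represented
by the concatenation of

* a **word-level embedding** (200 dims) looked up on the lowercased,
  number-normalized token surface,
* a **character-level representation** (20 dims): character embeddings
  (20 dims each) passed through a width-3 convolution with 20 filters and a
  max over positions, capturing prefix/suffix morphology and rare-word shape,
* a **lexicon feature embedding** (5 dims): the embedded B/I/O tag assigned
  by greedy leftmost-longest dictionary matching against a disease
  vocabulary (MEDIC-style, or any term list).

The $13 \times 225$ window then passes through a stack of **pooling-free**
width-3 "valid" convolutions with 100 filters and ReLU, shrinking
$13 \to 11 \to 9 \to 7$ positions over the default 3 layers (4 layers,
ending at 5, fit larger corpora). There is deliberately no pooling in this
stack: shift invariance is not wanted when the relative position of context
around the centre token is the signal. The surviving positions are flattened
(length 700 by default) and feed two affine heads:

* the **main head** (3 scores): the centre token's own label;
* the **auxiliary head**: the *multiple label strategy* (MLS). It predicts
  the (previous, next) token label pair, by default as one joint softmax
  over the $3^2 = 9$ pair classes.

With softmax probabilities $p_{main}$ and $p_{aux}$, training maximizes

$$J(\theta) = \sum_i \log p_{main}(y^{(i)} \mid x^{(i)}, \theta)
            + \sum_i \log p_{aux}(y_{aux}^{(i)} \mid x^{(i)}, \theta),$$

so label correlations (e.g. that `O` is never followed by `I`) shape the
shared representation without a transition matrix or Viterbi decoding. At
prediction time the auxiliary head is discarded and each token takes the
argmax of the main head. Setting `mls = FALSE` in `mcnn_config()` removes
the second sum, leaving plain 3-way cross-entropy (the package tests verify
this equivalence exactly).

### Why a joint 9-class auxiliary head

The auxiliary target is one ordered pair drawn from $\{B,I,O\}^2$. A single
softmax over the 9 pair classes matches the form of the auxiliary
distribution (one normalized distribution over all auxiliary outcomes) and
lets the head model the *joint* of the two neighbours. The alternative —
two separate 3-way softmaxes — is available as `aux_mode = "pair"` and is
gradient-checked too; the joint head is the default.

## Preprocessing

Sentences are split on `.?!` followed by whitespace and a capital, with a
configurable abbreviation exception list; splitting is deliberately crude
because the tagger itself never crosses a window of 13 tokens. Tokens are
split on whitespace and on a delimiter set
`/ − - > < ; : ? [ ] { } ( ) ! @ # $ % ^ & * + , .`; delimiters are *kept*
as single-character tokens so hyphens and parentheses inside mention spans
survive and exact spans can be reconstructed. One exception: a period
between two digits is a decimal point and does not split, so `81.6` stays
one token. Whole tokens matching an optionally signed integer/decimal
pattern get the normalized surface `num` (offsets and original text are
never touched); in the sentence
*"164 patients (mean age +/- standard deviation [SD] 81.6 +/- 6.8 years)
were admitted"* exactly the three tokens `164`, `81.6`, `6.8` normalize.
Word-level lookup uses the lowercased normalized surface; the character CNN
sees the original cased text, delegating case information to morphology.

Gold mentions that cross a detected sentence boundary force a sentence
merge, which preserves exact-span evaluability. Overlapping gold mentions
(BIO cannot encode overlaps) are resolved leftmost-longest-first with a
warning.

## Post-processing

Raw per-token decisions can produce ill-legal BIO sequences. The repair rule
sets every `I` whose predecessor is neither `B` nor `I` to `O`, left to
right until stable; the operation is idempotent. Under standard BIO
semantics two adjacent `B` tokens are two legal single-token mentions, so
the additional `B,B -> B,O` repair is gated behind `strict_bb = TRUE`
(default off). Second, abbreviation definitions are recovered with the
Schwartz–Hearst parenthesis alignment heuristic (short form 2–10 characters
with a letter, characters aligned right-to-left into the preceding tokens,
long form at most $\min(|SF|+5, 2|SF|)$ words); when a recognized mention
exactly matches a long form, every occurrence of its short form in the same
document becomes a mention unless the span is already covered. Propagation
is document-scoped and never removes a mention.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window` | 13 tokens | context fed to the classifier (odd) |
| `word_dim` / `char_dim` / `lex_dim` | 200 / 20 / 5 | embedding dimensions |
| `char_cnn_window`, `char_cnn_filters` | 3, 20 | character CNN shape |
| `conv_window`, `conv_filters` | 3, 100 | word-level convolution shape |
| `n_conv_layers` | 3 | stacked convolutions (4 for larger corpora) |
| `dropout` | 0.5 | after embedding concatenation and on char embeddings |
| `lr`, `batch_size`, `epochs` | 0.1, 128, 10 | SGD settings |

The architecture defaults are the published configuration for this model
family. The optimizer settings are this package's own: gradients are
averaged per batch and plain SGD is used; with that normalization a
learning rate of 0.01 stalls in the all-`O` marginal solution at CPU-scale
epoch counts, while 0.1 converges cleanly on the synthetic generator, so
0.1 with 10 epochs was fixed once as the default (the acceptance script
demonstrates the resulting held-out performance). When a development set is supplied, mention-level
F is computed after every epoch and the best epoch's parameters are kept.

## Numerical choices

* Softmax uses max-subtraction; probabilities sum to 1 within 1e-9.
* Convolution and head weights use Glorot-uniform initialization, biases
  zero, embeddings uniform in ±0.05; all randomness (initialization,
  shuffling, dropout) flows from `config$seed`.
* Dropout is "inverted" (activations scaled by $1/(1-p)$ at train time), so
  inference needs no rescaling. The character CNN computes one
  representation per unique word form per batch; the dropout mask is
  therefore shared across window positions holding the same form, a
  deliberate efficiency choice.
* Prediction ties break toward `O`, then `B` — an untrained zero-weight
  model abstains rather than hallucinate mentions.
* Backpropagation is hand-written; a finite-difference check over every
  parameter block of a tiny model (`mcnn_gradient_check()`) holds the
  maximum relative error under 1e-4 (biases are randomly jittered there
  because a ReLU pre-activation of exactly zero is a kink where one-sided
  analytic and central numeric derivatives legitimately differ).
* `window - n_conv_layers * (conv_window - 1) >= 1` is validated up front.

## The synthetic generator

Real DNER corpora cannot be redistributed here, so `gen_lexicon()` /
`gen_corpus()` create seeded corpora that emulate their load-bearing
features: multi-token disease mentions (1–5 tokens, weighted toward short
mentions), mention-internal hyphens (exercising delimiter retention),
partial lexicon coverage (default 0.7: 30% of mention types are absent from
the emitted dictionary, so the model cannot just copy the lexicon feature),
parenthesized abbreviation definitions whose short forms recur later in the
document, and numeric noise tokens. Disease-name words are built from a
syllable inventory disjoint from the distractor vocabulary, which makes the
task learnable by construction.

What the generator does **not** emulate: real biomedical language (no
ambiguous words that are diseases only in context, no coordination
ellipses, no nested mentions, no concept identifiers), realistic
class-imbalance at corpus scale, or annotation noise. Passing the
end-to-end tests therefore shows the *machinery* — encoding, optimization,
decoding, post-processing, evaluation — is correct and that the model can
exploit lexical, dictionary and character evidence; it does not certify
corpus-level accuracy on NCBI/CDR-class data, which additionally depends on
pre-trained word vectors and long GPU training runs.

Test and acceptance problem sizes were chosen to keep a full run on one CPU
in minutes: 2,000 training / 500 held-out sentences for the learnability
check (the model reaches mention F ≥ 0.90 there), 320-sentence corpora over
3 seeds for the MLS legality comparison, and tiny window-5 models for
gradient checks.

## Known limitations

* Windows never cross sentence boundaries; out-of-sentence positions are
  padding and their labels count as `O` for the auxiliary target.
* The lexicon matcher is exact (after normalization); no fuzzy matching.
* Training is plain SGD without momentum or rate decay; very large corpora
  would likely want both, plus the 4-layer configuration.
* `read_pubtator()` expects the title + `" "` + abstract offset convention
  of the public disease-corpus releases; BioC XML is out of scope.
* Concept-level normalization (MeSH/OMIM identifiers) is out of scope; the
  `type` column is carried but only one type is modelled at a time.
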