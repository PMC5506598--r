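---
title: "Sequence labeling for clinical entity recognition: model, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence labeling for clinical entity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nerlstm` recognizes typed entity mentions in free text with a
bidirectional peephole-LSTM encoder and a linear-chain CRF. This vignette
is the package's account of the method: the model and its assumptions, the
parameters that matter, what the synthetic corpus generator does and does
not emulate, and the numerical and design choices that were genuinely open.

## Task and text processing

Entity recognition is cast as sentence-level sequence labeling. Documents
are split into sentences by four terminators — newline, `.`, `?`, `!` —
with no abbreviation list: a period always ends a sentence. This
over-splits around honorifics and decimal-free abbreviations, which is
accepted deliberately; the tagger never sees cross-sentence context, and a
reproducible two-rule splitter is worth more here than a heuristic one.
Tokens are maximal runs of a single character class (letters, digits,
other) within whitespace-delimited chunks, so `4/16/91CPT Code:` becomes
`4 / 16 / 91 CPT Code :`. This aggressive class-splitting is what makes
digit-pattern PHI (dates, record numbers) visible to the model as short
token patterns. All offsets in the package are 0-based and half-open, and
annotations are character spans against the raw document, so they survive
re-tokenization.

Mentions are encoded per sentence as BIOES tags. Encoding demands exact
token alignment and non-overlap and fails loudly otherwise, because silent
misalignment corrupts training data. Decoding never fails: model output may
be structurally invalid, and the repair policy — scan left to right, open a
mention at `B-t` or an orphan `I-t`/`E-t`, close at `E-t`, before an
`S`/`O`/type change/new `B`, and at sentence end — is deterministic and
never discards predicted entity evidence. Annotations that cross a sentence
boundary have no well-defined tag encoding in this scheme; the package
requires sentence-internal mentions and reports violations rather than
guessing.

## Input layer

A word representation is the concatenation of a token-level vector and an
optional character-level vector.

Token vectors come from an embedding table: either loaded from word2vec
text format (typically pre-trained on a large unlabeled corpus) or
initialized uniformly at random. Lookup backs off from the exact surface to
its lowercased form before falling to UNK. Clinical text is case-noisy and
pre-trained vocabularies are usually lowercased, so the back-off recovers
many forms; the cost is conflating genuinely case-distinct tokens, a
divergence of unknown direction that we accept and document. Digits are
*not* normalized: date and identifier recognition depends on raw digit
patterns, which the character models must see. The UNK vector is the mean
of the loaded vectors — deterministic, and it keeps unknown words inside
the embedding cloud rather than at a random corner.

Character-level vectors come in two flavours, selected by the `mode`
argument (`token`, `char-lstm`, `char-cnn`, `both`):

* **char-LSTM**: a bidirectional LSTM over the character embeddings of the
  word; the representation is the concatenation of the final forward and
  final backward hidden states (2 × 25 dimensions at defaults).
* **char-CNN**: the embedding sequence is zero-padded by `⌊k/2⌋` on each
  side, each of F width-k filters is slid over all positions with a
  per-filter bias, and responses are max-pooled over positions. Max is the
  standard pooling choice for character CNNs. No nonlinearity is applied
  after convolution or pooling: the linear-plus-bias reading is the minimal
  one, and we flag that an activation there is a defensible variant we did
  not take.

Character embeddings are initialized uniformly in [-1, 1] and the alphabet
is built from training data plus a reserved UNK character, so unseen test
characters cannot crash inference. Both embedding tables are trainable:
gradients flow into exactly the rows that were looked up.

## Encoder and inference layer

The encoder is a bidirectional peephole LSTM. The gates read the memory
cell element-wise (diagonal peepholes): input and forget gates read
`c_{t-1}`, the output gate reads `c_t`. We read the peephole weights as
vectors, not full matrices — the standard Graves-style reading, which also
keeps the parameter count sane. Initial states are zero; the context at
position t is the concatenation of the two directional hidden states.

The CRF scores a label sequence as `Σ_t θ_{y_{t-1} y_t}ᵀ h_t`: a full
weight vector per ordered transition, dotted with the context vector. This
transition-specific emission parameterization is the package's default
(`crf_parameterization = "pairvec"`) because it is the formulation the
architecture is built around; the common factorization into per-label
emission vectors plus scalar transition weights is implemented as
`"factored"` for comparison. A distinguished START symbol supplies `y_0`
and there is no STOP transition — the score sum runs `t = 1..n` only.
Chains are first-order.

All likelihood computation happens in log space with log-sum-exp
stabilization at every forward step. Viterbi decoding breaks ties toward
the lowest label index at each backtracking step, which makes decoding
fully deterministic (on an all-tied lattice the decode is the all-first-
label sequence). Invalid BIOES transitions are *not* masked in the lattice
by default: repair happens at decode time instead, so the probabilistic
model stays unconstrained. An optional hard mask
(`mask_invalid = TRUE`) adds a large negative constant (−1e30, not −Inf,
to avoid NaN arithmetic in the recursions) to structurally impossible
transitions; note a transition-local mask cannot force entity closure at
sentence end, which remains the repair step's job. The softmax reduction —
classify each position independently by `argmax_y w_yᵀ h_t` — is provided
as the non-structured baseline and may emit invalid sequences by
construction.

CRF gradients are empirical minus expected transition features, with
expectations from forward-backward pairwise marginals; the same pass
returns per-position marginals (they sum to one, which the tests assert)
and the log-likelihood.

## Training

Training is per-sentence stochastic gradient descent, batch size one,
constant learning rate, no momentum — nothing beyond plain SGD is assumed.
Dropout (inverted, so inference needs no rescaling) is applied at exactly
two places: on the word-representation input to the encoder and on the
encoder output before the CRF, not inside recurrences and not on the
character sub-networks. Gradients of the whole parameter set — CRF, both
encoder directions, character models, and the touched embedding rows — are
clipped jointly by global L2 norm; a single clipping scalar reads most
naturally as a global-norm rule. Sentences are reshuffled every epoch under
the run seed, and every random draw (initialization, shuffling, dropout)
derives from that one seed, so a run is exactly repeatable.

Defaults follow the hyperparameters the architecture family is usually run
with: token embedding 50, character embedding 25, character LSTM 25,
character CNN 25 filters of width 3, token LSTM 100 per direction, dropout
0.5, learning rate 0.005, clipping 5.0, 50 epochs (30 or 55 fit related
task settings; the epoch count is ordinary configuration). Weight matrices
initialize uniformly in the symmetric Glorot range, biases at zero except
the forget-gate bias at one (so early training does not erase the cell
state), a conservative convention chosen because nothing in the
formulation pins initialization down. When a development corpus is
supplied, the checkpoint with the best dev exact-F1 is returned; otherwise
the epoch count is fixed. Cross-validated hyperparameter search is out of
the default path.

## Evaluation

`evaluate_corpus()` reports micro-averaged precision, recall and F1 —
counts are summed globally before ratios are formed — under five criteria:
exact (same boundary and type), inexact (overlap and same type), span
(overlap), type (overlap and same type), and token (exact matching of
covered (document, token span, type) triples under the shared
tokenization). Overlap-based criteria use greedy one-to-one matching:
candidate pairs ordered by decreasing overlap length, ties by earlier gold
then earlier predicted start, each mention matchable once. One-to-one
matching is a deliberate design decision — allowing a single prediction to
match many gold mentions would inflate recall — and since official scorer
internals for such criteria are generally not published, we define and test
this deterministic policy instead and flag it as a possible divergence.
The `type` criterion is computed as an F1 like the others (where a source
reports it as an accuracy, that reading is noted but not implemented).
Zero-denominator conventions are fixed at 0 and unit-tested.

## The synthetic corpus generator

Real clinical corpora with entity annotations sit behind data-use
agreements, so the package generates its own study material.
`generate_corpus()` emits documents of short sentences of nonsense carrier
words (a closed vocabulary of pronounceable syllable strings) with typed
entity mentions embedded at random positions, plus standoff annotations
that align with the package tokenizer by construction. Entity surfaces
carry morphology cues: `problem`/`test`/`treatment` heads end in
type-specific suffixes (`-itis`, `-ase`, `-cillin`), `date` is a `d/dd/dd`
digit pattern, `id` a six-digit number; a fraction of suffixed mentions
take a known modifier word, producing multi-token B/I/E spans. Carrier
words are filtered so none ends in a cue suffix. The `oov_rate` knob makes
that fraction of *test-split* entity heads freshly generated — same
morphology, never seen in training — which isolates exactly the property
character-level representations are meant to contribute: recognizing an
entity from its shape rather than its identity. Sentence terminators are
mixed (`.`, `?`, `!`, bare newline) and commas are occasionally attached
to carrier words so the generator exercises the splitter and tokenizer,
not only the model.

Defaults (20 documents of 3–6 sentences, carrier vocabulary 80, entity
density 1.0 per sentence, 30% multi-token mentions, five entity types)
are chosen to look like short clinical-note sentences at a size where the
whole pipeline trains in seconds. Carrier and lexicon draws use sub-seeds
derived independently from the master seed, so changing one knob does not
reshuffle unrelated material; train and test splits are disjoint at
document level. What the generator does *not* emulate: real clinical
vocabulary and its Zipfian distribution, annotator disagreement,
section structure, misspellings, and entity mentions whose type is cued
only by context. Passing tests on this material therefore demonstrates
mechanical correctness and the morphology effect, not clinical-grade
accuracy on real notes.

## Problem sizes used by the tests and acceptance script

The verification suite runs at deliberately small scale, chosen so each
check finishes in seconds to a few minutes while still exercising every
code path: enumeration oracles up to 6 positions and 5 labels (at most
15,625 sequences), gradient checks at hidden sizes ≤ 4 over 50+ sampled
scalars, memorization of a 50-sentence corpus (token mode, 10-dimensional
embeddings and hidden states, learning rate 0.05 — small models need a
larger step than the full-size default), and the character-benefit
comparison on 12-document corpora with `oov_rate = 1`, 12 epochs, three
seeds per mode. These experiments measure directions and invariants
(char modes beat token-only on OOV morphology; decoding is exact;
gradients are right), not the absolute scores a full-size model reaches on
real corpora.

## Known limitations

* Pure-R training is practical at the test scales above and for small
  corpora; full-size hyperparameters on large corpora would want a
  compiled backend.
* The sentence splitter's abbreviation-blindness and the tokenizer's
  aggressive class-splitting are fidelity choices; both over-segment
  prose.
* No minibatching, learning-rate schedules, momentum or adaptive
  optimizers; no higher-order CRFs, semi-Markov decoding or n-best lists;
  no word2vec training (tables are loaded or random-initialized).
* Whether dropout should also cover the character sub-networks, and
  whether the character CNN should carry a nonlinearity, are open variants
  deliberately not taken; both places are single functions if a user wants
  to experiment.
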