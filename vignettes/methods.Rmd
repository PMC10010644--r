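---
title: "Two-language-model chest X-ray report generation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-language-model chest X-ray report generation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`raycap` implements a report-generation framework for chest radiographs
built from two cooperating language models:

1. **An attention captioner** ("show, attend and tell" family): a CNN
   encoder produces a grid of `N = D x D` spatial feature vectors
   `a = {a_1, ..., a_N}`, `a_i` of dimension `C`; an LSTM decoder emits the
   report word by word, at each step attending over the grid.
2. **A decoder-only transformer language model** over byte-pair-encoded
   subwords, fine-tuned self-supervised on report text.

The two models are combined in two ways. *Approach 1* learns a joint
next-word distribution: at each step the captioner's word scores and the
transformer's scores (discretized onto the word vocabulary) are
concatenated and passed through a small feed-forward head.  *Approach 2*
stacks them: the transformer continues the caption emitted by the
captioner, from a start-of-continuation marker appended to the caption,
until it emits its end-of-text token.

Everything runs on one CPU: the models are trained by a compact
reverse-mode automatic differentiation engine included in the package
(`R/autograd.R`), with Adam and optional global-norm gradient clipping.

## The captioner in detail

At step `t`, with previous hidden state `h_{t-1}`:

* attention scores `e_i = w' relu(U a_i + V h_{t-1} + b)` for every
  location `i`; weights `alpha_t = softmax(e)` (they sum to 1 by
  construction, asserted in every decode path); soft-attention context
  `\hat a_t = sum_i alpha_{ti} a_i`, a convex combination of location
  features;
* LSTM gates `[i, f, o, g]` from a single affine map of
  `[E z_{t-1}; h_{t-1}; \hat a_t]` (embedding of the previous word, the
  previous hidden state, the context), then `c_t = f * c_{t-1} + i * g`,
  `h_t = o * tanh(c_t)`;
* a *deep output layer*
  `P(z_t) = softmax(L_o (L_h h_t + L_a \hat a_t + E z_{t-1}))`;
* `h_0` and `c_0` come from two separate one-layer perceptrons (tanh)
  applied to the mean location feature.

Training is teacher-forced cross-entropy: the ground-truth previous word
is always fed, captions are framed by start/end tokens, padded, and
sorted by decreasing length so that at each time step only the effective
batch (sequences still active) is processed; pads never contribute to the
loss.  The loss is plain cross-entropy — no attention regularizer is
used, on the argument that chest anatomy occupies stable positions across
images, so encouraging attention to spread over the whole image is
counterproductive for radiographs.

Inference is greedy (argmax per step, ties to the lowest token id) or
K-beam search (length-synchronous, hypotheses retired at the end token,
ranked by total log-probability).  Model selection during pipeline
training uses the geometric mean of BLEU-1..4 on validation captions.

## Encoder design

The default backbone is a compact 3-block CNN trained from scratch
(desk scale); the large pretrained backbones used at full scale
(DenseNet-121 with C = 1024, VGG-16 with 512, ResNet-101/InceptionV3 with
2048) are supported as pluggable feature functions followed by the same
adaptive average pooling.  Three design choices matter and were made
deliberately after studying how the spatial statistics of phantom images
interact with attention learning:

* **Reference subtraction.** Chest radiographs are approximately
  spatially aligned, so the stem subtracts a reference image (the mean
  training image) before downsampling.  Without it, the shared anatomy
  dominates every pooling statistic: the maximum and the softmax
  concentrate on anatomy that is identical across images, the gradient
  signal of small lesions is diluted by a factor `1/N`, and both caption
  conditioning and attention stall at the label prior.  With it, focal
  abnormalities become the dominant signal.
* **Coordinate channels.** The last convolution block receives two extra
  channels holding the normalized (row, col) of each cell.  A shallow
  network lacks the large receptive fields through which deep backbones
  become position-aware; with coordinates, "bright region inside the left
  lung field" is expressible.
* **Optional global-context channels** (`global_channels` in
  `encoder_new()`): a learned projection of the location features,
  max-pooled over the grid and appended to every location.  These help
  pure memorization but are *disabled by default*: being identical at
  every location, they let the decoder read label evidence through the
  context vector regardless of where attention points, which removes the
  incentive for attention to localize.  When enabled, `sat_config_for()`
  excludes them from the attention context (they still reach the init
  MLPs through the feature mean).

An optional pretraining stage (`encoder_pretrain()`) trains the CNN to
predict the lesion labels with a position-specific linear head — the
analogue of the classifier-pretrained encoders used at full scale.  The
default pipeline does not need it once reference subtraction is in place.

## Attention heatmaps and localization

Per-step attention weights are reshaped to the `D x D` grid (row-major)
and bilinearly upsampled to image size; in mass-preserving form each map
sums to ~1 and the attention mass inside a lesion mask can be compared
with the mask's area fraction (the uniform-attention baseline).
Localization is measured at the step that predicts the pathology word
(the label token naming the lesion): that is the step where the image
alone determines the word — later mentions of the pathology are largely
predictable from the preceding text, so attention carries no image
information there.

## The transformer side

Byte-pair encoding is learned by greedy merge counting over a
word-frequency table (ties broken lexicographically, early stop when no
pair repeats), with an end-of-word marker per word and byte-fallback
symbols for characters outside the training set, so encoding never emits
an unknown token and decoding inverts encoding up to whitespace
normalization.

The language model is a pre-norm decoder-only transformer: learned token
and positional embeddings, masked multi-head self-attention (strictly
causal: position `t` depends only on positions `<= t`), position-wise
feed-forward blocks, and a linear head.  Fine-tuning is self-supervised
next-token cross-entropy with Adam and gradient-norm clipping at 1.0.
Because inference conditions on "caption text + start-of-continuation
marker", training inserts the marker at a per-epoch sampled split point
of each document, teaching the model to continue any prefix.  Following
the reading that the second-ranked beam hypothesis is used as the
continuation, `continue_report()` returns rank 2 by default, falling
back to the best hypothesis when the beam is narrower.

## Fusion

For Approach 1 the transformer's next-step distribution is discretized
onto the word vocabulary: each word's score is the log-probability of its
greedy BPE segmentation continued from the current transformer context
(chain rule over subword steps); the word-level end token maps to the
transformer's end-of-text token.  Scores from both models are
log-probabilities (commensurable scales) concatenated into a `2W` vector
and passed through a one-hidden-layer head (`2W -> W -> W`, ReLU) with a
softmax.  The head is trained teacher-forced with both backbones frozen.
Both models advance with each chosen word; emitted words are restricted
to the word vocabulary by construction — the discretization cost of this
approach.  Approach 2 needs no extra training; its output always begins
with the captioner's text verbatim and carries provenance markers
separating seed from continuation.

## The phantom corpus

The phantom simulator stands in for the access-restricted radiograph
corpora used at full scale.  Each sample is a pure function of
`(seed, index)` (per-sample seeds are hashed, so random access is
reproducible): a fixed parametric torso/lung/heart template, zero to two
planted pathologies — focal lung opacities (bright Gaussian blobs with
jittered position and size), an enlarged cardiac silhouette, a support
device line — additive Gaussian noise (`sigma = 0.03` gray levels), and
values clipped to [0, 1].  Lesion frequencies are 30% no-finding, 50%
one lesion, 20% two, a deliberately balanced mix rather than the
normal-dominated distribution of real archives.  Reports come from a
template grammar: one findings sentence per pathology drawn from 2-3
surface variants (chosen deterministically from the sample seed), a fixed
normal sentence for no-finding samples, an impression line, and the label
tokens prepended to the text — emulating label-prefixed ground truth
reports.  Images are stored as float32 `(n, 1, 224, 224)` in HDF5;
reports as JSON-lines.

What the phantoms do *not* emulate: anatomical variability between
patients, texture, projection and exposure differences, label noise, and
the strong class imbalance of real corpora.  Passing tests on phantoms
therefore demonstrates that the algorithms are implemented correctly and
that the attention mechanism can learn to localize planted pathologies —
not that the models reach any particular accuracy on real radiographs.

## Preprocessing

A report is the concatenation of its impression and findings sections; a
report with both sections empty is excluded.  Tokens are lowercased and
stripped of non-alphanumeric characters (hyphens deleted, digits kept) —
chosen because the stated rule ("removing all non-alphanumerical
tokens") does not say whether partly alphanumeric tokens are dropped or
cleaned; cleaning preserves more signal and is covered by tests.  An
abbreviation dictionary (two-column TSV; a starter file ships in
`inst/extdata/`) is expanded in a single pass without re-expansion.
Label tokens are prepended with a period delimiter.  The word vocabulary
keeps tokens with frequency >= `min_freq` (default 1 — the phantom
grammar is a closed vocabulary; real corpora would raise it), ordered by
frequency then lexicographically after the four fixed specials.  Label
prefixes are present in both training and evaluation targets, matching a
pipeline that trains and scores on the prefixed ground truth; a flag in
`prepare_corpus()` disables prefixing.

## Evaluation

BLEU-1..4 are corpus-level clipped n-gram precisions with a brevity
penalty (effective reference length: closest, ties to the shorter);
"BLEU-n" uses n-grams up to order n.  ROUGE-L is the LCS F-measure with
the captioning-kit convention beta = 1.2, max over references, mean over
samples.  CIDEr uses TF-IDF n-gram vectors (n = 1..4, IDF over the
reference corpus), clipped cosine similarity, a Gaussian length penalty
with sigma = 6 and a factor 10.  Clinical-efficacy metrics extract a
binary label-presence vector from each text by exact matching of the
closed label vocabulary after normalization (a deliberate simplification
of rule-based labellers: presence only, no negation handling) and pool
TP/FP/FN/TN over all (sample, label) pairs (micro-averaging);
zero-denominator conventions return 0.  The test suite cross-checks all
three text metrics against an independent Python implementation of the
published formulas.

## Scales, defaults, and profiles

Two named profiles keep full-scale hyperparameters visible while desk
runs stay CPU-friendly.  The `paper` profile carries the full-scale
values (captioner: 70 epochs, batch 16, embedding 100, attention/decoder
width 512, dropout 0.1, encoder/decoder learning rates 4e-7/3e-7;
transformer: 30 epochs, batch 4, lr 5e-5, context window 1024, clip 1.0;
splits 75% / 24.75% / 0.25%) and refuses to run without a real corpus.
The `desk` profile trains on a few hundred phantoms with a small
captioner (embedding 48, width 96), a 2-layer/2-head/64-dim transformer
with a 256 context window, splits 75/15/10 (so the test split is
non-empty at a few hundred samples), and learning rates around 1e-3 —
sizes chosen so the full pipeline, the memorization properties (a tiny
captioner reaching >= 99% teacher-forced accuracy on 10 phantoms within
200 epochs; a tiny transformer memorizing one sentence below 0.1 nats
per token) and the localization property (500 training phantoms,
attention mass at the pathology word above the uniform baseline on 50
held-out samples) all run comfortably on a single CPU.  Dropout
placement (before the deep output layer only), the absence of a context
gating scalar, argmax/beam tie-breaking toward lower token ids, and
single-seed determinism of data, splits, initialization and training are
all deliberate choices; degenerate inputs (empty reports, empty label
sets, single-sample CIDEr corpora, k = 1 beams) are handled and tested.

## Known limitations

* The phantom grammar's small closed vocabulary makes word-level
  perplexities and n-gram metrics much higher than anything achievable
  on real reports; numbers from desk runs are not comparable to
  full-scale results.
* The clinical-efficacy extractor is presence-only; negated mentions
  count as mentions.
* Approach 1's vocabulary discretization evaluates the transformer once
  per multi-subword word and step; at large vocabularies this is the
  slowest path in the package.
* The localization property is demonstrated for single-lesion phantoms;
  multi-lesion attribution is not measured.
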