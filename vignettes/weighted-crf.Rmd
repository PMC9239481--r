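---
title: "Class-weighted CRFs for imbalanced sequence labeling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-weighted CRFs for imbalanced sequence labeling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
model, the design decisions that were genuinely open, the numerical
choices, what the synthetic data does and does not emulate, and the known
limitations.

## The problem

Adverse-drug-reaction (ADR) mention extraction is BIO sequence labeling
under strong class imbalance: in annotated social-media corpora roughly
86–87% of tokens are `O`, with ADR tokens an order of magnitude rarer and
indication tokens rarer still. Cross-entropy training approximates
accuracy, and under a 99:1 imbalance a tagger can reach 99% accuracy by
predicting the majority class everywhere — which is useless, because the
minority tokens are the entire point. Resampling strategies that work for
independent classification (up-/down-sampling, synthetic minority
examples) do not transfer cleanly to sequences: adding or deleting
individual tokens destroys the syntax that sequence models rely on. The
remedy implemented here acts at the objective level instead: re-price each
token's loss term by the rarity of its class, inside a model that keeps
the label-to-label dependencies.

## The linear-chain CRF

For a sentence of `N` tokens and a tag alphabet of size `K` (`O` plus
`B-`/`I-` per entity class), a labeling `y` is scored by
`s(x, y) = Σᵢ A[yᵢ₋₁, yᵢ] + P[i, yᵢ]`, where the emission table `P`
(`N × K`) comes from the context encoder and the transition matrix `A` is
learned. Synthetic start and end states are mandatory — `y₀` is the start
state, and a final transition into the end state closes the chain — so `A`
is `(K + 2) × (K + 2)`, with emissions only for real positions.
`p(y|x) = exp(s)/Z(x)` is normalized by the partition function over all
`K^N` paths, computed by the forward recursion in `O(NK²)`; posterior
marginals `m[i, k] = p(yᵢ = k | x)` come from forward–backward, decoding
from Viterbi.

All internal arithmetic is carried in log space with the log-sum-exp
shift; naive exponentiation overflows for realistic score magnitudes. The
package keeps a brute-force path-enumeration oracle
(`enumerate_oracle()`) as a first-class exported function: every dynamic
program is tested against exhaustive enumeration on instances with
`K^N ≤ 10⁶`, at `1e-8` absolute tolerance in the log domain (double
precision accumulates a few thousand terms at worst). Viterbi ties are
broken toward the lowest tag index at each backtracking step so decoding
is deterministic; the enumeration oracle returns the lexicographically
smallest maximizer, which coincides with the Viterbi rule on the
zero-potential tie case the tests cover, and exact ties have probability
zero under the continuous random potentials used elsewhere.

## The weighted objective

The package's central quantity is the class-weighted CRF loss

    L = Σᵢ w_c(yᵢ) · ( −log m[i, yᵢ] )

with `m` the forward–backward marginals and `c(·)` mapping a tag to its
pooled class (`B-X` and `I-X` share the weight of class `X`; `O` has its
own). This per-token decomposition was a genuine design decision. A
sequence-level weighted likelihood has no canonical per-class grouping:
one labeling touches several classes at once, so "weight the terms of
class k" is only well defined once the objective is written as a sum over
observations. Rewriting the log-partition per observation — the classic
per-position decomposition used for hidden Markov models — yields exactly
the posterior log-marginals, and the weighted sum of their negatives is
the only reading under which a per-class grouping of loss terms is
coherent. Two properties make it a faithful weighted generalization:

* with all weights 1 and zero transitions it collapses exactly to the sum
  of per-token softmax cross-entropies (asserted at `1e-10`);
* the transitions still shape every `m[i, yᵢ]`, so label dependencies are
  retained — unlike weighted softmax, which treats positions
  independently.

The gradient is obtained by reverse-mode accumulation through the forward
and backward log-sum-exp recursions (adjoints of `α`, `β` and `log Z`
propagated in `O(NK²)`, the same cost as inference). Hand-derived
gradients are only trustworthy when independently checked, so
central-difference validation (`numerical_gradient_check()`) is part of
the public surface and the test suite arbitrates every head at `1e-4`
relative tolerance.

## Weighting strategies

`compute_class_weights()` implements four rules on pooled token counts
`n_k` (`N = Σ n_k`, `K` classes):

| strategy        | `w_k`          | notes                                    |
|-----------------|----------------|------------------------------------------|
| `balanced`      | `N / (K·n_k)`  | default; conserves `Σ w_k n_k = N`; balanced counts give all 1 |
| `inverse_count` | `1 / n_k`      | scale-free variant, `balanced / (N/K)`   |
| `inverse_ratio` | `N / n_k`      | `K ×` balanced                           |
| `uniform`       | `1`            | recovers the unweighted objective        |

The balanced rule is the same prescription as scikit-learn's
`class_weight = "balanced"`: it accounts for both the count and the ratio
of each class, and the two simpler rules are kept because they are the
natural comparison points. A zero count is an error by default — silent
smoothing hides corpus bugs — with opt-in add-one smoothing.

Baseline objectives for the same comparison: weighted softmax
cross-entropy; focal loss `Σ (1−p)^γ(−log p)` (default `γ = 2`, no
per-class α term beyond an optional scalar, since the modulating factor is
the mechanism of interest); dice loss
`1 − (2Σpy + ε)/(Σp² + Σy² + ε)` with Sørensen smoothing `ε = 1` by
default (prevents 0/0 on empty classes). Losses are sums over tokens, not
means — the weighting is defined on totals — with the per-batch mean taken
by the trainer.

## The context encoder

At full scale the natural encoder is a pretrained transformer fine-tuned
end to end; the loss machinery is deliberately encoder-agnostic (any
module producing one hidden vector per token can feed the emission
projection). The package's own encoder is a desk-scale trainable stack:
embedding table (default 32 dims) → bidirectional LSTM (default 32 per
direction) → optional scaled dot-product self-attention → dropout
(default 0.1) → linear emission projection. Optional character-level
composition runs a small BiLSTM (default 16 per direction) over each
word's characters and concatenates the two final states to the word
embedding, the usual recipe for out-of-vocabulary robustness. All
embeddings initialize uniform(−0.25, 0.25) — the standard treatment of
unseen words — and unknown tokens map to a reserved UNK id.

Forward and backward passes are written in base R and the backward pass is
validated coordinate-wise against central differences for every
architecture variant. Subword front-ends are supported through
`align_subword_labels()`: the first piece of a split word inherits its
tag, the remaining pieces get the `[IGN]` sentinel, and `[IGN]` positions
are excluded from losses (mask argument) and metrics; `[IGN]` is a mask,
never a member of the tag alphabet or the transition matrix.

## Training

`wcrf()` fits by Adam (default learning rate `1e-2`, suited to the small
randomly initialized encoder; fine-tuning a pretrained encoder would use
~`2e-5`) with mini-batches of 16 sentences. Batching is per-sequence
gradient accumulation — mathematically identical to pad-and-mask batching
for these losses, with no padded positions to mask. One seed controls
initialization, shuffling and dropout, so runs are bit-reproducible. There
is no early stopping by default; `dev_split = 0.2` reproduces the usual
8:2 monitoring split when epoch counts are being tuned. A non-finite loss
aborts with a diagnostic rather than silently continuing.

Decoding uses Viterbi for CRF heads and per-position argmax for softmax
heads. By default decoding also bars BIO-invalid transitions (`I-X` after
anything but `B-X`/`I-X`) by assigning them a large negative score, so
predictions always validate; the unconstrained decoder is available for
inspecting what the learned transitions alone do.

## Evaluation

ADR systems are conventionally scored with approximate matching: a
predicted span overlapping a gold span of the same class by at least one
token is credited in full (predicting *lasting sleep paralysis* or just
*paralysis* for gold *sleep paralysis* leaves no false negative). The
counting is token-level: true positives are the tokens of overlapping
predicted spans, false positives the tokens of unmatched predicted spans,
false negatives the tokens of gold spans no prediction touches.
"Approximate" is not fully standardized in the literature; this
overlap-based token counting is the reading fixed by the *sleep
paralysis* convention above, and a strict exact-boundary mode is exposed
(`match = "strict"`) both for debugging and because strict true positives
can never exceed approximate ones — a property the tests assert.
Zero-denominator ratios are defined as 0.

## Local explanations

`explain_token()` rephrases one token's tagging as a local classification
problem and explains it by perturbation: mask random subsets of the
context tokens (the target always survives), read the model's probability
for the target label on each variant, and fit a weighted linear surrogate
of probability on the presence bits. Three design choices matter:

* "removing" a token replaces it with UNK rather than deleting it, so the
  sequence length and the target index are preserved — deletion would
  shift positions and break the per-token reading;
* the probability explained is the forward–backward posterior marginal
  `m[i, label]` for CRF heads (the per-token probability the rephrasing
  requires), the row softmax for independent heads;
* the proximity kernel is `exp(−d²/width²)` on the Hamming distance `d`
  (number of masked tokens), width 25 by default, with 1000 variants — wide
  enough that desk-scale sentences (≤ 36 tokens) all carry substantial
  weight while closer variants still dominate.

The additive reading of the surrogate is `removal_effect()`: removing a
token set is expected to change the probability by minus the sum of their
contributions, clipped into `[0, 1]` to keep the contract probabilistic.
The surrogate fit is plain weighted least squares (`stats::lm.wfit`); on a
model that is genuinely linear in the mask bits it recovers the true
coefficients to numerical precision, which the tests assert with planted
coefficients.

## Synthetic corpora

`generate_corpus()` exists so that every claim in the package is testable
without downloads. Sentences are built by a segment-level process:
segment types (single `O` token, or an entity span of a class) are drawn
with probabilities calibrated so expected token fractions equal the
configured class ratios — entity probabilities divided by the mean span
length (1.7 under the default span-length law `{1: 0.5, 2: 0.3, 3: 0.2}`,
chosen because real ADR mentions are overwhelmingly 1–3 tokens:
*depression*, *sleep paralysis*, *lasting sleep paralysis*). Span words
come from class-specific sub-vocabularies with probability
`emission_sharpness` (default 0.8), otherwise from the shared vocabulary;
sharpness is the single dial for task difficulty, and higher sharpness
demonstrably raises attainable F1 (a monotonicity the tests check at two
settings across five seeds). Labels are valid BIO by construction. One
global seed derives an explicit sub-seed per sentence, so corpora are
reproducible and extendable.

The default profile mirrors the published Twitter-style statistics:
ratios `O/ADR/Indication = 0.865/0.123/0.012`, mean length 20, max 36.
(The printed percentages 86.5/12.3/1.3 sum to 100.1 after rounding; the
Indication share is set to 0.012 so the simplex constraint holds exactly.)
What the generator deliberately does **not** emulate: real word
frequencies (Zipfian structure), contextual cues beyond word identity,
misspellings and creative drug names, annotation noise, and
document-level effects. Passing tests on synthetic corpora therefore
demonstrate the correctness and the qualitative behavior of the machinery
— e.g. that balanced weighting raises minority recall — not benchmark-level
performance on real ADR corpora, which additionally requires a pretrained
encoder and the external datasets.

## Numerical choices and problem sizes

* Log-space everywhere; `log_partition(zeros) = N·log K` holds to `1e-12`.
* Oracle agreement tolerance `1e-8` (log domain); gradient checks `1e-4`
  relative with step `1e-5`; degeneracy identities `1e-10`.
* Viterbi ties → lowest tag index; invalid `I-X` repaired as `B-X` during
  span extraction (validation still reports it); `0/0 = 0` in metrics.
* Token indices are 0-based half-open in spans (`[start, end)`);
  validation reports 1-based positions, the R convention.
* Test problem sizes are chosen for seconds-scale feedback: enumeration
  instances `N ≤ 6, K ≤ 4`; training fixtures of 8–30 sentences with a
  16/8 encoder; the imbalance experiment uses 1,000 training sentences at
  a 95:5 `O`:ADR ratio, 5 training seeds, 3 epochs, evaluated on a 200-
  sentence held-out split from the same generator run; memorization uses
  10 sentences of a two-class 90:10 profile for 200 epochs (a two-class
  profile keeps weighted training well-posed — a 10-sentence draw of the
  three-class profile can contain zero Indication tokens, which the
  weight computation treats as an error by design).

## Limitations

* The pretrained-transformer path is an interface, not an implementation:
  the encoder contract (one vector per token) is where a BERT-class model
  would plug in, and reported full-scale F1 levels are out of reach of
  the desk-scale encoder by design.
* The weighted objective's per-token decomposition is one principled
  reading of a sequence-level weighted likelihood; alternatives (e.g.
  weighting the gold path score only) exist but lack a coherent per-class
  grouping.
* Nested and discontinuous entities, and raw-text tokenization, are out
  of scope; inputs are pre-tokenized.
* `fit()`-time costs are `O(sentences × N × (K² + encoder))` per epoch in
  pure R; the implementation is vectorized per time step but is built for
  method study, not production-scale corpora.
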