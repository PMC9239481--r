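# wcrf: weighted conditional random fields for imbalanced sequence labeling

Mentions of adverse drug reactions (ADRs) in social-media posts and
biomedical abstracts are the raw material of post-marketing drug safety
surveillance, and extracting them is a sequence labeling problem with a
severe class imbalance: in a typical annotated Twitter ADR corpus about
86.5% of tokens carry the `O` (outside) tag, ~12% name an ADR and ~1% name
an indication. A tagger trained with plain cross-entropy — an accuracy
surrogate — can score very well by drifting toward the majority class and
ignoring exactly the spans the task exists to find.

`wcrf` addresses this with a **class-weighted conditional random field**.
A linear-chain CRF scores a labeling *y* of a sentence *x* as

    s(x, y) = Σᵢ ( A[yᵢ₋₁, yᵢ] + P[i, yᵢ] )

with `P` the emission scores produced by a context encoder, `A` a learned
transition matrix over the `K` tags plus synthetic start/end states
(`(K+2) × (K+2)`), and `p(y|x) = exp s(x,y) / Z(x)`. The partition function
`Z`, posterior marginals and the best path are computed exactly by the
forward(-backward) and Viterbi dynamic programs in `O(NK²)`. The weighted
training objective re-prices each token by its class:

    L = Σᵢ w_c(yᵢ) · ( −log m[i, yᵢ] ),      w_k = N / (K · n_k)

where `m[i, k] = p(yᵢ = k | x)` are forward-backward marginals (so label
dependencies still shape every term), `n_k` is the token count of class `k`
and `N` the corpus token total. The balanced weights satisfy
`Σ w_k n_k = N` and up-weight minority classes by their rarity — with a
95:5 `O`:ADR corpus the ADR terms count 10×. Alternative weightings
(`1/n_k`, `N/n_k`, uniform) and four baseline objectives (softmax
cross-entropy, its weighted variant, focal loss, dice loss) are included
for comparison, along with:

* CoNLL-style corpus IO, BIO validation, span extraction and corpus
  statistics;
* a small trainable embedding + BiLSTM context encoder (optional
  character composition and self-attention) with hand-derived analytic
  gradients, checked against central differences;
* approximate-match precision/recall/F1 (a predicted span overlapping a
  gold span counts in full — the standard ADR evaluation convention);
* perturbation-based local explanations of single-token predictions
  (LIME-style weighted linear surrogate over masked sentence variants);
* a synthetic imbalanced-corpus generator so every component is testable
  without external data;
* a command-line front end (`exec/wcrf`) with `train / predict / evaluate /
  explain / generate / stats` subcommands.

## Worked example

Generate an imbalanced corpus with the Twitter-like default profile, fit a
weighted CRF, and inspect it:

```r
library(wcrf)
gen   <- generate_corpus(generator_config(n_sentences = 120, seed = 7))
corpus_stats(gen$corpus)
#> Samples 120 | Max length 30 | Mean length 20.0 | Vocab 590 | Tokens 2401
#>   O                2075 tokens   86.4%
#>   ADR               297 tokens   12.4%
#>   Indication         29 tokens    1.2%

train <- wcrf_corpus(gen$corpus$sequences[1:100], gen$corpus$alphabet)
test  <- wcrf_corpus(gen$corpus$sequences[101:120], gen$corpus$alphabet)
fit   <- wcrf(train, loss = "wcrf", epochs = 10, seed = 1)

round(coef(fit)$class_weights, 3)
#>          O        ADR Indication
#>      0.386      2.661     30.242

wcrf_evaluate(fit, test)
#>        class tp fp fn precision   recall        f1
#> 1        ADR 42  8  5      0.84 0.893617 0.8659794
#> 2 Indication  9  1  1      0.90 0.900000 0.9000000
```

The class weights are the balanced rule applied to the training counts:
`O` tokens are discounted to 0.386 while the rare Indication tokens are
up-weighted 30-fold, and the fitted tagger recovers ~90% of minority-class
spans under approximate matching. Predictions and explanations:

```r
s <- test$sequences[[1]]
predict(fit, s$tokens)
#> w0414/O w0447/O w0275/O w0525/B-ADR w0063/O ...

explain_token(fit, s$tokens, 4, n_samples = 300, seed = 2)
#> Explanation for token 4 ('w0525') as B-ADR (p = 0.995)
#>  token position contribution
#>  w0275        3       0.0188
#>  w0447        2       0.0158
#>  ...
```

Each contribution is the coefficient of a weighted linear surrogate fitted
to the model's target-label marginal probability on perturbed copies of the
sentence; `removal_effect()` turns them into expected probabilities after
removing context tokens (e.g. base 0.95 minus contributions 0.33 and 0.31
leaves 0.31).

The same workflows are scriptable from the shell:

```sh
Rscript exec/wcrf generate --n 200 --seed 7 -o toy.conll
Rscript exec/wcrf stats --input toy.conll
Rscript exec/wcrf train --input toy.conll --model m.rds --loss wcrf --epochs 20
Rscript exec/wcrf evaluate --model m.rds --input toy.conll --json metrics.json
```

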