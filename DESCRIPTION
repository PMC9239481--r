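Package: wcrf
Title: Weighted Conditional Random Fields for Imbalanced Sequence Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Linear-chain conditional random fields (CRF) with class-weighted
    objectives for sequence labeling under severe class imbalance, as arises in
    adverse-drug-reaction (ADR) mention extraction from social-media and
    biomedical text. Provides exact forward-backward and Viterbi inference, a
    class-weighted CRF loss with several weighting strategies, weighted
    softmax, focal and dice baseline losses, a small trainable
    embedding + bidirectional LSTM context encoder, approximate-match span
    evaluation, perturbation-based local explanations of single-token
    predictions, CoNLL-style corpus input/output with BIO tag validation, and a
    synthetic imbalanced-corpus generator for controlled experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
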