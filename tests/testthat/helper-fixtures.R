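# shared fixtures, all generated in code

rand_potentials <- function(N, K, seed) {
  set.seed(seed)
  potential_tables(matrix(rnorm(N * K), N, K),
                   matrix(rnorm((K + 2)^2), K + 2L, K + 2L))
}

rand_instance <- function(seed, n_max = 6L, k_max = 4L) {
  set.seed(seed)
  N <- sample(1:n_max, 1L)
  K <- sample(2:k_max, 1L)
  list(pot = rand_potentials(N, K, seed + 1000L),
       labels = sample(K, N, replace = TRUE),
       N = N, K = K)
}

# small well-separated two-class corpus for fast training tests
tiny_corpus <- function(n = 10L, seed = 5L, sharpness = 0.8) {
  generate_corpus(generator_config(
    n_sentences = n, class_ratios = c(O = 0.9, ADR = 0.1),
    emission_sharpness = sharpness, vocab_size = 120L,
    mean_length = 12, max_length = 20L, seed = seed))$corpus
}

small_encoder <- function(corpus, seed = 1L, ...) {
  encoder_config(vocab_size = length(unique(unlist(
    lapply(corpus$sequences, `[[`, "tokens")))) + 1L,
    embed_dim = 16L, hidden_dim = 8L, dropout_rate = 0, seed = seed, ...)
}

# flatten a nested parameter list in a fixed order
flatten_params <- function(p) unlist(p, use.names = FALSE)
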