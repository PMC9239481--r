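test_that("hidden states honour the shape and determinism contract", {
  cfg <- encoder_config(vocab_size = 20L, embed_dim = 8L, hidden_dim = 6L,
                        dropout_rate = 0, seed = 3L)
  params <- wcrf:::init_encoder_params(cfg)
  for (n in c(1L, 4L, 9L)) {
    ids <- rep_len(c(2L, 5L, 9L), n)
    H <- encode_tokens(ids, params, cfg)
    expect_equal(dim(H), c(n, 2L * cfg$hidden_dim))
    expect_true(all(is.finite(H)))
  }
  ids <- c(3L, 7L, 1L, 12L)
  expect_identical(encode_tokens(ids, params, cfg),
                   encode_tokens(ids, params, cfg))
  expect_error(encode_tokens(c(1L, 99L), params, cfg), "vocabulary")
})

test_that("the backward direction carries context to the first position", {
  cfg <- encoder_config(vocab_size = 20L, embed_dim = 8L, hidden_dim = 6L,
                        dropout_rate = 0, seed = 4L)
  params <- wcrf:::init_encoder_params(cfg)
  h_a <- encode_tokens(c(2L, 3L, 4L, 5L), params, cfg)
  h_b <- encode_tokens(c(2L, 3L, 4L, 6L), params, cfg)
  expect_gt(max(abs(h_a[1L, ] - h_b[1L, ])), 0)
  # and the forward direction carries context to the last position
  h_c <- encode_tokens(c(7L, 3L, 4L, 5L), params, cfg)
  expect_gt(max(abs(h_a[4L, ] - h_c[4L, ])), 0)
})

test_that("self-attention is a row-stochastic mixture preserving shape", {
  set.seed(11)
  H <- matrix(rnorm(24L), 4L, 6L)
  out <- self_attention(H)
  W <- attr(out, "attention")
  expect_equal(dim(out), dim(H))
  expect_equal(rowSums(W), rep(1, 4L), tolerance = 1e-12)
  # independent dense evaluation of the attention formula
  G <- H %*% t(H) / sqrt(ncol(H))
  Wd <- exp(G - apply(G, 1L, max))
  Wd <- Wd / rowSums(Wd)
  expect_equal(unclass(out), Wd %*% H, ignore_attr = TRUE,
               tolerance = 1e-12)
  # a single token attends only to itself
  one <- self_attention(H[1L, , drop = FALSE])
  expect_equal(unclass(one), H[1L, , drop = FALSE], ignore_attr = TRUE)
  expect_equal(attr(one, "attention")[1L, 1L], 1)
  expect_error(self_attention(matrix(0, 0L, 3L)), "empty")
})

test_that("encoder gradients are exact for all architecture variants", {
  run_check <- function(cfg, char_ids = NULL) {
    set.seed(cfg$seed + 7L)
    params <- wcrf:::init_encoder_params(cfg)
    ids <- sample(cfg$vocab_size, 4L, replace = TRUE)
    D <- 2L * cfg$hidden_dim
    Rm <- matrix(rnorm(4L * D), 4L, D)
    cache <- wcrf:::encode_forward(ids, params, cfg, char_ids)
    grads <- wcrf:::encode_backward(cache, Rm, params, cfg)[names(params)]
    th <- flatten_params(params)
    lf <- function(v) {
      sum(wcrf:::encode_forward(ids, utils::relist(v, params), cfg,
                                char_ids)$H * Rm)
    }
    coords <- sort(sample(length(th), 40L))
    numerical_gradient_check(lf, flatten_params(grads), th, 1e-5, coords)
  }
  plain <- encoder_config(vocab_size = 10L, embed_dim = 5L, hidden_dim = 4L,
                          dropout_rate = 0, seed = 1L)
  expect_lt(run_check(plain), 1e-6)
  attn <- encoder_config(vocab_size = 10L, embed_dim = 5L, hidden_dim = 4L,
                         use_attention = TRUE, dropout_rate = 0, seed = 2L)
  expect_lt(run_check(attn), 1e-6)
  char <- encoder_config(vocab_size = 10L, embed_dim = 5L, hidden_dim = 4L,
                         use_char = TRUE, char_dim = 3L,
                         char_vocab_size = 7L, dropout_rate = 0, seed = 3L)
  set.seed(8)
  char_ids <- lapply(1:4, function(i) sample(7L, sample(2:5, 1L), TRUE))
  expect_lt(run_check(char, char_ids), 1e-6)
})

test_that("subword alignment keeps labels on first pieces only", {
  al <- align_subword_labels("depression", "B-ADR",
                             list(c("de", "##press", "##ion")))
  expect_equal(al$subtokens, c("de", "##press", "##ion"))
  expect_equal(al$labels, c("B-ADR", "[IGN]", "[IGN]"))
  single <- align_subword_labels(c("no", "pain"), c("O", "B-ADR"),
                                 list("no", c("pa", "##in")))
  expect_equal(single$labels, c("O", "B-ADR", "[IGN]"))
  # non-ignored label count always equals the original word count
  words <- c("a", "bb", "ccc")
  labs <- c("O", "B-ADR", "I-ADR")
  splits <- list(c("a"), c("b", "##b"), c("c", "##c", "##c"))
  al2 <- align_subword_labels(words, labs, splits)
  expect_equal(sum(al2$labels != "[IGN]"), length(words))
  expect_equal(al2$labels[al2$labels != "[IGN]"], labs)
  expect_error(align_subword_labels("x", "O", list(character())), "empty")
})
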