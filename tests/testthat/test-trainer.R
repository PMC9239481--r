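test_that("training reduces the loss within five epochs for every head", {
  corp <- tiny_corpus(n = 8L, seed = 9L)
  enc <- small_encoder(corp)
  for (head in c("wcrf", "crf", "softmax", "wsoftmax", "focal", "dice")) {
    m <- wcrf(corp, loss = head, encoder = enc, epochs = 5L,
              learning_rate = 5e-2, batch_size = 4L, seed = 1L)
    expect_lt(m$history$train_loss[[5L]], m$history$train_loss[[1L]])
  }
})

test_that("fitting is reproducible from the seed", {
  corp <- tiny_corpus(n = 6L, seed = 2L)
  enc <- small_encoder(corp)
  m1 <- wcrf(corp, epochs = 3L, encoder = enc, seed = 7L)
  m2 <- wcrf(corp, epochs = 3L, encoder = enc, seed = 7L)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_identical(m1$params, m2$params)
})

test_that("predictions match input lengths and respect BIO constraints", {
  corp <- generate_corpus(generator_config(
    n_sentences = 12L, class_ratios = c(O = 0.7, ADR = 0.2,
                                        Indication = 0.1),
    vocab_size = 100L, mean_length = 10, max_length = 16L, seed = 3L))$corpus
  m <- wcrf(corp, epochs = 4L, encoder = small_encoder(corp),
            learning_rate = 5e-2, seed = 2L)
  preds <- predict(m, corp)
  for (i in seq_along(preds)) {
    expect_length(preds[[i]]$labels, length(corp$sequences[[i]]$tokens))
    expect_equal(nrow(validate_boi(preds[[i]]$labels, corp$alphabet)), 0L)
  }
})

test_that("an over-parameterized model memorizes a tiny corpus", {
  corp <- tiny_corpus(n = 10L, seed = 5L)
  m <- wcrf(corp, epochs = 60L, learning_rate = 2e-2, seed = 1L)
  res <- wcrf_evaluate(m, corp)
  expect_equal(res$f1, rep(1, nrow(res)))
  # decoding the training set reproduces the gold labels
  preds <- predict(m, corp)
  for (i in seq_along(preds)) {
    expect_identical(preds[[i]]$labels, corp$sequences[[i]]$labels)
  }
})

test_that("model state serializes losslessly", {
  corp <- tiny_corpus(n = 6L, seed = 4L)
  m <- wcrf(corp, epochs = 2L, encoder = small_encoder(corp), seed = 3L)
  f <- withr::local_tempfile(fileext = ".rds")
  wcrf_save(m, f)
  back <- wcrf_load(f)
  expect_identical(back$params, m$params)
  toks <- corp$sequences[[1L]]$tokens
  expect_identical(predict(back, toks)$labels, predict(m, toks)$labels)
  expect_identical(predict(back, toks, type = "marginals"),
                   predict(m, toks, type = "marginals"))
})

test_that("numerical_gradient_check behaves on analytic ground truth", {
  # quadratic: central differences are exact up to rounding
  quad <- function(x) sum((x - 2)^2)
  x0 <- c(0.5, -1, 3)
  expect_lt(numerical_gradient_check(quad, 2 * (x0 - 2), x0, 1e-4), 1e-8)
  # at the constructed minimum the measured gradient norm vanishes
  g_at_min <- vapply(1:3, function(j) {
    e <- numeric(3); e[j] <- 1e-5
    (quad(c(2, 2, 2) + e) - quad(c(2, 2, 2) - e)) / 2e-5
  }, 0)
  expect_lt(sqrt(sum(g_at_min^2)), 1e-6)
  expect_error(numerical_gradient_check(quad, c(0, 0, 0), x0, 1), "epsilon")
  expect_error(numerical_gradient_check(function(x) NaN, 0, 1), "finite")
})

test_that("full-model gradients pass the central-difference check", {
  corp <- tiny_corpus(n = 3L, seed = 6L)
  enc <- encoder_config(vocab_size = length(wcrf:::build_vocab(corp)) + 1L,
                        embed_dim = 4L, hidden_dim = 3L, dropout_rate = 0,
                        seed = 2L)
  ab <- corp$alphabet
  set.seed(1)
  params <- wcrf:::init_encoder_params(enc)
  params$W_out <- wcrf:::runif_mat(2L * enc$hidden_dim, ab$K)
  params$b_out <- numeric(ab$K)
  params$A <- matrix(rnorm((ab$K + 2L)^2, sd = 0.1), ab$K + 2L)
  s <- corp$sequences[[1L]]
  ex <- list(ids = wcrf:::tokens_to_ids(s$tokens, wcrf:::build_vocab(corp)),
             y = wcrf:::tag_index(s$labels, ab), chars = NULL)
  w_tag <- tag_weights(compute_class_weights(class_token_counts(corp)), ab)
  for (head in c("wcrf", "crf", "wsoftmax", "focal", "dice")) {
    r <- wcrf:::sentence_grad(ex, params, enc, head, w_tag, 2, 1)
    th <- flatten_params(params)
    lf <- function(v) {
      wcrf:::sentence_grad(ex, utils::relist(v, params), enc, head, w_tag,
                           2, 1)$loss
    }
    set.seed(3)
    coords <- sort(sample(length(th), 30L))
    dev <- numerical_gradient_check(lf, flatten_params(r$grads[names(params)]),
                                    th, 1e-5, coords)
    expect_lt(dev, 1e-4)
  }
})

test_that("a held-out development split is monitored when requested", {
  corp <- tiny_corpus(n = 10L, seed = 8L)
  m <- wcrf(corp, epochs = 2L, encoder = small_encoder(corp),
            dev_split = 0.2, seed = 1L)
  expect_false(anyNA(m$history$dev_loss))
})

test_that("degenerate fits fail loudly", {
  corp <- tiny_corpus(n = 4L, seed = 3L)
  expect_error(wcrf(corp, learning_rate = -1), "learning_rate")
  expect_error(wcrf(wcrf_corpus(list(), label_alphabet("ADR"))), "empty")
  m <- wcrf(corp, epochs = 1L, encoder = small_encoder(corp))
  expect_error(predict(m, character()), "empty")
})
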