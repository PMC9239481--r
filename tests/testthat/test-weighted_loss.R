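test_that("class-weight strategies compute the stated formulas", {
  cw <- compute_class_weights(c(O = 90, ADR = 10), "balanced")
  expect_equal(unname(cw$weights), c(100 / 180, 5), tolerance = 1e-12)
  # balanced counts give exactly 1 for every class
  eq <- compute_class_weights(c(O = 10, ADR = 10, Indication = 10))
  expect_identical(unname(eq$weights), c(1, 1, 1))
  # all strategies agree (up to scale) on balanced counts
  for (s in c("inverse_count", "inverse_ratio", "uniform")) {
    w <- compute_class_weights(c(A = 7, B = 7), s)$weights
    expect_equal(w[[1L]], w[[2L]])
  }
})

test_that("Twitter-style pooled counts give the expected O weight", {
  # 16,023 tokens over 3 classes, 13,852 of them O
  cw <- compute_class_weights(c(O = 13852, ADR = 1970, Indication = 201))
  expect_equal(unname(cw$weights[["O"]]), 16023 / (3 * 13852),
               tolerance = 1e-12)
  expect_equal(round(cw$weights[["O"]], 4L), 0.3856)
  expect_gt(cw$weights[["ADR"]], 1)
  expect_gt(cw$weights[["Indication"]], 1)
})

test_that("weight strategies obey exact scale relations and conservation", {
  for (seed in 1:5) {
    set.seed(seed)
    counts <- sample(1:500, 4L)
    names(counts) <- c("O", "A", "B", "C")
    N <- sum(counts); K <- length(counts)
    bal <- compute_class_weights(counts, "balanced")$weights
    inv_c <- compute_class_weights(counts, "inverse_count")$weights
    inv_r <- compute_class_weights(counts, "inverse_ratio")$weights
    expect_equal(inv_r, K * bal, tolerance = 1e-12)
    expect_equal(inv_c, bal / (N / K), tolerance = 1e-12)
    expect_equal(sum(bal * counts), N, tolerance = 1e-12)
    # minority classes get weight > 1 under balanced weighting
    expect_true(all((bal > 1) == (counts < N / K)))
  }
})

test_that("zero counts error unless smoothing is requested", {
  expect_error(compute_class_weights(c(O = 10, ADR = 0)), "zero token count")
  sm <- compute_class_weights(c(O = 10, ADR = 0), smooth = TRUE)
  expect_equal(unname(sm$weights[["ADR"]]), 12 / (2 * 1))
})

test_that("weighted CRF loss degenerates to softmax cross-entropy", {
  set.seed(21)
  N <- 6L; K <- 3L
  P <- matrix(rnorm(N * K), N, K)
  y <- sample(K, N, replace = TRUE)
  pot <- potential_tables(P, matrix(0, K + 2L, K + 2L))
  expect_equal(weighted_crf_nll(pot, y, rep(1, K)),
               weighted_softmax_ce(P, y, rep(1, K)), tolerance = 1e-10)
})

test_that("weighted CRF loss is linear in the weights and monotone in the
           gold marginal", {
  inst <- rand_instance(3L)
  w <- runif(inst$K, 0.5, 3)
  l1 <- weighted_crf_nll(inst$pot, inst$labels, w)
  expect_equal(weighted_crf_nll(inst$pot, inst$labels, 2 * w), 2 * l1,
               tolerance = 1e-10)
  # raising the gold tag's emission raises its marginal and lowers the loss
  P2 <- inst$pot$emissions
  P2[1L, inst$labels[[1L]]] <- P2[1L, inst$labels[[1L]]] + 1
  pot2 <- potential_tables(P2, inst$pot$transitions)
  expect_lt(weighted_crf_nll(pot2, inst$labels, w), l1)
})

test_that("analytic weighted-CRF gradients match central differences", {
  for (seed in 1:5) {
    inst <- rand_instance(seed + 50L, n_max = 5L)
    N <- inst$N; K <- inst$K
    w <- runif(K, 0.2, 4)
    g <- wcrf:::weighted_crf_grad(inst$pot, inst$labels, w)
    expect_equal(g$loss, weighted_crf_nll(inst$pot, inst$labels, w),
                 tolerance = 1e-12)
    loss_fn <- function(th) {
      weighted_crf_nll(potential_tables(matrix(th[1:(N * K)], N, K),
                                        matrix(th[-(1:(N * K))], K + 2L)),
                       inst$labels, w)
    }
    dev <- numerical_gradient_check(
      loss_fn, c(g$d_emissions, g$d_transitions),
      c(inst$pot$emissions, inst$pot$transitions))
    expect_lt(dev, 1e-4)
  }
})

test_that("masked positions drop out of the weighted loss", {
  inst <- rand_instance(17L, n_max = 5L)
  w <- rep(1, inst$K)
  mask <- rep(TRUE, inst$N); mask[1L] <- FALSE
  full <- weighted_crf_nll(inst$pot, inst$labels, w)
  part <- weighted_crf_nll(inst$pot, inst$labels, w, mask)
  m <- posterior_marginals(inst$pot)
  expect_equal(full - part, -log(m[1L, inst$labels[[1L]]]),
               tolerance = 1e-10)
})

test_that("weighted softmax cross-entropy matches closed forms", {
  set.seed(4)
  N <- 5L; K <- 3L
  logits <- matrix(rnorm(N * K), N, K)
  y <- sample(K, N, replace = TRUE)
  plain <- -sum(log(wcrf:::row_softmax(logits)[cbind(seq_len(N), y)]))
  expect_equal(weighted_softmax_ce(logits, y, rep(1, K)), plain,
               tolerance = 1e-12)
  # margin -> infinity drives the loss to zero
  hot <- matrix(0, 1L, 2L); hot[1L, 1L] <- 50
  expect_lt(weighted_softmax_ce(hot, 1L, c(1, 1)), 1e-10)
  # uniform logits, doubled weight on the gold class
  expect_equal(weighted_softmax_ce(matrix(0, 1L, 2L), 1L, c(2, 1)),
               2 * log(2), tolerance = 1e-12)
  expect_error(weighted_softmax_ce(matrix(0, 2L, 2L), 1L, c(1, 1)),
               "labels length")
})

test_that("focal loss reduces to cross-entropy at gamma zero", {
  set.seed(10)
  p <- runif(8L, 0.05, 0.99)
  expect_equal(focal_loss(p, gamma = 0), sum(-log(p)), tolerance = 1e-12)
  expect_equal(focal_loss(1, gamma = 2), 0)
  expect_equal(focal_loss(0.5, gamma = 2), 0.25 * log(2), tolerance = 1e-12)
  expect_error(focal_loss(0), "0, 1")
  # harder tokens keep more of their cross-entropy under the modulation
  expect_lt(focal_loss(0.9, 2) / -log(0.9), focal_loss(0.2, 2) / -log(0.2))
})

test_that("dice loss measures soft overlap", {
  y <- diag(3L)
  expect_equal(dice_loss(y, y, eps = 1e-9), 0, tolerance = 1e-8)
  orth <- y[, c(2L, 3L, 1L)]
  expect_equal(dice_loss(orth, y, eps = 1e-9), 1, tolerance = 1e-8)
  set.seed(6)
  probs <- wcrf:::row_softmax(matrix(rnorm(12L), 4L, 3L))
  one_hot <- diag(3L)[sample(3L, 4L, replace = TRUE), ]
  eps <- 1
  direct <- 1 - (2 * sum(probs * one_hot) + eps) /
    (sum(probs^2) + sum(one_hot^2) + eps)
  expect_equal(dice_loss(probs, one_hot), direct, tolerance = 1e-12)
  expect_error(dice_loss(probs, diag(3L)), "shape")
})
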