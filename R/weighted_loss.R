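#' Class weights for imbalanced sequence labeling
#'
#' Computes one positive cost parameter per class from token counts. The
#' default `"balanced"` strategy sets `w_k = N / (K * n_k)`, where `N` is the
#' total token count, `K` the number of classes and `n_k` the token count of
#' class `k`; it satisfies the conservation identity `sum(w_k * n_k) = N` and
#' gives every class weight 1 when counts are balanced. Two simpler
#' strategies are provided for comparison: `"inverse_count"` (`w_k = 1 /
#' n_k`) and `"inverse_ratio"` (`w_k = N / n_k`); `"uniform"` sets all
#' weights to 1. Classes are pooled entity classes (`B-` and `I-` tags of a
#' class share one weight) plus `O`.
#'
#' @param counts named numeric vector of per-class token counts `n_k`
#'   (typically from [class_token_counts]).
#' @param strategy one of `"balanced"`, `"inverse_count"`, `"inverse_ratio"`,
#'   `"uniform"`.
#' @param smooth if `TRUE`, add-one smooth zero counts (`n_k <- n_k + 1` for
#'   all classes); by default a zero count is an error, since it usually
#'   signals a corpus bug.
#' @return An object of class `class_weights`: list with `weights` (named,
#'   per class), `strategy`, `counts`, `N`, `K`.
#' @examples
#' compute_class_weights(c(O = 90, ADR = 10))
#' @export
compute_class_weights <- function(counts,
                                  strategy = c("balanced", "inverse_count",
                                               "inverse_ratio", "uniform"),
                                  smooth = FALSE) {
  strategy <- match.arg(strategy)
  counts <- unlist(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector of per-class token counts")
  }
  if (any(counts < 0)) stop("negative class count")
  if (any(counts == 0)) {
    if (smooth) counts <- counts + 1
    else stop("zero token count for class(es): ",
              paste(names(counts)[counts == 0], collapse = ", "),
              " (set smooth = TRUE to add-one smooth)")
  }
  N <- sum(counts)
  K <- length(counts)
  w <- switch(strategy,
              balanced      = N / (K * counts),
              inverse_count = 1 / counts,
              inverse_ratio = N / counts,
              uniform       = stats::setNames(rep(1, K), names(counts)))
  structure(list(weights = w, strategy = strategy, counts = counts,
                 N = N, K = K),
            class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat("Class weights (", x$strategy, " strategy, N = ", x$N, ", K = ", x$K,
      "):\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

#' Expand pooled class weights to per-tag weights
#'
#' Maps class-level weights onto the tag alphabet: `O` keeps its own weight
#' and `B-X` / `I-X` share the weight of class `X`.
#'
#' @param class_weights a [compute_class_weights] result (or a named numeric
#'   vector of per-class weights).
#' @param alphabet a [label_alphabet].
#' @return Numeric vector of length `K` (one weight per tag, alphabet order).
#' @export
tag_weights <- function(class_weights, alphabet) {
  w <- if (inherits(class_weights, "class_weights")) class_weights$weights
       else unlist(class_weights)
  cls <- tag_class(alphabet$tags)
  missing <- setdiff(unique(cls), names(w))
  if (length(missing)) stop("no weight for class(es): ",
                            paste(missing, collapse = ", "))
  unname(w[cls])
}

check_tag_weights <- function(weights, K) {
  weights <- as.numeric(weights)
  if (length(weights) != K) {
    stop("weight vector length ", length(weights), " != K = ", K)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("tag weights must be positive and finite")
  }
  weights
}

#' Class-weighted CRF loss
#'
#' The weighted training objective: each position contributes the negative
#' log posterior marginal of its gold tag, scaled by that tag's class weight,
#'
#' \deqn{L = \sum_i w_{c(y_i)} \, (-\log m_{i, y_i})}
#'
#' where the marginals `m` come from the forward-backward algorithm, so label
#' transitions still shape every term. With all weights 1 and zero
#' transitions the loss reduces exactly to the sum of per-token softmax
#' cross-entropies. The loss is a sum over tokens (no averaging).
#'
#' @param pot a [potential_tables].
#' @param labels integer gold tag indices, length `N`.
#' @param weights per-tag positive weights, length `K` (see [tag_weights]).
#' @param mask optional logical vector, length `N`; positions with `FALSE`
#'   (e.g. non-initial subword pieces) contribute nothing.
#' @return A single non-negative number.
#' @export
weighted_crf_nll <- function(pot, labels, weights, mask = NULL) {
  labels <- check_labels(pot, labels)
  weights <- check_tag_weights(weights, pot$K)
  mask <- check_mask(mask, pot$N)
  m <- posterior_marginals(pot)
  gold <- m[cbind(seq_len(pot$N), labels)]
  sum((weights[labels] * (-log(gold)))[mask])
}

check_mask <- function(mask, N) {
  if (is.null(mask)) return(rep(TRUE, N))
  mask <- as.logical(mask)
  if (length(mask) != N) stop("mask length != N")
  mask
}

# loss + analytic gradients of the weighted CRF loss wrt emissions and
# transitions, by reverse-mode accumulation through the forward and backward
# log-sum-exp recursions (same O(N K^2) cost as inference)
weighted_crf_grad <- function(pot, labels, weights, mask = NULL) {
  labels <- check_labels(pot, labels)
  weights <- check_tag_weights(weights, pot$K)
  mask <- check_mask(mask, pot$N)
  N <- pot$N; K <- pot$K
  ks <- seq_len(K)
  A <- pot$transitions[ks, ks, drop = FALSE]
  P <- pot$emissions
  alpha <- forward_messages(pot)
  beta <- backward_messages(pot)
  aend <- pot$transitions[ks, pot$end]
  logZ <- log_sum_exp(alpha[N, ] + aend)

  w_pos <- weights[labels] * mask          # per-position weight, 0 if masked
  loss <- sum(w_pos * (logZ - alpha[cbind(seq_len(N), labels)] -
                         beta[cbind(seq_len(N), labels)]))
  W <- sum(w_pos)

  dP <- matrix(0, N, K)
  dA <- matrix(0, K, K)
  d_start <- numeric(K)
  d_end <- numeric(K)

  # ---- adjoints of alpha ----
  abar <- matrix(0, N, K)
  abar[cbind(seq_len(N), labels)] <- -w_pos
  q <- exp(alpha[N, ] + aend - logZ)       # softmax at the end transition
  abar[N, ] <- abar[N, ] + W * q
  d_end <- d_end + W * q
  if (N > 1L) {
    for (i in N:2L) {
      g <- abar[i, ]
      dP[i, ] <- dP[i, ] + g
      # S[j, k] = P(prev tag = j | alpha recursion into tag k at position i)
      S <- exp(outer(alpha[i - 1L, ], alpha[i, ] - P[i, ], "-") + A)
      abar[i - 1L, ] <- abar[i - 1L, ] + as.vector(S %*% g)
      dA <- dA + S * rep(g, each = K)
    }
  }
  dP[1L, ] <- dP[1L, ] + abar[1L, ]
  d_start <- d_start + abar[1L, ]

  # ---- adjoints of beta ----
  bbar <- matrix(0, N, K)
  bbar[cbind(seq_len(N), labels)] <- -w_pos
  if (N > 1L) {
    for (i in 1:(N - 1L)) {
      g <- bbar[i, ]
      nxt <- P[i + 1L, ] + beta[i + 1L, ]
      # R[k, j] = P(next tag = j | beta recursion out of tag k at position i)
      R <- exp(outer(-beta[i, ], nxt, "+") + A)
      contrib <- colSums(R * g)
      dA <- dA + R * g
      dP[i + 1L, ] <- dP[i + 1L, ] + contrib
      bbar[i + 1L, ] <- bbar[i + 1L, ] + contrib
    }
  }
  d_end <- d_end + bbar[N, ]

  dAfull <- matrix(0, K + 2L, K + 2L)
  dAfull[ks, ks] <- dA
  dAfull[pot$start, ks] <- d_start
  dAfull[ks, pot$end] <- d_end
  list(loss = loss, d_emissions = dP, d_transitions = dAfull)
}

# loss + gradients of the standard CRF negative log-likelihood
crf_nll_grad <- function(pot, labels) {
  labels <- check_labels(pot, labels)
  N <- pot$N; K <- pot$K
  ks <- seq_len(K)
  A <- pot$transitions[ks, ks, drop = FALSE]
  P <- pot$emissions
  alpha <- forward_messages(pot)
  beta <- backward_messages(pot)
  aend <- pot$transitions[ks, pot$end]
  logZ <- log_sum_exp(alpha[N, ] + aend)
  loss <- logZ - score_path(pot, labels)

  m <- exp(alpha + beta - logZ)
  dP <- m
  dP[cbind(seq_len(N), labels)] <- dP[cbind(seq_len(N), labels)] - 1

  dA <- matrix(0, K, K)
  if (N > 1L) {
    for (i in 1:(N - 1L)) {
      p2 <- exp(outer(alpha[i, ], P[i + 1L, ] + beta[i + 1L, ], "+") + A - logZ)
      dA <- dA + p2
      dA[labels[i], labels[i + 1L]] <- dA[labels[i], labels[i + 1L]] - 1
    }
  }
  d_start <- m[1L, ]; d_start[labels[1L]] <- d_start[labels[1L]] - 1
  d_end <- m[N, ]; d_end[labels[N]] <- d_end[labels[N]] - 1

  dAfull <- matrix(0, K + 2L, K + 2L)
  dAfull[ks, ks] <- dA
  dAfull[pot$start, ks] <- d_start
  dAfull[ks, pot$end] <- d_end
  list(loss = loss, d_emissions = dP, d_transitions = dAfull)
}

row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Class-weighted softmax cross-entropy
#'
#' Baseline loss that treats every position independently:
#' `sum_i w_{c(y_i)} * (-log softmax(logits_i)[y_i])`. With uniform weights
#' this is plain summed cross-entropy.
#'
#' @param logits numeric `N x K` matrix of per-token tag scores.
#' @param labels integer gold tag indices, length `N`.
#' @param weights per-tag positive weights, length `K`.
#' @param mask optional logical vector, length `N`.
#' @return A single non-negative number.
#' @export
weighted_softmax_ce <- function(logits, labels, weights, mask = NULL) {
  logits <- as.matrix(logits)
  N <- nrow(logits); K <- ncol(logits)
  labels <- as.integer(labels)
  if (length(labels) != N) stop("labels length != nrow(logits)")
  if (any(labels < 1L | labels > K)) stop("label index out of range")
  weights <- check_tag_weights(weights, K)
  mask <- check_mask(mask, N)
  s <- row_softmax(logits)
  sum((weights[labels] * (-log(s[cbind(seq_len(N), labels)])))[mask])
}

softmax_ce_grad <- function(logits, labels, weights, mask = NULL) {
  logits <- as.matrix(logits)
  N <- nrow(logits); K <- ncol(logits)
  weights <- check_tag_weights(weights, K)
  mask <- check_mask(mask, N)
  s <- row_softmax(logits)
  gold <- s[cbind(seq_len(N), labels)]
  w_pos <- weights[labels] * mask
  loss <- sum(w_pos * (-log(gold)))
  d <- s
  d[cbind(seq_len(N), labels)] <- d[cbind(seq_len(N), labels)] - 1
  list(loss = loss, d_logits = d * w_pos)
}

#' Focal loss
#'
#' Cross-entropy modulated by `(1 - p)^gamma`, which down-weights easy
#' (high-probability) tokens and concentrates the training signal on hard
#' ones: `sum_i alpha * (1 - p_i)^gamma * (-log p_i)` where `p_i` is the
#' model probability of the gold tag at position `i`. With `gamma = 0` it
#' reduces to plain cross-entropy.
#'
#' @param probs_of_true numeric vector of gold-tag probabilities in `(0, 1]`.
#' @param gamma focusing exponent, `>= 0`; default 2.
#' @param alpha optional scalar multiplier, default 1 (no per-class term).
#' @return A single non-negative number.
#' @export
focal_loss <- function(probs_of_true, gamma = 2, alpha = 1) {
  p <- as.numeric(probs_of_true)
  if (any(p <= 0 | p > 1)) stop("probabilities must lie in (0, 1]")
  if (gamma < 0) stop("gamma must be >= 0")
  sum(alpha * (1 - p)^gamma * (-log(p)))
}

focal_softmax_grad <- function(logits, labels, gamma = 2, alpha = 1,
                               mask = NULL) {
  logits <- as.matrix(logits)
  N <- nrow(logits); K <- ncol(logits)
  mask <- check_mask(mask, N)
  s <- row_softmax(logits)
  p <- s[cbind(seq_len(N), labels)]
  keep <- as.numeric(mask)
  loss <- sum(keep * alpha * (1 - p)^gamma * (-log(p)))
  # dL/dp, then chain through the softmax row
  dLdp <- keep * alpha * (gamma * (1 - p)^pmax(gamma - 1, 0) * log(p) -
                            (1 - p)^gamma / p)
  if (gamma == 0) dLdp <- keep * alpha * (-1 / p)
  d <- matrix(0, N, K)
  for (i in seq_len(N)) {
    dpdz <- -p[i] * s[i, ]
    dpdz[labels[i]] <- dpdz[labels[i]] + p[i]
    d[i, ] <- dLdp[i] * dpdz
  }
  list(loss = loss, d_logits = d)
}

#' Dice loss
#'
#' One minus a smoothed soft Sørensen-Dice coefficient between predicted
#' probabilities and one-hot gold labels, an approximation of 1 minus the
#' F1 score: `1 - (2 * sum(p*y) + eps) / (sum(p^2) + sum(y^2) + eps)`.
#'
#' @param probs numeric `N x K` matrix of probabilities in `[0, 1]`.
#' @param one_hot numeric `N x K` one-hot gold label matrix.
#' @param eps smoothing constant, default 1 (Sørensen smoothing).
#' @return A number in `[0, 1]`.
#' @export
dice_loss <- function(probs, one_hot, eps = 1) {
  probs <- as.matrix(probs); one_hot <- as.matrix(one_hot)
  if (!all(dim(probs) == dim(one_hot))) stop("shape mismatch")
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  num <- 2 * sum(probs * one_hot) + eps
  den <- sum(probs^2) + sum(one_hot^2) + eps
  1 - num / den
}

dice_softmax_grad <- function(logits, labels, eps = 1, mask = NULL) {
  logits <- as.matrix(logits)
  N <- nrow(logits); K <- ncol(logits)
  mask <- check_mask(mask, N)
  s <- row_softmax(logits)
  y <- matrix(0, N, K)
  y[cbind(seq_len(N), labels)] <- 1
  s_m <- s[mask, , drop = FALSE]
  y_m <- y[mask, , drop = FALSE]
  num <- 2 * sum(s_m * y_m) + eps
  den <- sum(s_m^2) + sum(y_m^2) + eps
  loss <- 1 - num / den
  dLdS <- -(2 * y * den - num * 2 * s) / den^2
  dLdS[!mask, ] <- 0
  d <- matrix(0, N, K)
  for (i in seq_len(N)) {
    g <- dLdS[i, ]
    d[i, ] <- s[i, ] * (g - sum(g * s[i, ]))
  }
  list(loss = loss, d_logits = d)
}

#' Central-difference gradient check
#'
#' Compares an implemented gradient against central finite differences of the
#' loss, coordinate by coordinate, and returns the largest relative
#' deviation. Used throughout the package's tests as the arbiter of the
#' hand-derived analytic gradients.
#'
#' @param loss_fn function taking a numeric parameter vector, returning the
#'   scalar loss.
#' @param grad analytic gradient at `params` (numeric vector, same length).
#' @param params numeric parameter vector at which to check.
#' @param epsilon step size in `(0, 1e-2]`; default `1e-5`.
#' @param coords indices of coordinates to check; default all.
#' @return Maximum over checked coordinates of
#'   `|g_num - g_ana| / max(1, |g_num|, |g_ana|)`.
#' @export
numerical_gradient_check <- function(loss_fn, grad, params, epsilon = 1e-5,
                                     coords = seq_along(params)) {
  if (epsilon <= 0 || epsilon > 1e-2) stop("epsilon must be in (0, 1e-2]")
  if (!is.finite(loss_fn(params))) stop("loss is not finite at params")
  worst <- 0
  for (j in coords) {
    up <- params; up[j] <- up[j] + epsilon
    dn <- params; dn[j] <- dn[j] - epsilon
    g_num <- (loss_fn(up) - loss_fn(dn)) / (2 * epsilon)
    dev <- abs(g_num - grad[j]) / max(1, abs(g_num), abs(grad[j]))
    worst <- max(worst, dev)
  }
  worst
}
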