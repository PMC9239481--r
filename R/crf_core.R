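#' Potential tables for one sequence
#'
#' The linear-chain CRF scores a labeling through two tables: an emission
#' matrix `P` (`N x K`, one row per token, one column per tag) produced by the
#' context encoder, and a transition matrix `A` of size `(K + 2) x (K + 2)`
#' whose entry `A[j, k]` scores moving from tag `j` to tag `k`. The two extra
#' states are the synthetic sentence start (row `K + 1`) and end (column
#' `K + 2`); emissions exist only for real positions.
#'
#' @param emissions numeric `N x K` matrix of per-token tag scores.
#' @param transitions numeric `(K + 2) x (K + 2)` matrix of transition scores.
#' @return An object of class `potential_tables`.
#' @export
potential_tables <- function(emissions, transitions) {
  emissions <- as.matrix(emissions)
  transitions <- as.matrix(transitions)
  N <- nrow(emissions); K <- ncol(emissions)
  if (N < 1L || K < 1L) stop("emissions must be a non-empty N x K matrix")
  if (!all(dim(transitions) == K + 2L)) {
    stop("transitions must be square of size K + 2 = ", K + 2L)
  }
  if (!all(is.finite(emissions)) || !all(is.finite(transitions))) {
    stop("potentials must be finite")
  }
  structure(list(emissions = emissions, transitions = transitions,
                 N = N, K = K, start = K + 1L, end = K + 2L),
            class = "potential_tables")
}

# log(sum(exp(x))) with the max-shift trick; -Inf-safe
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

check_labels <- function(pot, labels) {
  labels <- as.integer(labels)
  if (length(labels) != pot$N) {
    stop("labels length ", length(labels), " != N = ", pot$N)
  }
  if (any(labels < 1L | labels > pot$K)) stop("label index out of range")
  labels
}

#' Unnormalized log-score of one label path
#'
#' Sums the per-token scores `A[y_{i-1}, y_i] + P[i, y_i]`, with the
#' synthetic start state preceding the first token and a final transition
#' into the end state.
#'
#' @param pot a [potential_tables].
#' @param labels integer vector of tag indices in `1..K`, length `N`.
#' @return The path score (log domain), a single finite number.
#' @export
score_path <- function(pot, labels) {
  labels <- check_labels(pot, labels)
  prev <- c(pot$start, labels[-pot$N])
  sum(pot$transitions[cbind(prev, labels)]) +
    sum(pot$emissions[cbind(seq_len(pot$N), labels)]) +
    pot$transitions[labels[pot$N], pot$end]
}

#' Log-partition function via the forward algorithm
#'
#' Computes `log Z`, the log of the sum of exponentiated path scores over all
#' `K^N` labelings, in `O(N K^2)` by the forward recursion carried entirely in
#' log space (log-sum-exp), so no exponential ever overflows.
#'
#' @param pot a [potential_tables].
#' @return `log Z`, a single number.
#' @export
log_partition <- function(pot) {
  alpha <- forward_messages(pot)
  log_sum_exp(alpha[pot$N, ] + pot$transitions[seq_len(pot$K), pot$end])
}

forward_messages <- function(pot) {
  N <- pot$N; K <- pot$K
  A <- pot$transitions[seq_len(K), seq_len(K), drop = FALSE]
  P <- pot$emissions
  alpha <- matrix(0, N, K)
  alpha[1L, ] <- pot$transitions[pot$start, seq_len(K)] + P[1L, ]
  if (N > 1L) {
    for (i in 2:N) {
      prev <- alpha[i - 1L, ]
      m <- max(prev)
      alpha[i, ] <- P[i, ] + m +
        log(as.vector(crossprod(exp(prev - m), exp(A - max(A)))) ) + max(A)
    }
  }
  alpha
}

backward_messages <- function(pot) {
  N <- pot$N; K <- pot$K
  A <- pot$transitions[seq_len(K), seq_len(K), drop = FALSE]
  P <- pot$emissions
  beta <- matrix(0, N, K)
  beta[N, ] <- pot$transitions[seq_len(K), pot$end]
  if (N > 1L) {
    for (i in (N - 1L):1L) {
      nxt <- beta[i + 1L, ] + P[i + 1L, ]
      m <- max(nxt)
      beta[i, ] <- m + log(as.vector(exp(A - max(A)) %*% exp(nxt - m))) + max(A)
    }
  }
  beta
}

#' Posterior marginal tag probabilities
#'
#' Runs the forward-backward algorithm and returns `m[i, k] = P(y_i = k | X)`,
#' the exact per-position posterior over tags under the CRF distribution.
#' Each row sums to 1.
#'
#' @param pot a [potential_tables].
#' @return An `N x K` matrix of probabilities.
#' @export
posterior_marginals <- function(pot) {
  alpha <- forward_messages(pot)
  beta <- backward_messages(pot)
  logZ <- log_sum_exp(alpha[pot$N, ] + pot$transitions[seq_len(pot$K), pot$end])
  m <- exp(alpha + beta - logZ)
  m / rowSums(m)  # absorb residual float error; rows already ~1
}

#' Negative log-likelihood of a labeling under the CRF
#'
#' `log Z - score_path`, the standard CRF training objective for one
#' sequence; non-negative up to floating-point error.
#'
#' @param pot a [potential_tables].
#' @param labels integer tag indices, length `N`.
#' @return A single non-negative number.
#' @export
crf_nll <- function(pot, labels) {
  log_partition(pot) - score_path(pot, labels)
}

#' Viterbi decoding
#'
#' Returns a maximum-score label path by dynamic programming. Ties are broken
#' toward the lowest tag index at each backtracking step, so decoding is
#' deterministic.
#'
#' @param pot a [potential_tables].
#' @return Integer vector of tag indices, length `N`.
#' @export
viterbi_decode <- function(pot) {
  N <- pot$N; K <- pot$K
  A <- pot$transitions[seq_len(K), seq_len(K), drop = FALSE]
  P <- pot$emissions
  delta <- matrix(-Inf, N, K)
  back <- matrix(0L, N, K)
  delta[1L, ] <- pot$transitions[pot$start, seq_len(K)] + P[1L, ]
  if (N > 1L) {
    for (i in 2:N) {
      cand <- delta[i - 1L, ] + A          # K x K: row j = from tag j
      best <- apply(cand, 2L, which.max)   # which.max takes the first (lowest) index
      back[i, ] <- best
      delta[i, ] <- P[i, ] + cand[cbind(best, seq_len(K))]
    }
  }
  final <- delta[N, ] + pot$transitions[seq_len(K), pot$end]
  path <- integer(N)
  path[N] <- which.max(final)
  if (N > 1L) {
    for (i in N:2L) path[i - 1L] <- back[i, path[i]]
  }
  path
}

#' Exhaustive path enumeration oracle
#'
#' Brute-force reference for the dynamic programs: enumerates all `K^N`
#' label paths and computes the log-partition, the best path (ties toward the
#' lexicographically smallest path) and the posterior marginals directly.
#' Only feasible for tiny instances; intended for testing.
#'
#' @param pot a [potential_tables] with `K^N <= 1e6`.
#' @return A list with `log_partition`, `best_path` and `marginals`.
#' @export
enumerate_oracle <- function(pot) {
  N <- pot$N; K <- pot$K
  if (K^N > 1e6) stop("instance too large to enumerate (K^N > 1e6)")
  # rows come out in lexicographic path order, so which.max picks the
  # lexicographically smallest maximizer on exact ties
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), N))[, N:1, drop = FALSE])
  colnames(paths) <- NULL
  scores <- apply(paths, 1L, function(y) score_path(pot, y))
  logZ <- log_sum_exp(scores)
  probs <- exp(scores - logZ)
  marg <- matrix(0, N, K)
  for (i in seq_len(N)) {
    for (k in seq_len(K)) marg[i, k] <- sum(probs[paths[, i] == k])
  }
  list(log_partition = logZ,
       best_path = as.integer(paths[which.max(scores), ]),
       marginals = marg)
}
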