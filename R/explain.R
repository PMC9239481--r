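#' Perturbed copies of a sentence
#'
#' Generates the neighborhood a local surrogate is fitted on: each variant
#' keeps the target token and masks a random subset of the remaining context
#' tokens. Masking replaces a token with the UNK word rather than deleting
#' it, so sequence length — and hence the target position — is preserved.
#'
#' @param tokens character vector of tokens (length >= 2; a single-token
#'   sentence has no context to perturb).
#' @param target_index 1-based position of the token being explained.
#' @param n_samples number of perturbed variants; default 1000.
#' @param removal_rate probability that each context token is masked in a
#'   variant; default 0.5.
#' @param seed integer seed; the variant set is deterministic given it.
#' @param unk_token replacement string for masked tokens; default `"<unk>"`
#'   (anything outside the model vocabulary maps to UNK).
#' @return A list with `variants` (list of token vectors; the first variant
#'   is always the unperturbed sentence), `masks` (`n_samples x (N - 1)`
#'   0/1 matrix over context positions; 1 = token present) and
#'   `context_index` (the sentence positions the mask columns refer to).
#' @export
perturb_sequence <- function(tokens, target_index, n_samples = 1000L,
                             removal_rate = 0.5, seed = 1L,
                             unk_token = "<unk>") {
  tokens <- as.character(tokens)
  N <- length(tokens)
  if (N < 2L) stop("single-token sequence: no context to perturb")
  if (target_index < 1L || target_index > N) stop("target index out of range")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  context_index <- setdiff(seq_len(N), target_index)
  set.seed(seed)
  masks <- matrix(stats::rbinom(n_samples * length(context_index), 1L,
                                1 - removal_rate),
                  n_samples, length(context_index))
  masks[1L, ] <- 1L  # anchor the fit at the intact sentence
  variants <- lapply(seq_len(n_samples), function(s) {
    v <- tokens
    v[context_index[masks[s, ] == 0L]] <- unk_token
    v
  })
  list(variants = variants, masks = masks, context_index = context_index)
}

#' Fit the local linear surrogate
#'
#' Weighted least-squares regression of the model's target-label probability
#' on the presence bits of the context tokens, with an exponential proximity
#' kernel `exp(-d^2 / width^2)` on the number of masked tokens `d`, so
#' variants close to the original sentence dominate the fit. The coefficient
#' of a context token is its contribution: the amount by which its presence
#' raises (positive) or lowers (negative) the predicted probability.
#'
#' @param masks 0/1 matrix of presence bits (`n_samples x n_context`).
#' @param probabilities model probability of the target label for each
#'   variant, length `n_samples`.
#' @param kernel_width proximity kernel width in masked-token units;
#'   default 25.
#' @return Numeric vector of per-context-token contribution weights, plus an
#'   `"intercept"` attribute.
#' @export
fit_local_surrogate <- function(masks, probabilities, kernel_width = 25) {
  masks <- as.matrix(masks)
  probabilities <- as.numeric(probabilities)
  if (nrow(masks) != length(probabilities)) {
    stop("masks and probabilities disagree in sample count")
  }
  if (nrow(unique(masks)) < 2L) stop("need at least 2 distinct masks")
  d <- rowSums(masks == 0)
  kw <- exp(-d^2 / kernel_width^2)
  X <- cbind(1, masks)
  fit <- stats::lm.wfit(X, probabilities, kw)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    stop("rank-deficient design after weighting: some context tokens are ",
         "never varied; increase n_samples or the removal rate")
  }
  structure(unname(beta[-1L]), intercept = unname(beta[1L]))
}

#' Expected probability after removing context tokens
#'
#' The additive reading of a local explanation: removing a set of context
#' tokens is expected to change the target-label probability by minus the
#' sum of their contributions, clipped into `[0, 1]`. E.g. with base
#' probability 0.95 and removed contributions 0.33 and 0.31 the expected
#' probability is 0.95 - 0.33 - 0.31 = 0.31.
#'
#' @param base_probability model probability of the target label on the
#'   intact sentence, in `[0, 1]`.
#' @param contributions numeric vector of per-context-token weights.
#' @param removed_indices indices into `contributions` of the removed
#'   tokens (possibly empty).
#' @return The expected probability, a number in `[0, 1]`.
#' @examples
#' removal_effect(0.95, c(0.33, 0.31), c(1, 2))
#' @export
removal_effect <- function(base_probability, contributions,
                           removed_indices = integer()) {
  if (base_probability < 0 || base_probability > 1) {
    stop("base probability must lie in [0, 1]")
  }
  removed_indices <- as.integer(removed_indices)
  if (length(removed_indices) &&
      (min(removed_indices) < 1L ||
       max(removed_indices) > length(contributions))) {
    stop("removed index out of range")
  }
  min(1, max(0, base_probability - sum(contributions[removed_indices])))
}

#' Explain one token's predicted label
#'
#' The full local-explanation procedure for a fitted tagger: predict the
#' sentence, take the posterior marginal probability of the target token's
#' label as the quantity to explain, probe the model on perturbed copies of
#' the sentence ([perturb_sequence]), and fit the weighted linear surrogate
#' ([fit_local_surrogate]). The result attributes the prediction to the
#' surrounding context tokens.
#'
#' @param object a fitted [wcrf] model.
#' @param tokens character vector of tokens.
#' @param target_index 1-based position of the token to explain.
#' @param target_label tag whose probability is explained; default the
#'   model's predicted tag at the target position.
#' @param n_samples number of perturbed variants; default 1000.
#' @param kernel_width proximity kernel width; default 25.
#' @param removal_rate context masking probability per token; default 0.5.
#' @param seed integer seed; explanations are a pure function of (model,
#'   sentence, seed).
#' @return An object of class `wcrf_explanation`: list with `target_index`,
#'   `target_token`, `target_label`, `base_probability`, `contributions`
#'   (named by context token, ordered by sentence position) and
#'   `context_index`.
#' @export
explain_token <- function(object, tokens, target_index, target_label = NULL,
                          n_samples = 1000L, kernel_width = 25,
                          removal_rate = 0.5, seed = 1L) {
  stopifnot(inherits(object, "wcrf"))
  tokens <- as.character(tokens)
  if (is.null(target_label)) {
    target_label <- predict(object, tokens)$labels[[target_index]]
  }
  lab_idx <- tag_index(target_label, object$alphabet)
  prob_of <- function(toks) {
    m <- predict(object, toks, type = "marginals")
    m[target_index, lab_idx]
  }
  pert <- perturb_sequence(tokens, target_index, n_samples, removal_rate,
                           seed)
  probs <- vapply(pert$variants, prob_of, 0)
  contrib <- fit_local_surrogate(pert$masks, probs, kernel_width)
  names(contrib) <- tokens[pert$context_index]
  structure(list(target_index = target_index,
                 target_token = tokens[[target_index]],
                 target_label = target_label,
                 base_probability = probs[[1L]],
                 contributions = contrib,
                 context_index = pert$context_index),
            class = "wcrf_explanation")
}

#' @export
print.wcrf_explanation <- function(x, ...) {
  cat(sprintf("Explanation for token %d ('%s') as %s (p = %.3f)\n",
              x$target_index, x$target_token, x$target_label,
              x$base_probability))
  ord <- order(abs(x$contributions), decreasing = TRUE)
  df <- data.frame(token = names(x$contributions)[ord],
                   position = x$context_index[ord],
                   contribution = round(unname(x$contributions[ord]), 4))
  print(utils::head(df, 10L), row.names = FALSE)
  invisible(x)
}
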