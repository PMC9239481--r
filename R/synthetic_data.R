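#' Synthetic corpus generator configuration
#'
#' Settings for generating imbalanced BIO-labeled corpora that emulate the
#' token-imbalance structure of social-media ADR data: a large `O` majority
#' (default 86.5% of tokens), short minority entity spans of 1-3 tokens, and
#' sentences around 20 tokens. Words are drawn from class-specific
#' sub-vocabularies with a controllable signal strength, so word identity
#' predicts entity class about as unreliably as one chooses.
#'
#' @param n_sentences number of sentences to generate.
#' @param mean_length mean sentence length in tokens; default 20.
#' @param max_length maximum sentence length; default 36.
#' @param vocab_size number of word types; default 600.
#' @param class_ratios named vector of target token fractions summing to 1;
#'   default `c(O = 0.865, ADR = 0.123, Indication = 0.012)`, the
#'   Twitter-style profile. Classes with ratio 0 are dropped.
#' @param span_length_dist named probability vector over entity span
#'   lengths; default `c("1" = 0.5, "2" = 0.3, "3" = 0.2)`.
#' @param emission_sharpness probability in `[0, 1]` that a token is drawn
#'   from its class's own sub-vocabulary rather than from the shared
#'   vocabulary; higher values make the tagging task easier. Default 0.8.
#' @param seed integer seed; the corpus is deterministic given it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_sentences,
                             mean_length = 20,
                             max_length = 36L,
                             vocab_size = 600L,
                             class_ratios = c(O = 0.865, ADR = 0.123,
                                              Indication = 0.012),
                             span_length_dist = c("1" = 0.5, "2" = 0.3,
                                                  "3" = 0.2),
                             emission_sharpness = 0.8,
                             seed = 1L) {
  stopifnot(n_sentences >= 1L, mean_length >= 1, max_length >= mean_length,
            vocab_size >= 10L, emission_sharpness >= 0,
            emission_sharpness <= 1)
  if (abs(sum(class_ratios) - 1) > 1e-8) {
    stop("class ratios must sum to 1 (got ", sum(class_ratios), ")")
  }
  if (!"O" %in% names(class_ratios)) stop("class_ratios must include 'O'")
  if (any(class_ratios < 0)) stop("negative class ratio")
  if (abs(sum(span_length_dist) - 1) > 1e-8) {
    stop("span length distribution must sum to 1")
  }
  class_ratios <- class_ratios[class_ratios > 0 | names(class_ratios) == "O"]
  structure(list(n_sentences = as.integer(n_sentences),
                 mean_length = mean_length,
                 max_length = as.integer(max_length),
                 vocab_size = as.integer(vocab_size),
                 class_ratios = class_ratios,
                 span_length_dist = span_length_dist,
                 emission_sharpness = emission_sharpness,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic imbalanced labeled corpus
#'
#' Builds sentences by a segment-level Markov process over outside/in-span
#' states: segment types are drawn with probabilities calibrated so that
#' expected token fractions hit the configured class ratios (entity
#' probabilities are divided by the mean span length), span lengths follow
#' the configured distribution (truncated at the sentence boundary), and
#' each token's word is drawn from its class's sub-vocabulary with
#' probability `emission_sharpness`, otherwise from the shared vocabulary.
#' Emitted labels always form valid BIO sequences. A single global seed
#' derives one sub-seed per sentence, so generation is reproducible.
#'
#' @param config a [generator_config].
#' @return A list with `corpus` (a [wcrf_corpus]) and `ground_truth`: the
#'   per-sentence generated spans (`spans`, list of data frames) and the
#'   bookkeeping token counts per class (`class_counts`).
#' @examples
#' g <- generate_corpus(generator_config(n_sentences = 3, seed = 7))
#' corpus_stats(g$corpus)
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ratios <- config$class_ratios
  classes <- setdiff(names(ratios), "O")
  lens <- as.integer(names(config$span_length_dist))
  lbar <- sum(lens * config$span_length_dist)
  # segment-type probabilities: entity classes discounted by mean span length
  seg_w <- c(O = unname(ratios[["O"]]),
             stats::setNames(unname(ratios[classes]) / lbar, classes))
  seg_p <- seg_w / sum(seg_w)

  # sub-vocabulary allocation: every class gets a slice proportional to its
  # token share, at least 5 types
  vocab_words <- sprintf("w%04d", seq_len(config$vocab_size))
  shares <- pmax(round(config$vocab_size * ratios / sum(ratios)), 5L)
  excess <- sum(shares) - config$vocab_size
  if (excess > 0L) shares[[which.max(shares)]] <-
    shares[[which.max(shares)]] - excess
  if (any(shares < 5L)) {
    stop("vocab_size too small for per-class sub-vocabularies")
  }
  cuts <- cumsum(shares)
  sub_vocab <- list()
  lo <- 1L
  for (nm in names(ratios)) {
    sub_vocab[[nm]] <- vocab_words[lo:cuts[[nm]]]
    lo <- cuts[[nm]] + 1L
  }

  set.seed(config$seed)
  sent_seeds <- sample.int(.Machine$integer.max - 1L, config$n_sentences)
  sequences <- vector("list", config$n_sentences)
  spans_list <- vector("list", config$n_sentences)
  class_counts <- stats::setNames(integer(length(ratios)), names(ratios))

  draw_word <- function(class_name) {
    if (stats::runif(1) < config$emission_sharpness) {
      sample(sub_vocab[[class_name]], 1L)
    } else {
      sample(vocab_words, 1L)
    }
  }

  for (s in seq_len(config$n_sentences)) {
    set.seed(sent_seeds[[s]])
    n <- max(1L, min(config$max_length, stats::rpois(1L, config$mean_length)))
    toks <- character(n); labs <- character(n)
    cls_out <- character(); st_out <- integer(); en_out <- integer()
    i <- 1L
    while (i <= n) {
      seg <- sample(names(seg_p), 1L, prob = seg_p)
      if (seg == "O" || length(classes) == 0L) {
        toks[i] <- draw_word("O"); labs[i] <- "O"
        class_counts[["O"]] <- class_counts[["O"]] + 1L
        i <- i + 1L
      } else {
        L <- min(sample(lens, 1L, prob = config$span_length_dist), n - i + 1L)
        toks[i:(i + L - 1L)] <- vapply(seq_len(L), function(j) draw_word(seg),
                                       "")
        labs[i] <- paste0("B-", seg)
        if (L > 1L) labs[(i + 1L):(i + L - 1L)] <- paste0("I-", seg)
        cls_out <- c(cls_out, seg)
        st_out <- c(st_out, i - 1L)
        en_out <- c(en_out, i - 1L + L)
        class_counts[[seg]] <- class_counts[[seg]] + L
        i <- i + L
      }
    }
    sequences[[s]] <- labeled_sequence(toks, labs)
    spans_list[[s]] <- data.frame(class = cls_out, start = st_out,
                                  end = en_out, stringsAsFactors = FALSE)
  }

  alphabet <- label_alphabet(classes)
  list(corpus = wcrf_corpus(sequences, alphabet),
       ground_truth = list(spans = spans_list, class_counts = class_counts))
}

#' Corpus summary statistics
#'
#' The usual descriptive table for an imbalanced tagging corpus: sample
#' count, maximum and mean sentence length, vocabulary size, total tokens,
#' and per-class token counts with percentages.
#'
#' @param corpus a non-empty [wcrf_corpus].
#' @return An object of class `corpus_stats`: list with `samples`,
#'   `max_length`, `mean_length`, `vocab`, `tokens`, `class_counts` and
#'   `class_pct`.
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "wcrf_corpus"))
  if (length(corpus$sequences) == 0L) stop("empty corpus")
  lens <- vapply(corpus$sequences, length, 1L)
  counts <- class_token_counts(corpus)
  structure(list(samples = length(corpus$sequences),
                 max_length = max(lens),
                 mean_length = mean(lens),
                 vocab = length(unique(unlist(lapply(corpus$sequences,
                                                     `[[`, "tokens")))),
                 tokens = sum(lens),
                 class_counts = counts,
                 class_pct = 100 * counts / sum(counts)),
            class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("Samples %d | Max length %d | Mean length %.1f | Vocab %d | Tokens %d\n",
              x$samples, x$max_length, x$mean_length, x$vocab, x$tokens))
  for (nm in names(x$class_counts)) {
    cat(sprintf("  %-12s %8d tokens  %5.1f%%\n", nm, x$class_counts[[nm]],
                x$class_pct[[nm]]))
  }
  invisible(x)
}
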