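#' Labeled token sequence
#'
#' Constructs the basic unit of training and evaluation: a sentence as a
#' character vector of tokens with one BIO tag per token.
#'
#' @param tokens character vector of pre-tokenized words.
#' @param labels character vector of tags, same length as `tokens`; each tag is
#'   `"O"` or `"B-<class>"` / `"I-<class>"`.
#' @return An object of class `labeled_sequence`: a list with elements
#'   `tokens` and `labels`.
#' @examples
#' labeled_sequence(c("sleep", "paralysis"), c("B-ADR", "I-ADR"))
#' @export
labeled_sequence <- function(tokens, labels) {
  tokens <- as.character(tokens)
  labels <- as.character(labels)
  if (length(tokens) != length(labels)) {
    stop("tokens and labels must have the same length (",
         length(tokens), " vs ", length(labels), ")")
  }
  bad <- labels[!is_valid_tag_shape(labels)]
  if (length(bad)) {
    stop("malformed tag(s): ", paste(unique(bad), collapse = ", "))
  }
  structure(list(tokens = tokens, labels = labels),
            class = "labeled_sequence")
}

#' @export
print.labeled_sequence <- function(x, ...) {
  cat(paste(x$tokens, x$labels, sep = "/"), "\n")
  invisible(x)
}

#' @export
length.labeled_sequence <- function(x) length(x$tokens)

is_valid_tag_shape <- function(tags) {
  tags == "O" | grepl("^[BI]-.+$", tags)
}

tag_class <- function(tags) {
  ifelse(tags == "O", "O", sub("^[BI]-", "", tags))
}

tag_prefix <- function(tags) {
  ifelse(tags == "O", "O", substr(tags, 1L, 1L))
}

#' Label alphabet with synthetic boundary states
#'
#' Builds the tag inventory for a set of entity classes. For `m` classes the
#' alphabet holds `K = 2m + 1` tags (`O` plus `B-`/`I-` per class), and the
#' CRF transition matrix over this alphabet has dimension `K + 2`: two extra
#' synthetic states mark the start and end of every sentence.
#'
#' @param classes character vector of entity class names (e.g. `c("ADR",
#'   "Indication")`); order is preserved.
#' @return An object of class `label_alphabet` with elements `classes`, `tags`
#'   (length `K`, `O` first), `K`, `start_index` (`K + 1`) and `end_index`
#'   (`K + 2`).
#' @examples
#' ab <- label_alphabet(c("ADR", "Indication"))
#' ab$tags
#' @export
label_alphabet <- function(classes) {
  classes <- as.character(classes)
  if (anyDuplicated(classes)) stop("duplicate class names")
  if ("O" %in% classes) stop("'O' is not an entity class")
  tags <- c("O", as.vector(rbind(paste0("B-", classes), paste0("I-", classes))))
  if (length(classes) == 0L) tags <- "O"
  K <- length(tags)
  structure(list(classes = classes, tags = tags, K = K,
                 start_index = K + 1L, end_index = K + 2L),
            class = "label_alphabet")
}

#' @export
print.label_alphabet <- function(x, ...) {
  cat("Label alphabet: K =", x$K, "tags (", paste(x$tags, collapse = ", "),
      "), start/end states", x$start_index, "/", x$end_index, "\n")
  invisible(x)
}

tag_index <- function(labels, alphabet) {
  idx <- match(labels, alphabet$tags)
  if (anyNA(idx)) {
    stop("tag(s) not in alphabet: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Labeled corpus
#'
#' Bundles labeled sequences with the label alphabet they are tagged over.
#'
#' @param sequences list of [labeled_sequence] objects.
#' @param alphabet a [label_alphabet]; if `NULL`, inferred from the classes
#'   observed in `sequences` (sorted alphabetically).
#' @return An object of class `wcrf_corpus` with elements `sequences` and
#'   `alphabet`.
#' @export
wcrf_corpus <- function(sequences, alphabet = NULL) {
  stopifnot(is.list(sequences))
  if (is.null(alphabet)) {
    seen <- unique(unlist(lapply(sequences, function(s) tag_class(s$labels))))
    alphabet <- label_alphabet(sort(setdiff(seen, "O")))
  }
  for (s in sequences) tag_index(s$labels, alphabet)  # validates membership
  structure(list(sequences = sequences, alphabet = alphabet),
            class = "wcrf_corpus")
}

#' @export
print.wcrf_corpus <- function(x, ...) {
  cat("Corpus:", length(x$sequences), "sequences,",
      sum(vapply(x$sequences, length, 1L)), "tokens, classes:",
      if (length(x$alphabet$classes)) paste(x$alphabet$classes, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' @export
length.wcrf_corpus <- function(x) length(x$sequences)

#' Read a CoNLL-style labeled corpus
#'
#' Reads the token-per-line dialect: one `token<TAB>label` pair per line,
#' sentences separated by blank lines, UTF-8.
#'
#' @param path a file path or connection.
#' @param alphabet optional [label_alphabet]; inferred from the observed tags
#'   when `NULL`.
#' @return A [wcrf_corpus].
#' @examples
#' f <- tempfile()
#' writeLines(c("sleep\tB-ADR", "paralysis\tI-ADR", ""), f)
#' read_conll(f)
#' @export
read_conll <- function(path, alphabet = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sequences <- list()
  toks <- character()
  labs <- character()
  flush_sentence <- function() {
    if (length(toks)) {
      sequences[[length(sequences) + 1L]] <<- labeled_sequence(toks, labs)
      toks <<- character(); labs <<- character()
    }
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) { flush_sentence(); next }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 2L || !nzchar(fields[[1L]])) {
      stop("parse error at line ", i, ": expected 'token<TAB>label', got ",
           deparse(line))
    }
    if (!is_valid_tag_shape(fields[[2L]])) {
      stop("parse error at line ", i, ": unknown tag shape ",
           deparse(fields[[2L]]))
    }
    toks <- c(toks, fields[[1L]])
    labs <- c(labs, fields[[2L]])
  }
  flush_sentence()
  wcrf_corpus(sequences, alphabet)
}

#' Write a corpus in CoNLL-style format
#'
#' Emits exactly the dialect accepted by [read_conll]: `token<TAB>label`
#' lines with one blank line after each sentence (including the last).
#'
#' @param corpus a [wcrf_corpus].
#' @param path a file path or connection.
#' @return Invisibly, `corpus`.
#' @export
write_conll <- function(corpus, path) {
  stopifnot(inherits(corpus, "wcrf_corpus"))
  out <- unlist(lapply(corpus$sequences, function(s) {
    c(paste(s$tokens, s$labels, sep = "\t"), "")
  }))
  if (is.null(out)) out <- character()
  writeLines(out, path, useBytes = TRUE)
  invisible(corpus)
}

#' Validate BIO tag transitions
#'
#' Checks the continuation rule of the BIO scheme: an `I-X` tag may only
#' follow `B-X` or `I-X` of the same class. In particular `I-ADR` cannot be
#' connected after `B-Indication`, nor may a sentence start with `I-X`.
#'
#' @param labels character vector of tags.
#' @param alphabet a [label_alphabet]; tags outside it are an error.
#' @return A data frame with columns `position` (1-based) and `rule`
#'   describing each violation; zero rows iff the labeling is valid.
#' @examples
#' ab <- label_alphabet(c("ADR", "Indication"))
#' validate_boi(c("B-Indication", "I-ADR"), ab)
#' @export
validate_boi <- function(labels, alphabet) {
  tag_index(labels, alphabet)
  pos <- integer()
  rule <- character()
  prev <- NULL
  for (i in seq_along(labels)) {
    lab <- labels[[i]]
    if (tag_prefix(lab) == "I") {
      cls <- tag_class(lab)
      ok <- !is.null(prev) && tag_prefix(prev) %in% c("B", "I") &&
        tag_class(prev) == cls
      if (!ok) {
        pos <- c(pos, i)
        rule <- c(rule, sprintf("%s cannot follow %s", lab,
                                if (is.null(prev)) "sentence start" else prev))
      }
    }
    prev <- lab
  }
  data.frame(position = pos, rule = rule, stringsAsFactors = FALSE)
}

#' Extract entity spans from a BIO labeling
#'
#' Materializes maximal `B-X (I-X)*` runs as spans. Invalid continuations
#' (an `I-X` with no live `X` span, e.g. after `O` or after a tag of another
#' class) are repaired as a fresh `B-X`, the standard CoNLL convention;
#' [validate_boi] still reports them.
#'
#' @param labels character vector of tags.
#' @return A data frame with columns `class`, `start` (0-based inclusive) and
#'   `end` (0-based exclusive), one row per span, in sentence order.
#' @examples
#' extract_spans(c("O", "B-ADR", "I-ADR", "O"))
#' @export
extract_spans <- function(labels) {
  cls_out <- character(); start_out <- integer(); end_out <- integer()
  open_class <- NULL
  open_start <- NA_integer_
  close_span <- function(end_pos) {
    if (!is.null(open_class)) {
      cls_out <<- c(cls_out, open_class)
      start_out <<- c(start_out, open_start)
      end_out <<- c(end_out, end_pos)
      open_class <<- NULL
    }
  }
  for (i in seq_along(labels)) {
    lab <- labels[[i]]
    pre <- tag_prefix(lab)
    if (pre == "O") {
      close_span(i - 1L)
    } else if (pre == "B") {
      close_span(i - 1L)
      open_class <- tag_class(lab)
      open_start <- i - 1L
    } else {  # I-
      cls <- tag_class(lab)
      if (is.null(open_class) || open_class != cls) {
        close_span(i - 1L)  # repair: treat as a new B-X
        open_class <- cls
        open_start <- i - 1L
      }
    }
  }
  close_span(length(labels))
  data.frame(class = cls_out, start = start_out, end = end_out,
             stringsAsFactors = FALSE)
}

spans_to_labels <- function(spans, n) {
  labels <- rep("O", n)
  if (nrow(spans)) {
    for (r in seq_len(nrow(spans))) {
      s <- spans$start[[r]] + 1L
      e <- spans$end[[r]]
      labels[s] <- paste0("B-", spans$class[[r]])
      if (e > s) labels[(s + 1L):e] <- paste0("I-", spans$class[[r]])
    }
  }
  labels
}

#' Per-class token counts
#'
#' Counts tokens by entity class, pooling `B-` and `I-` tags of a class, with
#' `O` as its own category. The counts always sum to the corpus token total.
#'
#' @param corpus a non-empty [wcrf_corpus].
#' @return A named integer vector with one entry per class in the alphabet
#'   order (`O` first).
#' @export
class_token_counts <- function(corpus) {
  stopifnot(inherits(corpus, "wcrf_corpus"))
  if (length(corpus$sequences) == 0L) stop("empty corpus")
  groups <- c("O", corpus$alphabet$classes)
  counts <- stats::setNames(integer(length(groups)), groups)
  all_cls <- tag_class(unlist(lapply(corpus$sequences, `[[`, "labels")))
  tab <- table(factor(all_cls, levels = groups))
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Entity token ratio of one sentence
#'
#' The percentage of tokens in a sentence carrying a given entity class
#' (pooling `B-` and `I-` tags), e.g. the fraction of words naming an ADR
#' symptom. Values are rounded half-up to two decimals.
#'
#' @param sequence a non-empty [labeled_sequence].
#' @param class_name entity class to measure; default `"ADR"`.
#' @return The percentage as a number in `[0, 100]`.
#' @examples
#' s <- labeled_sequence(rep("w", 12), c(rep("O", 2), "B-ADR", rep("O", 9)))
#' adr_token_ratio(s)  # 8.33
#' @export
adr_token_ratio <- function(sequence, class_name = "ADR") {
  stopifnot(inherits(sequence, "labeled_sequence"))
  n <- length(sequence$tokens)
  if (n == 0L) stop("empty sequence")
  hits <- sum(tag_class(sequence$labels) == class_name)
  round_half_up(100 * hits / n, 2L)
}

round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
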