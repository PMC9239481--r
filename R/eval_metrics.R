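#' Approximate-match token counts for one sentence
#'
#' Token-level confusion counts for one entity class under the
#' approximate-matching convention used for ADR span evaluation: a predicted
#' span that overlaps a gold span of the class by at least one token is
#' credited in full. Concretely, a predicted class token is a true positive
#' when its span overlaps some gold span of that class; predicted class
#' tokens in spans overlapping no gold span are false positives; gold class
#' tokens in spans overlapped by no prediction are false negatives. So with
#' a gold mention *sleep paralysis*, predicting either *lasting sleep
#' paralysis* or just *paralysis* leaves no false negative for that span.
#' `match = "strict"` instead requires exact span boundaries and never
#' yields more true positives than approximate matching.
#'
#' @param gold_labels character vector of gold tags.
#' @param predicted_labels character vector of predicted tags, same length.
#' @param class_name entity class to score.
#' @param match `"approx"` (default) or `"strict"`.
#' @return A list with integer counts `tp`, `fp`, `fn`.
#' @export
approximate_match_counts <- function(gold_labels, predicted_labels,
                                     class_name,
                                     match = c("approx", "strict")) {
  match <- match.arg(match)
  if (length(gold_labels) != length(predicted_labels)) {
    stop("gold and predicted label sequences differ in length")
  }
  keep <- gold_labels != "[IGN]"
  gold_labels <- gold_labels[keep]
  predicted_labels <- predicted_labels[keep]
  g <- span_subset(extract_spans(gold_labels), class_name)
  p <- span_subset(extract_spans(predicted_labels), class_name)
  overlaps <- function(a_start, a_end, b) {
    any(b$start < a_end & b$end > a_start)
  }
  exact <- function(a_start, a_end, b) {
    any(b$start == a_start & b$end == a_end)
  }
  hit <- if (match == "approx") overlaps else exact
  tp <- 0L; fp <- 0L
  if (nrow(p)) {
    for (r in seq_len(nrow(p))) {
      len <- p$end[[r]] - p$start[[r]]
      if (hit(p$start[[r]], p$end[[r]], g)) tp <- tp + len else fp <- fp + len
    }
  }
  fn <- 0L
  if (nrow(g)) {
    for (r in seq_len(nrow(g))) {
      if (!hit(g$start[[r]], g$end[[r]], p)) {
        fn <- fn + g$end[[r]] - g$start[[r]]
      }
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

span_subset <- function(spans, class_name) {
  spans[spans$class == class_name, , drop = FALSE]
}

#' Precision, recall and F1 from match counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)` and their
#' harmonic mean `f1 = 2 P R / (P + R)`. Ratios with zero denominator are
#' defined as 0, so degenerate corpora stay finite.
#'
#' @param counts a list or vector with elements `tp`, `fp`, `fn`.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @examples
#' precision_recall_f1(list(tp = 2, fp = 1, fn = 0))
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  if (min(tp, fp, fn) < 0) stop("counts must be non-negative")
  safe_div <- function(a, b) if (b > 0) a / b else 0
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}
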