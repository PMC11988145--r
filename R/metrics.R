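#' Round half-up to a fixed number of decimals
#'
#' Reporting convention for percentage metrics: ties round away from zero
#' (97.355 -> 97.36), matching how results tables are usually typeset,
#' unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Tally a binary confusion matrix
#'
#' Counts true/false positives and negatives for the estrus detection
#' task. Estrus is the positive class (label 1).
#'
#' @param truth integer vector of true labels in \{0, 1\}.
#' @param estimate integer vector of predicted labels in \{0, 1\}.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`, `n`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion_counts <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate))
  truth <- as.integer(truth)
  estimate <- as.integer(estimate)
  if (!all(truth %in% c(0L, 1L)) || !all(estimate %in% c(0L, 1L))) {
    rlang::abort("labels and predictions must be coded 0/1 (1 = estrus)")
  }
  tibble::tibble(
    tp = sum(truth == 1L & estimate == 1L),
    fp = sum(truth == 0L & estimate == 1L),
    fn = sum(truth == 1L & estimate == 0L),
    tn = sum(truth == 0L & estimate == 0L),
    n  = length(truth)
  )
}

#' Precision, recall and F1 from confusion counts
#'
#' Computes precision `P = TP / (TP + FP) * 100`, recall
#' `R = TP / (TP + FN) * 100` and their harmonic mean
#' `F1 = 2 P R / (P + R)`, all as percentages. Degenerate denominators
#' follow the usual convention (the metric is 0 and the row is flagged):
#' `P = 0` when `TP + FP = 0`, `R = 0` when `TP + FN = 0`, `F1 = 0` when
#' `P + R = 0`.
#'
#' @param counts a data frame with columns `tp`, `fp`, `fn`, `tn`
#'   (e.g. from [confusion_counts()]); extra columns are carried through.
#' @return The input tibble with columns `precision`, `recall`, `f1`
#'   (raw percentages) and a logical `degenerate` flag appended.
#' @examples
#' compute_metrics(tibble::tibble(tp = 92, fp = 1, fn = 4, tn = 95))
#' @export
compute_metrics <- function(counts) {
  counts <- tibble::as_tibble(counts)
  req <- c("tp", "fp", "fn", "tn")
  if (!all(req %in% names(counts))) {
    rlang::abort("counts must have columns tp, fp, fn, tn")
  }
  if (any(counts$tp < 0 | counts$fp < 0 | counts$fn < 0 | counts$tn < 0)) {
    rlang::abort("confusion counts must be nonnegative")
  }
  dplyr::mutate(
    counts,
    precision = ifelse(.data$tp + .data$fp > 0,
                       .data$tp / (.data$tp + .data$fp) * 100, 0),
    recall    = ifelse(.data$tp + .data$fn > 0,
                       .data$tp / (.data$tp + .data$fn) * 100, 0),
    f1        = ifelse(.data$precision + .data$recall > 0,
                       2 * .data$precision * .data$recall /
                         (.data$precision + .data$recall), 0),
    degenerate = .data$tp + .data$fp == 0 | .data$tp + .data$fn == 0 |
      .data$precision + .data$recall == 0
  )
}

#' F1 score from printed precision and recall percentages
#'
#' Harmonic mean of a precision/recall pair already expressed in percent,
#' rounded half-up to two decimals — the form used when re-deriving the
#' F1 column of a results table from its P and R columns.
#'
#' @param p precision in percent, in \[0, 100\].
#' @param r recall in percent, in \[0, 100\].
#' @return F1 in percent, rounded half-up to 2 decimals.
#' @examples
#' f1_from_pr(98.92, 95.83)
#' @export
f1_from_pr <- function(p, r) {
  stopifnot(all(p >= 0 & p <= 100), all(r >= 0 & r <= 100))
  if (any(p + r == 0)) rlang::abort("p + r must be positive")
  round_half_up(2 * p * r / (p + r), 2)
}
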