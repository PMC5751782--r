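# Mention-level exact-span evaluation: micro-averaged precision, recall and
# balanced F-score, plus the ill-legal-sequence-rate diagnostic.

#' Balanced F-score from precision and recall
#'
#' `F = 2PR / (P + R)`, 0 when `P + R = 0`. Works on fractions or on the
#' percent scale (the result is on the same scale as the inputs).
#'
#' @param precision,recall Numeric scalars or vectors.
#' @return The balanced F-score.
#' @examples
#' f_measure(85.08, 85.26)   # 85.17 to two decimals
#' @export
f_measure <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

# Round half up (the convention of printed results tables; R's round() is
# banker's rounding).
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Mention-level precision/recall/F with exact span matching
#'
#' A predicted mention counts as a true positive iff a gold mention has the
#' identical `(doc_id, start, end)` triple; matching is one-to-one and
#' duplicated predictions are collapsed before scoring. Counts are
#' micro-averaged over the corpus.
#'
#' @param pred,gold Mention data.frames with columns `doc_id`, `start`, `end`.
#' @return List of class `mcnn_prf`: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f` (fractions).
#' @export
mention_prf <- function(pred, gold) {
  key <- function(m) {
    if (is.null(m) || nrow(m) == 0L) return(character(0))
    unique(paste(m$doc_id, m$start, m$end, sep = "\r"))
  }
  pk <- key(pred)
  gk <- key(gold)
  tp <- sum(pk %in% gk)
  fp <- length(pk) - tp
  fn <- length(gk) - tp
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f = f_measure(precision, recall)),
            class = "mcnn_prf")
}

#' @export
print.mcnn_prf <- function(x, ...) {
  cat(sprintf("P %.2f  R %.2f  F %.2f  (tp %d, fp %d, fn %d)\n",
              round_half_up(100 * x$precision),
              round_half_up(100 * x$recall),
              round_half_up(100 * x$f), x$tp, x$fp, x$fn))
  invisible(x)
}

#' Fraction of sentences with an ill-legal raw label sequence
#'
#' A sentence is ill-legal if it contains an `I` not preceded by `B` or `I`
#' (the default legality rule). Diagnostic for the effect of the multiple
#' label strategy on raw predictions.
#'
#' @param label_lists List of character label vectors (one per sentence).
#' @return Fraction in \[0, 1\]; 0 for an empty list.
#' @export
illegal_rate <- function(label_lists) {
  if (length(label_lists) == 0L) return(0)
  bad <- vapply(label_lists, function(l) {
    if (length(l) == 0L) return(FALSE)
    any(l == "I" & c("O", l[-length(l)]) == "O")
  }, logical(1))
  mean(bad)
}
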