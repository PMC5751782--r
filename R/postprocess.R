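# Post-processing of raw BIO predictions: repair of ill-legal label
# sequences, Schwartz-Hearst abbreviation extraction, propagation of disease
# labels to abbreviations, and conversion of BIO runs to character spans.

#' Repair ill-legal BIO label sequences
#'
#' Default mode: every `I` whose predecessor is neither `B` nor `I`
#' (including a sentence-initial `I`) is set to `O`, applied left-to-right
#' until stable. Strict mode additionally treats a `B` immediately following
#' a `B` as ill-legal and sets the second `B` to `O` (under standard BIO two
#' adjacent single-token mentions are legal, so this is off by default).
#' Idempotent.
#'
#' @param labels Character vector over `{"B","I","O"}`.
#' @param strict_bb Also repair the `B,B` pattern.
#' @return `list(labels, n_fixed)` where `n_fixed` counts changed positions.
#' @examples
#' repair_illegal(c("O", "I", "O"))$labels   # "O" "O" "O"
#' @export
repair_illegal <- function(labels, strict_bb = FALSE) {
  if (length(labels) == 0L) return(list(labels = labels, n_fixed = 0L))
  if (!all(labels %in% BIO_LABELS)) {
    stop("unknown label symbol: ",
         paste(setdiff(unique(labels), BIO_LABELS), collapse = ", "))
  }
  n_fixed <- 0L
  prev <- "O"
  for (i in seq_along(labels)) {
    if (labels[i] == "I" && prev == "O") {
      labels[i] <- "O"
      n_fixed <- n_fixed + 1L
    } else if (strict_bb && labels[i] == "B" && prev == "B") {
      labels[i] <- "O"
      n_fixed <- n_fixed + 1L
    }
    prev <- labels[i]
  }
  list(labels = labels, n_fixed = n_fixed)
}

#' Extract abbreviation definitions from a document
#'
#' Finds parenthesized short forms `"(SF)"` and aligns them against the
#' preceding tokens with the Schwartz-Hearst character-alignment heuristic:
#' the short form must be 2-10 characters with at least one letter; its
#' alphanumeric characters must occur in order (case-insensitively) in the
#' candidate long form, the first one at a word start; and the long form may
#' span at most `min(|SF| + 5, 2 * |SF|)` words.
#'
#' @param doc A preprocessed document (with `sentences`).
#' @return data.frame with columns `doc_id`, `short`, `long`, `long_start`,
#'   `long_end` (0-based half-open char offsets of the long form).
#' @export
extract_abbreviations <- function(doc) {
  out <- data.frame(doc_id = character(0), short = character(0),
                    long = character(0), long_start = integer(0),
                    long_end = integer(0), stringsAsFactors = FALSE)
  for (toks in doc$sentences) {
    n <- nrow(toks)
    if (n < 3L) next
    opens <- which(toks$text == "(")
    for (oi in opens) {
      close <- which(toks$text == ")" & seq_len(n) > oi)
      if (length(close) == 0L || oi == 1L) next
      ci <- close[1]
      if (ci == oi + 1L) next
      sf <- substr(doc$text, toks$end[oi] + 1L, toks$start[ci])
      sf <- trimws(sf)
      if (nchar(sf) < 2L || nchar(sf) > 10L || !grepl("[A-Za-z]", sf)) next
      if (grepl("[()]", sf)) next
      max_words <- min(nchar(sf) + 5L, 2L * nchar(sf))
      cand_last <- oi - 1L
      cand_first <- max(1L, cand_last - max_words + 1L)
      lf_tokens <- toks[cand_first:cand_last, , drop = FALSE]
      lf_text <- substr(doc$text, lf_tokens$start[1] + 1L,
                        lf_tokens$end[nrow(lf_tokens)])
      start_in_lf <- sh_align(sf, lf_text)
      if (is.null(start_in_lf)) next
      long_start <- lf_tokens$start[1] + start_in_lf - 1L
      # snap to the token containing the aligned start
      tok_i <- which(lf_tokens$start <= long_start & lf_tokens$end > long_start)
      if (length(tok_i) == 0L) next
      long_start <- lf_tokens$start[tok_i[1]]
      long_end <- lf_tokens$end[nrow(lf_tokens)]
      n_words <- nrow(lf_tokens) - tok_i[1] + 1L
      if (n_words > max_words) next
      out <- rbind(out, data.frame(
        doc_id = doc$doc_id, short = sf,
        long = substr(doc$text, long_start + 1L, long_end),
        long_start = long_start, long_end = long_end,
        stringsAsFactors = FALSE))
    }
  }
  unique(out)
}

# Schwartz-Hearst right-to-left alignment. Returns the 1-based character
# position in `lf` where the long form starts, or NULL if no alignment.
sh_align <- function(sf, lf) {
  sfc <- tolower(strsplit(sf, "", fixed = TRUE)[[1]])
  lfc <- tolower(strsplit(lf, "", fixed = TRUE)[[1]])
  i <- length(sfc)
  j <- length(lfc)
  while (i > 0L) {
    c <- sfc[i]
    if (!grepl("[a-z0-9]", c)) {
      i <- i - 1L
      next
    }
    # the first short-form character must match at a word start
    while (j > 0L &&
           (lfc[j] != c ||
            (i == 1L && j > 1L && grepl("[a-z0-9]", lfc[j - 1L])))) {
      j <- j - 1L
    }
    if (j == 0L) return(NULL)
    i <- i - 1L
    j <- j - 1L
  }
  j + 1L
}

#' Propagate disease labels to abbreviation occurrences
#'
#' If an extracted abbreviation pair's long form exactly matches a recognized
#' mention span, every occurrence of the short form in the same document
#' becomes a mention too (added only where the span is not already covered by
#' an existing mention). Never removes a mention.
#'
#' @param doc A preprocessed document.
#' @param mentions Mention data.frame from decoding.
#' @param pairs Abbreviation pairs from [extract_abbreviations()].
#' @return The augmented mention data.frame.
#' @export
propagate_abbreviations <- function(doc, mentions, pairs) {
  if (nrow(pairs) == 0L) return(mentions)
  toks <- do.call(rbind, doc$sentences)
  for (k in seq_len(nrow(pairs))) {
    hit <- any(mentions$doc_id == doc$doc_id &
                 mentions$start == pairs$long_start[k] &
                 mentions$end == pairs$long_end[k])
    if (!hit) next
    occ <- which(toks$text == pairs$short[k])
    for (ti in occ) {
      s <- toks$start[ti]; e <- toks$end[ti]
      covered <- any(mentions$doc_id == doc$doc_id &
                       mentions$start < e & mentions$end > s)
      if (!covered) {
        mentions <- rbind(mentions, data.frame(
          doc_id = doc$doc_id, start = s, end = e,
          text = toks$text[ti], type = "Disease", stringsAsFactors = FALSE))
      }
    }
  }
  mentions[order(mentions$start), , drop = FALSE]
}

#' Convert a repaired BIO sequence to mention spans
#'
#' Each maximal run `B I*` becomes one mention spanning from the first
#' token's start to the last token's end. The input must already be legal
#' (an `I` not preceded by `B`/`I` is a contract violation and errors).
#'
#' @param tokens Token data.frame with document-absolute offsets.
#' @param labels Character vector over `{"B","I","O"}`.
#' @param doc_id Document id for the produced mentions.
#' @param text Optional document text used to fill the mention `text` field.
#' @return Mention data.frame (`doc_id`, `start`, `end`, `text`, `type`).
#' @export
bio_to_mentions <- function(tokens, labels, doc_id = "doc", text = NULL) {
  stopifnot(nrow(tokens) == length(labels))
  out <- empty_mentions()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (labels[i] == "I") {
      stop("orphan 'I' at position ", i, ": repair labels before decoding")
    }
    if (labels[i] == "B") {
      j <- i
      while (j < n && labels[j + 1L] == "I") j <- j + 1L
      s <- tokens$start[i]; e <- tokens$end[j]
      mtext <- if (!is.null(text)) substr(text, s + 1L, e) else {
        paste(tokens$text[i:j], collapse = " ")
      }
      out <- rbind(out, data.frame(doc_id = doc_id, start = s, end = e,
                                   text = mtext, type = "Disease",
                                   stringsAsFactors = FALSE))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}
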