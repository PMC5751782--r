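# Text preprocessing: sentence splitting, offset-preserving tokenization and
# number normalization. Tokens are plain data.frames so downstream code can use
# vectorized operations; character offsets are 0-based half-open over the
# document text, so BIO labels round-trip to exact character spans.

# Delimiter characters that separate tokens and are retained as
# single-character tokens. Includes both the ASCII hyphen-minus and the
# typographic minus/en/em dashes seen in journal text.
DEFAULT_DELIMITERS <- c(
  "/", "−", "-", "–", "—", ">", "<", ";", ":", "?",
  "[", "]", "{", "}", "(", ")", "!", "@", "#", "$", "%", "^", "&", "*",
  "+", ",", "."
)

# Build a regex character class from single characters: "]" goes first,
# "-" last, "^" and "\\" are escaped, so no character forms a range.
regex_char_class <- function(chars) {
  chars <- unique(chars)
  body <- paste0(
    if ("]" %in% chars) "]" else "",
    paste(vapply(setdiff(chars, c("]", "-", "^", "\\")), identity,
                 character(1)), collapse = ""),
    if ("\\" %in% chars) "\\\\" else "",
    if ("^" %in% chars) "\\^" else "",
    if ("-" %in% chars) "-" else "")
  paste0("[", body, "]")
}

# Sentence-final tokens that do not end a sentence even before a capital.
DEFAULT_ABBREV_EXCEPTIONS <- c(
  "e.g.", "i.e.", "etc.", "vs.", "cf.", "Fig.", "Figs.", "Dr.", "Prof.",
  "St.", "no.", "No.", "al.", "approx."
)

#' Split text into sentence spans
#'
#' Rule-based splitting: a sentence ends at `.`, `?` or `!` followed by
#' whitespace and an upper-case letter, unless the word ending at the period is
#' in the abbreviation exception list. Spans are 0-based half-open character
#' offsets into `text`, ordered, non-overlapping, and together cover all
#' non-whitespace characters.
#'
#' @param text A single character string (may be empty).
#' @param abbreviations Character vector of abbreviations (ending in `.`) that
#'   never terminate a sentence.
#' @return A data.frame with integer columns `start` and `end` (one row per
#'   sentence); zero rows for empty or all-whitespace input.
#' @examples
#' split_sentences("A rare disorder. It is fatal.")
#' @export
split_sentences <- function(text, abbreviations = DEFAULT_ABBREV_EXCEPTIONS) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  # candidate boundaries: terminator at i, whitespace run, then capital
  boundary_after <- logical(n)      # TRUE: sentence ends after char i (1-based)
  m <- gregexpr("[.?!][ \t\r\n]+[A-Z]", text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    for (pos in as.integer(m)) {
      if (chars[pos] == ".") {
        # word ending at the period, e.g. "e.g." or "al."
        ws <- pos
        while (ws > 1L && !grepl("[ \t\r\n]", chars[ws - 1L])) ws <- ws - 1L
        word <- substr(text, ws, pos)
        if (word %in% abbreviations) next
        # single capital letter + "." (initials like "J.") never ends a sentence
        if (grepl("^[A-Z]\\.$", word)) next
      }
      boundary_after[pos] <- TRUE
    }
  }

  nonws <- which(!grepl("[ \t\r\n]", chars))
  starts <- integer(0); ends <- integer(0)
  cur_start <- NA_integer_
  for (i in nonws) {
    if (is.na(cur_start)) cur_start <- i
    last <- i
    if (boundary_after[i]) {
      starts <- c(starts, cur_start); ends <- c(ends, i)
      cur_start <- NA_integer_
    }
  }
  # trailing sentence without a detected boundary
  if (!is.na(cur_start)) {
    starts <- c(starts, cur_start); ends <- c(ends, nonws[length(nonws)])
  }
  data.frame(start = starts - 1L, end = ends)  # to 0-based half-open
}

#' Tokenize sentence text on whitespace and delimiter characters
#'
#' Splits on whitespace and on each character of the delimiter set; delimiter
#' characters are retained as single-character tokens so that punctuation
#' inside entity names (hyphens, parentheses) survives for exact-span
#' reconstruction. A period between two digits is treated as a decimal point
#' and does not split (so "81.6" stays one token).
#'
#' @param sentence_text The sentence string.
#' @param offset 0-based character offset of the sentence within its document;
#'   token offsets are document-absolute.
#' @param delimiters Character vector of single delimiter characters.
#' @return data.frame with columns `text`, `start`, `end` (0-based half-open),
#'   `norm` (initially equal to `text`).
#' @examples
#' tokenize("(mean age")$text   # "(" "mean" "age"
#' @export
tokenize <- function(sentence_text, offset = 0L,
                     delimiters = DEFAULT_DELIMITERS) {
  stopifnot(is.character(sentence_text), length(sentence_text) == 1L)
  empty <- data.frame(text = character(0), start = integer(0),
                      end = integer(0), norm = character(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(sentence_text)) return(empty)
  delim_class <- regex_char_class(delimiters)
  # decimals first, then maximal runs of non-delimiter non-space characters,
  # then single delimiter characters
  pat <- paste0("\\d+(?:\\.\\d+)+|(?:(?!", delim_class, ")\\S)+|", delim_class)
  m <- gregexpr(pat, sentence_text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  texts <- substring(sentence_text, starts, starts + lens - 1L)
  data.frame(text = texts,
             start = offset + starts - 1L,
             end = offset + starts + lens - 1L,
             norm = texts,
             stringsAsFactors = FALSE)
}

#' Rewrite numeric token norms to "num"
#'
#' A token whose full text is an optionally signed integer or decimal gets
#' `norm = "num"`; all other tokens keep `norm = text`. Text and offsets are
#' never altered, so spans still resolve against the document. Idempotent.
#'
#' @param tokens Token data.frame from [tokenize()].
#' @return The token data.frame with the `norm` column rewritten.
#' @export
normalize_numbers <- function(tokens) {
  if (nrow(tokens) == 0L) return(tokens)
  is_num <- grepl("^[+-]?\\d+(\\.\\d+)?$", tokens$text)
  tokens$norm <- ifelse(is_num, "num", tokens$text)
  tokens
}

# Lowercased, number-normalized surface used for word-level lookup and
# lexicon matching; character-level features use the original cased text.
token_key <- function(tokens) tolower(tokens$norm)

#' Sentence-split and tokenize a document
#'
#' Runs [split_sentences()], merges any sentences that a gold mention crosses
#' (so exact-span evaluation stays possible), then tokenizes each sentence and
#' applies [normalize_numbers()].
#'
#' @param doc A document list with elements `doc_id`, `text` and optionally a
#'   `mentions` data.frame (`start`, `end`, `text`, `type`).
#' @param delimiters,abbreviations Passed to the tokenizer / splitter.
#' @return The document with a `sentences` element: a list of token
#'   data.frames, each with attribute `span = c(start, end)`.
#' @export
preprocess_document <- function(doc, delimiters = DEFAULT_DELIMITERS,
                                abbreviations = DEFAULT_ABBREV_EXCEPTIONS) {
  spans <- split_sentences(doc$text, abbreviations)
  if (!is.null(doc$mentions) && nrow(doc$mentions) > 0L && nrow(spans) > 1L) {
    spans <- merge_spans_for_mentions(spans, doc$mentions)
  }
  doc$sentences <- lapply(seq_len(nrow(spans)), function(i) {
    s <- spans$start[i]; e <- spans$end[i]
    toks <- tokenize(substr(doc$text, s + 1L, e), offset = s,
                     delimiters = delimiters)
    toks <- normalize_numbers(toks)
    attr(toks, "span") <- c(s, e)
    attr(toks, "doc_id") <- doc$doc_id
    toks
  })
  doc
}

# Merge consecutive sentence spans crossed by a mention.
merge_spans_for_mentions <- function(spans, mentions) {
  repeat {
    merged <- FALSE
    for (k in seq_len(nrow(mentions))) {
      ms <- mentions$start[k]; me <- mentions$end[k]
      hit <- which(spans$start < me & spans$end > ms)
      if (length(hit) > 1L) {
        i <- min(hit); j <- max(hit)
        spans <- rbind(
          if (i > 1L) spans[seq_len(i - 1L), ] else NULL,
          data.frame(start = spans$start[i], end = spans$end[j]),
          if (j < nrow(spans)) spans[(j + 1L):nrow(spans), ] else NULL)
        merged <- TRUE
        break
      }
    }
    if (!merged) return(spans)
  }
}
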