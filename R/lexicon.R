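# Disease vocabulary loading and dictionary BIO tagging (the lexicon feature).
# Terms are normalized exactly like corpus text (same tokenizer, lowercase,
# numbers -> "num") so that matching happens in the token space the model sees.

normalize_term <- function(term, delimiters = DEFAULT_DELIMITERS) {
  toks <- normalize_numbers(tokenize(term, delimiters = delimiters))
  paste(tolower(toks$norm), collapse = " ")
}

#' Load a disease vocabulary
#'
#' Two formats: `"plain"` (one term per line) and `"medic"` (TSV with a name
#' column and a pipe-separated synonyms column; both primary names and all
#' synonyms are included). Every term is tokenized and normalized with the
#' same pipeline as corpus text.
#'
#' @param path Path to the vocabulary file.
#' @param format `"plain"` or `"medic"`.
#' @param name_col,synonyms_col Column indices for the MEDIC dialect
#'   (defaults: 1 and 8, the layout of the public MEDIC TSV release).
#' @return An object of class `mcnn_lexicon`: a list with `terms` (environment
#'   used as a hash set of normalized token sequences), `max_len` (longest term
#'   in tokens), `size`, `name`.
#' @export
load_lexicon <- function(path, format = c("plain", "medic"),
                         name_col = 1L, synonyms_col = 8L) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  raw <- character(0)
  if (format == "plain") {
    raw <- lines[nzchar(trimws(lines))]
  } else {
    for (line in lines) {
      if (!nzchar(trimws(line))) next
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      raw <- c(raw, parts[name_col])
      if (length(parts) >= synonyms_col && nzchar(parts[synonyms_col])) {
        raw <- c(raw, strsplit(parts[synonyms_col], "|", fixed = TRUE)[[1]])
      }
    }
  }
  lex <- build_lexicon(raw, name = basename(path))
  if (lex$size == 0L) warning("empty lexicon loaded from ", path, call. = FALSE)
  lex
}

#' Build a lexicon from a character vector of terms
#'
#' @param terms Character vector of disease names/synonyms.
#' @param name Label for printing.
#' @return An `mcnn_lexicon` object (see [load_lexicon()]).
#' @export
build_lexicon <- function(terms, name = "lexicon") {
  keys <- vapply(terms, normalize_term, character(1), USE.NAMES = FALSE)
  keys <- unique(keys[nzchar(keys)])
  env <- new.env(hash = TRUE, parent = emptyenv())
  max_len <- 0L
  for (k in keys) {
    assign(k, TRUE, envir = env)
    max_len <- max(max_len, length(strsplit(k, " ", fixed = TRUE)[[1]]))
  }
  structure(list(terms = env, max_len = max_len, size = length(keys),
                 name = name),
            class = "mcnn_lexicon")
}

#' @export
print.mcnn_lexicon <- function(x, ...) {
  cat(sprintf("<mcnn_lexicon '%s': %d unique normalized terms, longest %d tokens>\n",
              x$name, x$size, x$max_len))
  invisible(x)
}

#' Dictionary-match BIO tagging of a token sequence
#'
#' Greedy left-to-right longest-match over normalized tokens (lowercased,
#' numbers as "num"): each matched span is labelled `B I ... I`, everything
#' else `O`; matches cannot overlap. Tagging is identical at train and
#' predict time.
#'
#' @param tokens Token data.frame (from the preprocessing pipeline) or a
#'   `list(tokens, labels)` sentence.
#' @param lexicon An `mcnn_lexicon`.
#' @return Character vector of labels over `{"B","I","O"}`, one per token.
#' @examples
#' lex <- build_lexicon(c("colorectal cancer"))
#' dict_tag(normalize_numbers(tokenize("colorectal cancer risk")), lex)
#' @export
dict_tag <- function(tokens, lexicon) {
  if (!is.null(tokens$tokens)) tokens <- tokens$tokens
  n <- nrow(tokens)
  labels <- rep("O", n)
  if (n == 0L || lexicon$size == 0L) return(labels)
  key <- tolower(tokens$norm)
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (len in seq.int(min(lexicon$max_len, n - i + 1L), 1L)) {
      k <- paste(key[i:(i + len - 1L)], collapse = " ")
      if (exists(k, envir = lexicon$terms, inherits = FALSE)) {
        matched <- len
        break
      }
    }
    if (matched > 0L) {
      labels[i] <- "B"
      if (matched > 1L) labels[(i + 1L):(i + matched - 1L)] <- "I"
      i <- i + matched
    } else {
      i <- i + 1L
    }
  }
  labels
}
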