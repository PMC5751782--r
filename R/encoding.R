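# Vocabulary construction, word-vector loading, and conversion of labelled
# sentences into fixed-size window instances: each token yields one instance
# x (a window of word/char/lexicon features centred on it), a main label y
# (the centre token's BIO label) and an auxiliary label pair (previous and
# next tokens' labels) used by the multiple label strategy.

BIO_LABELS <- c("B", "I", "O")
PAD_ID <- 1L   # reserved id for padding in word/char tables
UNK_ID <- 2L   # reserved id for out-of-vocabulary items

label_id <- function(labels) {
  id <- match(labels, BIO_LABELS)
  if (anyNA(id)) stop("unknown BIO label: ",
                      paste(unique(labels[is.na(id)]), collapse = ", "))
  id
}

# Joint auxiliary class over (prev, next) in {B,I,O}^2: a bijection onto 1..9.
aux_joint_id <- function(prev_id, next_id) (prev_id - 1L) * 3L + next_id

#' Build word and character vocabularies from a training corpus
#'
#' Word entries are lowercased, number-normalized token norms; the character
#' set contains every unique character of the (cased) training token texts.
#' Both tables reserve id 1 for padding and id 2 for unknowns; ids follow
#' first appearance in corpus order, so the result is deterministic.
#'
#' @param sentences List of `list(tokens, labels)` sentences (labels optional).
#' @return An object of class `mcnn_vocab`: list with `words` and `chars`
#'   character vectors (id -> symbol).
#' @export
build_vocabs <- function(sentences) {
  if (length(sentences) == 0L) stop("empty corpus")
  texts <- unlist(lapply(sentences, function(s) {
    toks <- if (!is.null(s$tokens)) s$tokens else s
    toks$text
  }), use.names = FALSE)
  norms <- unlist(lapply(sentences, function(s) {
    toks <- if (!is.null(s$tokens)) s$tokens else s
    token_key(toks)
  }), use.names = FALSE)
  words <- c("<pad>", "<unk>", unique(norms))
  chars <- c("<pad>", "<unk>",
             unique(unlist(strsplit(texts, "", fixed = TRUE), use.names = FALSE)))
  structure(list(words = words, chars = chars), class = "mcnn_vocab")
}

#' @export
print.mcnn_vocab <- function(x, ...) {
  cat(sprintf("<mcnn_vocab: %d words, %d characters (+pad/unk)>\n",
              length(x$words) - 2L, length(x$chars) - 2L))
  invisible(x)
}

word_ids <- function(keys, vocab) {
  id <- match(keys, vocab$words)
  id[is.na(id)] <- UNK_ID
  id
}

char_ids <- function(text, vocab) {
  if (!nzchar(text)) return(rep(PAD_ID, 3L))
  id <- match(strsplit(text, "", fixed = TRUE)[[1]], vocab$chars)
  id[is.na(id)] <- UNK_ID
  # pad to the character-CNN minimum window
  if (length(id) < 3L) id <- c(id, rep(PAD_ID, 3L - length(id)))
  id
}

#' Load pre-trained word vectors for a vocabulary
#'
#' Reads the whitespace-delimited word-vector text format (an optional
#' `count dim` header line is detected and skipped). Rows for in-vocabulary
#' words are copied; all other rows (including padding and unknown) are
#' initialized uniformly in \[-0.05, 0.05\] under the given seed.
#'
#' @param path Path to the vector file, or `NULL` for a fully random table.
#' @param vocab An `mcnn_vocab`.
#' @param dim Expected vector dimension (default 200).
#' @param seed Seed for the random rows.
#' @return Numeric matrix `length(vocab$words) x dim`.
#' @export
load_word_vectors <- function(path, vocab, dim = 200L, seed = 1L) {
  tab <- with_seed(seed, matrix(stats::runif(length(vocab$words) * dim,
                                             -0.05, 0.05),
                                nrow = length(vocab$words)))
  if (is.null(path)) return(tab)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(tab)
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    hdr_dim <- as.integer(first[2])
    if (hdr_dim != dim) {
      stop(sprintf("word-vector dimension %d does not match configured %d",
                   hdr_dim, dim))
    }
    lines <- lines[-1]
  }
  for (line in lines) {
    if (!nzchar(trimws(line))) next
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) - 1L != dim) {
      stop(sprintf("word-vector dimension %d does not match configured %d",
                   length(parts) - 1L, dim))
    }
    idx <- match(parts[1], vocab$words)
    if (!is.na(idx)) tab[idx, ] <- as.numeric(parts[-1])
  }
  tab
}

#' Encode a labelled sentence as fixed-size window instances
#'
#' One instance per token: the window of `window` tokens centred on it (word
#' id, character-id sequence via a form table, and lexicon BIO feature),
#' the centre token's label `y`, and the auxiliary pair
#' (previous label, next label) with out-of-sentence neighbours counting
#' as `O`. Out-of-sentence window positions are filled with the padding word,
#' padding characters and lexicon label `O`.
#'
#' @param sent A `list(tokens, labels)` sentence (labels optional at predict
#'   time).
#' @param vocab An `mcnn_vocab`.
#' @param lexicon Optional `mcnn_lexicon` for the dictionary feature
#'   (`NULL` = feature all `O`).
#' @param window Odd window size (default 13).
#' @return List: `W`, `Fm`, `L` (n x window integer matrices of word ids,
#'   form ids, lexicon label ids), `forms` (list of char-id sequences, entry
#'   1 = padding form), `y`, `y_prev`, `y_next` (integer vectors, `NULL`
#'   without labels), `n` (token count).
#' @export
encode_windows <- function(sent, vocab, lexicon = NULL, window = 13L) {
  if (window %% 2L == 0L) stop("window size must be odd")
  encode_corpus(list(sent), vocab, lexicon = lexicon, window = window)
}

# Encode a list of sentences into one instance set sharing a form table.
encode_corpus <- function(sentences, vocab, lexicon = NULL, window = 13L) {
  if (window %% 2L == 0L) stop("window size must be odd")
  half <- (window - 1L) %/% 2L
  form_env <- new.env(hash = TRUE, parent = emptyenv())
  forms <- list(rep(PAD_ID, 3L))          # id 1: padding form
  form_id <- function(texts) {
    vapply(texts, function(tx) {
      if (!nzchar(tx)) return(1L)
      id <- form_env[[tx]]
      if (is.null(id)) {
        id <- length(forms) + 1L
        forms[[id]] <<- char_ids(tx, vocab)
        assign(tx, id, envir = form_env)
      }
      id
    }, integer(1), USE.NAMES = FALSE)
  }
  O_ID <- label_id("O")
  Ws <- list(); Fs <- list(); Ls <- list()
  ys <- list(); yps <- list(); yns <- list(); sids <- list()
  has_labels <- TRUE
  for (si in seq_along(sentences)) {
    s <- sentences[[si]]
    toks <- if (!is.null(s$tokens)) s$tokens else s
    n <- nrow(toks)
    if (n == 0L) next
    w_id <- word_ids(token_key(toks), vocab)
    f_id <- form_id(toks$text)
    l_id <- if (is.null(lexicon)) rep(O_ID, n) else label_id(dict_tag(toks, lexicon))
    # padded index: 0 means out-of-sentence
    idx <- outer(seq_len(n) - half - 1L, seq_len(window), `+`)
    oob <- idx < 1L | idx > n
    idx[oob] <- 1L
    take <- function(v, fill) {
      m <- matrix(v[idx], nrow = n)
      m[oob] <- fill
      m
    }
    Ws[[length(Ws) + 1L]] <- take(w_id, PAD_ID)
    Fs[[length(Fs) + 1L]] <- take(f_id, 1L)
    Ls[[length(Ls) + 1L]] <- take(l_id, O_ID)
    sids[[length(sids) + 1L]] <- rep(si, n)
    if (!is.null(s$labels)) {
      lab <- label_id(s$labels)
      ys[[length(ys) + 1L]] <- lab
      yps[[length(yps) + 1L]] <- c(O_ID, lab[-n])[seq_len(n)]
      yns[[length(yns) + 1L]] <- c(lab[-1L], O_ID)
    } else {
      has_labels <- FALSE
    }
  }
  list(W = do.call(rbind, Ws), Fm = do.call(rbind, Fs), L = do.call(rbind, Ls),
       forms = forms,
       y = if (has_labels && length(ys)) unlist(ys) else NULL,
       y_prev = if (has_labels && length(yps)) unlist(yps) else NULL,
       y_next = if (has_labels && length(yns)) unlist(yns) else NULL,
       sentence = unlist(sids),
       n = if (length(Ws)) sum(vapply(Ws, nrow, integer(1))) else 0L,
       window = window)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
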