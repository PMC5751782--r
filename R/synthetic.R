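# Seeded synthetic corpora with known gold mentions: pronounceable fake
# disease names from a syllable grammar, a distractor vocabulary drawn from a
# disjoint syllable set (so mention words are statistically distinct and the
# tagging task is learnable), partial lexicon coverage, parenthesized
# abbreviation definitions, and numeric noise tokens. Everything is
# PubTator-compatible so the full pipeline can be exercised offline.

DISEASE_SYLLABLES <- c("kar", "vel", "dro", "myx", "thal", "osp", "quil",
                       "zen", "fib", "lux", "orn", "gad", "pex", "wir",
                       "juv", "crom", "bly", "sarn", "tev", "ulk")
DISEASE_SUFFIXES <- c("osis", "itis", "oma", "pathy", "emia", "plasia")
DISTRACTOR_SYLLABLES <- c("ta", "mo", "ri", "su", "lan", "bet", "cor", "dil",
                          "fam", "gen", "hol", "ket", "lum", "nov", "pra",
                          "sto", "tur", "win", "yor", "ed", "ab", "if", "on")

#' Synthetic corpus configuration
#'
#' @param n_docs Number of documents.
#' @param sentences_per_doc Sentences per document (the first doubles as the
#'   title).
#' @param lexicon_size Number of distinct disease terms in the full term list.
#' @param mention_rate Probability that a sentence carries a disease mention.
#' @param mention_length_dist Probabilities of mention lengths 1-5 tokens.
#' @param lexicon_coverage Fraction of the term list included in the emitted
#'   lexicon (partial dictionary coverage).
#' @param abbrev_rate Probability that a multi-token mention is followed by a
#'   parenthesized abbreviation definition, reused later in the document.
#' @param number_rate Probability that a sentence contains numeric tokens.
#' @param vocab_size Size of the distractor vocabulary.
#' @param seed Mandatory integer seed.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_docs = 100L, sentences_per_doc = 10L,
                         lexicon_size = 120L, mention_rate = 0.7,
                         mention_length_dist = c(0.45, 0.3, 0.15, 0.07, 0.03),
                         lexicon_coverage = 0.7, abbrev_rate = 0.1,
                         number_rate = 0.3, vocab_size = 300L, seed) {
  if (missing(seed)) stop("synth_config requires an explicit seed")
  rates <- c(mention_rate, lexicon_coverage, abbrev_rate, number_rate)
  stopifnot(all(rates >= 0), all(rates <= 1),
            length(mention_length_dist) == 5L,
            abs(sum(mention_length_dist) - 1) < 1e-8,
            n_docs >= 1L, sentences_per_doc >= 1L, lexicon_size >= 1L)
  structure(list(n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 lexicon_size = as.integer(lexicon_size),
                 mention_rate = mention_rate,
                 mention_length_dist = mention_length_dist,
                 lexicon_coverage = lexicon_coverage,
                 abbrev_rate = abbrev_rate, number_rate = number_rate,
                 vocab_size = as.integer(vocab_size),
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_disease_word <- function() {
  w <- paste(sample(DISEASE_SYLLABLES, sample(2:3, 1L), replace = TRUE),
             collapse = "")
  if (stats::runif(1) < 0.35) w <- paste0(w, sample(DISEASE_SUFFIXES, 1L))
  if (stats::runif(1) < 0.1) {
    w <- paste0(w, "-", sample(DISEASE_SYLLABLES, 1L))  # exercise hyphens
  }
  w
}

synth_distractor_word <- function() {
  paste(sample(DISTRACTOR_SYLLABLES, sample(2:3, 1L), replace = TRUE),
        collapse = "")
}

#' Generate the synthetic disease vocabulary
#'
#' Multi-token fake disease names from a syllable grammar disjoint from the
#' distractor vocabulary. The emitted lexicon is a `lexicon_coverage`
#' subsample of the full term list, emulating partial dictionary coverage.
#'
#' @param cfg A [synth_config()].
#' @return `list(full, lexicon)`: the full term character vector and the
#'   emitted [mcnn_lexicon][build_lexicon()].
#' @export
gen_lexicon <- function(cfg) {
  with_seed(cfg$seed, {
    terms <- character(0)
    guard <- 0L
    while (length(terms) < cfg$lexicon_size && guard < cfg$lexicon_size * 50L) {
      len <- sample(1:5, 1L, prob = cfg$mention_length_dist)
      t <- paste(replicate(len, synth_disease_word()), collapse = " ")
      if (!(t %in% terms)) terms <- c(terms, t)
      guard <- guard + 1L
    }
    k <- round(cfg$lexicon_coverage * length(terms))
    emitted <- if (k == 0L) character(0) else sample(terms, k)
    list(full = terms,
         lexicon = build_lexicon(emitted, name = "synthetic"))
  })
}

# One synthetic sentence: returns list(chunks, mention_idx, abbrev) where
# mention_idx is a list of chunk-index ranges carrying gold mentions.
synth_sentence <- function(cfg, term_list, doc_abbrevs) {
  n_ctx <- sample(5:10, 1L)
  chunks <- replicate(n_ctx, synth_distractor_word())
  mention_ranges <- list()
  new_abbrev <- NULL
  if (stats::runif(1) < cfg$number_rate) {
    pos <- sample(2:length(chunks), 1L)
    num <- if (stats::runif(1) < 0.5) {
      as.character(sample(1:999, 1L))
    } else {
      sprintf("%d.%d", sample(1:99, 1L), sample(0:9, 1L))
    }
    chunks <- append(chunks, num, after = pos - 1L)
  }
  use_sf <- length(doc_abbrevs) > 0L && stats::runif(1) < 0.5
  if (stats::runif(1) < cfg$mention_rate) {
    pos <- sample(2:(length(chunks) + 1L), 1L)
    if (use_sf) {
      sf <- sample(names(doc_abbrevs), 1L)
      chunks <- append(chunks, sf, after = pos - 1L)
      mention_ranges[[1]] <- c(pos, pos)
    } else {
      term <- sample(term_list, 1L)
      words <- strsplit(term, " ", fixed = TRUE)[[1]]
      chunks <- append(chunks, words, after = pos - 1L)
      mention_ranges[[1]] <- c(pos, pos + length(words) - 1L)
      if (length(words) >= 2L && stats::runif(1) < cfg$abbrev_rate) {
        sf <- toupper(paste(substr(words, 1L, 1L), collapse = ""))
        sf_pos <- pos + length(words)
        chunks <- append(chunks, paste0("(", sf, ")"), after = sf_pos - 1L)
        mention_ranges[[2]] <- c(-sf_pos, -sf_pos)   # negative: inner span
        new_abbrev <- stats::setNames(term, sf)
      }
    }
  }
  list(chunks = chunks, mention_ranges = mention_ranges,
       new_abbrev = new_abbrev)
}

#' Generate a synthetic annotated corpus
#'
#' Builds documents of template sentences (distractor words, inserted disease
#' mentions with exact character-offset gold annotations, optional
#' parenthesized abbreviation definitions whose short forms are reused later
#' in the document as gold mentions, and numeric noise). Document text is
#' `title + " " + abstract`; mentions never cross sentence boundaries.
#'
#' @param cfg A [synth_config()].
#' @param term_list Full term list from [gen_lexicon()].
#' @param path Optional path: when given, the corpus is also written in
#'   PubTator format.
#' @return List of preprocessed documents.
#' @export
gen_corpus <- function(cfg, term_list, path = NULL) {
  docs <- with_seed(cfg$seed + 7L, {
    lapply(seq_len(cfg$n_docs), function(di) {
      doc_abbrevs <- character(0)
      sent_texts <- character(0)
      mentions <- empty_mentions()
      offset <- 0L
      for (si in seq_len(cfg$sentences_per_doc)) {
        s <- synth_sentence(cfg, term_list, doc_abbrevs)
        if (!is.null(s$new_abbrev)) doc_abbrevs <- c(doc_abbrevs, s$new_abbrev)
        chunks <- s$chunks
        substr(chunks[1], 1L, 1L) <- toupper(substr(chunks[1], 1L, 1L))
        starts <- offset + c(0L, cumsum(nchar(chunks) + 1L))[seq_along(chunks)]
        ends <- starts + nchar(chunks)
        text <- paste(chunks, collapse = " ")
        for (r in s$mention_ranges) {
          if (r[1] > 0L) {
            ms <- starts[r[1]]; me <- ends[r[2]]
          } else {                       # parenthesized short form: inner span
            ms <- starts[-r[1]] + 1L; me <- ends[-r[2]] - 1L
          }
          mentions <- rbind(mentions, data.frame(
            doc_id = sprintf("S%04d", di), start = ms, end = me,
            text = "", type = "Disease", stringsAsFactors = FALSE))
        }
        sent_texts <- c(sent_texts, paste0(text, "."))
        offset <- offset + nchar(text) + 2L    # "." plus joining space
      }
      full_text <- paste(sent_texts, collapse = " ")
      if (nrow(mentions) > 0L) {
        mentions$text <- substring(full_text, mentions$start + 1L,
                                   mentions$end)
      }
      list(doc_id = sprintf("S%04d", di),
           title = sent_texts[1],
           abstract = paste(sent_texts[-1], collapse = " "),
           text = full_text,
           mentions = mentions)
    })
  })
  docs <- lapply(docs, preprocess_document)
  if (!is.null(path)) write_pubtator(docs, path)
  docs
}
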