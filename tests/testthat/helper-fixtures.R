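# Shared fixtures and independent oracles, all built in code.

# A two-document PubTator fixture with known mention counts.
pubtator_fixture <- function(path = tempfile(fileext = ".pubtator")) {
  lines <- c(
    "1001|t|Colorectal cancer in families.",
    "1001|a|We studied colorectal cancer and breast cancer risk in 164 patients.",
    "1001\t0\t17\tColorectal cancer\tDisease\tD015179",
    "1001\t42\t59\tcolorectal cancer\tDisease\tD015179",
    "1001\t64\t77\tbreast cancer\tDisease\tD001943",
    "",
    "1002|t|A rare disorder.",
    "1002|a|Inflammatory bowel disease (IBD) is chronic. IBD affects many.",
    "1002\t17\t43\tInflammatory bowel disease\tDisease\tD015212",
    "1002\t45\t48\tIBD\tDisease\tD015212",
    "1002\t62\t65\tIBD\tDisease\tD015212",
    "")
  writeLines(lines, path)
  path
}

# Same fixture with a deliberate off-by-one annotation span.
pubtator_fixture_offbyone <- function(path = tempfile(fileext = ".pubtator")) {
  lines <- c(
    "2001|t|Colorectal cancer in families.",
    "2001|a|Nothing else here.",
    "2001\t1\t18\tColorectal cancer\tDisease",
    "")
  writeLines(lines, path)
  path
}

# Exhaustive dictionary-matching oracle: enumerate every candidate span whose
# normalized tokens form a lexicon term, then select spans
# leftmost-longest-first without overlaps. Independent of dict_tag's greedy
# scan (which never enumerates candidates).
dict_tag_oracle <- function(tokens, terms) {
  norm_term <- function(t) {
    tk <- normalize_numbers(tokenize(t))
    paste(tolower(tk$norm), collapse = " ")
  }
  keys <- unique(vapply(terms, norm_term, character(1)))
  keys <- keys[nzchar(keys)]
  key <- tolower(tokens$norm)
  n <- length(key)
  cand <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (paste(key[i:j], collapse = " ") %in% keys) {
        cand[[length(cand) + 1L]] <- c(i, j)
      }
    }
  }
  labels <- rep("O", n)
  used <- rep(FALSE, n)
  while (length(cand) > 0L) {
    starts <- vapply(cand, `[`, integer(1), 1L)
    lens <- vapply(cand, function(c) c[2] - c[1], integer(1))
    pick <- order(starts, -lens)[1]
    span <- cand[[pick]]
    if (!any(used[span[1]:span[2]])) {
      labels[span[1]] <- "B"
      if (span[2] > span[1]) labels[(span[1] + 1L):span[2]] <- "I"
      used[span[1]:span[2]] <- TRUE
    }
    cand[[pick]] <- NULL
  }
  labels
}

# Brute-force ill-legality scan on the collapsed label string.
illegal_oracle <- function(labels) {
  s <- paste(labels, collapse = "")
  grepl("^I", s) || grepl("OI", s, fixed = TRUE)
}

empty_fixture_mentions <- function() {
  data.frame(doc_id = character(0), start = integer(0), end = integer(0),
             text = character(0), type = character(0), stringsAsFactors = FALSE)
}

# Random BIO sequence generator.
random_bio <- function(n) sample(c("B", "I", "O"), n, replace = TRUE,
                                 prob = c(0.2, 0.2, 0.6))

# A tiny fast model configuration for unit tests (not the study defaults).
tiny_config <- function(...) {
  defaults <- list(window = 5L, word_dim = 8L, char_dim = 4L, lex_dim = 2L,
                   char_cnn_filters = 4L, conv_filters = 8L,
                   n_conv_layers = 1L, dropout = 0.2, lr = 0.3,
                   batch_size = 32L, epochs = 3L, seed = 1L)
  do.call(mcnn_config, utils::modifyList(defaults, list(...)))
}

# A small synthetic corpus shared by model-level tests.
small_synth <- function(n_docs = 15L, seed = 1L, ...) {
  cfg <- synth_config(n_docs = n_docs, sentences_per_doc = 6L,
                      lexicon_size = 40L, seed = seed, ...)
  gl <- gen_lexicon(cfg)
  docs <- gen_corpus(cfg, gl$full)
  list(cfg = cfg, lexicon = gl$lexicon, full_terms = gl$full, docs = docs,
       gold = do.call(rbind, lapply(docs, function(d) d$mentions)))
}
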