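# PubTator-style corpus reading/writing, projection of character-offset
# mentions onto tokens as BIO labels, and CoNLL-style TSV dumps.
#
# A document is a list(doc_id, title, abstract, text, mentions, sentences)
# where text = title + " " + abstract (the offset base used by the public
# NCBI Disease and BioCreative V CDR releases) and mentions is a data.frame
# with doc_id, start, end, text, type (0-based half-open char offsets).

empty_mentions <- function() {
  data.frame(doc_id = character(0), start = integer(0), end = integer(0),
             text = character(0), type = character(0), stringsAsFactors = FALSE)
}

#' Read a PubTator-style annotated corpus
#'
#' Parses blocks of `PMID|t|title`, `PMID|a|abstract` lines followed by
#' tab-separated annotation lines (`PMID  start  end  text  type[  concept]`),
#' with a blank line between documents. Offsets are interpreted over
#' `title + " " + abstract`. Annotations whose text does not match the span
#' produce a warning but are kept; malformed lines are an error naming the
#' line number.
#'
#' @param path Path to the PubTator file.
#' @param types Annotation types to retain (default `"Disease"`); `NULL`
#'   keeps every type.
#' @param preprocess If `TRUE` (default) each document is sentence-split and
#'   tokenized via [preprocess_document()].
#' @return A list of document lists.
#' @export
read_pubtator <- function(path, types = "Disease", preprocess = TRUE) {
  lines <- readLines(path, warn = FALSE)
  docs <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    cur$text <- paste(cur$title, cur$abstract, sep = " ")
    bad <- which(cur$mentions$text !=
                   substr(rep(cur$text, nrow(cur$mentions)),
                          cur$mentions$start + 1L, cur$mentions$end))
    if (length(bad) > 0L) {
      warning(sprintf(
        "document %s: %d annotation span(s) do not match the document text",
        cur$doc_id, length(bad)), call. = FALSE)
    }
    cur
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) {
      d <- flush(cur); if (!is.null(d)) docs[[length(docs) + 1L]] <- d
      cur <- NULL
      next
    }
    tm <- regmatches(line, regexec("^([^|\t]+)\\|([ta])\\|(.*)$", line))[[1]]
    if (length(tm) == 4L) {
      pmid <- tm[2]; field <- tm[3]; value <- tm[4]
      if (is.null(cur)) {
        cur <- list(doc_id = pmid, title = "", abstract = "",
                    mentions = empty_mentions())
      }
      if (field == "t") cur$title <- value else cur$abstract <- value
      next
    }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 5L && !is.null(cur) && parts[1] == cur$doc_id) {
      start <- suppressWarnings(as.integer(parts[2]))
      end <- suppressWarnings(as.integer(parts[3]))
      if (is.na(start) || is.na(end) || start >= end) {
        stop(sprintf("malformed annotation at line %d: %s", ln, line))
      }
      if (is.null(types) || parts[5] %in% types) {
        cur$mentions <- rbind(cur$mentions, data.frame(
          doc_id = parts[1], start = start, end = end,
          text = parts[4], type = parts[5], stringsAsFactors = FALSE))
      }
      next
    }
    if (length(parts) >= 4L && length(parts) < 5L) {
      # relation lines (PMID\tCID\t...) and similar are silently skipped
      next
    }
    stop(sprintf("malformed line %d: %s", ln, line))
  }
  d <- flush(cur); if (!is.null(d)) docs[[length(docs) + 1L]] <- d
  if (preprocess) docs <- lapply(docs, preprocess_document)
  docs
}

#' Write documents in PubTator format
#'
#' @param docs List of document lists (as from [read_pubtator()] or
#'   [gen_corpus()]).
#' @param path Output path.
#' @export
write_pubtator <- function(docs, path) {
  out <- character(0)
  for (d in docs) {
    out <- c(out, paste0(d$doc_id, "|t|", d$title),
             paste0(d$doc_id, "|a|", d$abstract))
    if (!is.null(d$mentions) && nrow(d$mentions) > 0L) {
      out <- c(out, sprintf("%s\t%d\t%d\t%s\t%s", d$doc_id,
                            d$mentions$start, d$mentions$end,
                            d$mentions$text, d$mentions$type))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Project gold mentions onto tokens as BIO labels
#'
#' A token overlapping a mention is labelled `I`, the first overlapping token
#' `B`, all others `O`. Overlapping gold mentions are resolved
#' leftmost-longest-first (the loser is dropped with a warning); a mention
#' boundary falling strictly inside a token clips to the whole token with a
#' warning.
#'
#' @param doc A preprocessed document (with `sentences`).
#' @return A list with one element per sentence: `list(tokens, labels)` where
#'   `labels` is a character vector over `{"B","I","O"}`.
#' @export
project_mentions_to_bio <- function(doc) {
  mentions <- doc$mentions
  if (is.null(mentions)) mentions <- empty_mentions()
  if (nrow(mentions) > 0L) {
    ord <- order(mentions$start, -(mentions$end - mentions$start))
    mentions <- mentions[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(mentions))
    last_end <- -1L
    for (k in seq_len(nrow(mentions))) {
      if (mentions$start[k] < last_end) {
        keep[k] <- FALSE
      } else {
        last_end <- mentions$end[k]
      }
    }
    if (any(!keep)) {
      warning(sprintf("document %s: dropped %d overlapping gold mention(s)",
                      doc$doc_id, sum(!keep)), call. = FALSE)
      mentions <- mentions[keep, , drop = FALSE]
    }
  }
  lapply(doc$sentences, function(toks) {
    labels <- rep("O", nrow(toks))
    if (nrow(mentions) > 0L && nrow(toks) > 0L) {
      for (k in seq_len(nrow(mentions))) {
        ms <- mentions$start[k]; me <- mentions$end[k]
        ov <- which(toks$start < me & toks$end > ms)
        if (length(ov) == 0L) next
        if (toks$start[ov[1]] < ms || toks$end[ov[length(ov)]] > me) {
          warning(sprintf(
            "document %s: mention [%d,%d) not aligned to token boundaries; clipped",
            doc$doc_id, ms, me), call. = FALSE)
        }
        labels[ov] <- "I"
        labels[ov[1]] <- "B"
      }
    }
    list(tokens = toks, labels = labels)
  })
}

#' Write labelled sentences as CoNLL-style TSV
#'
#' One `token<TAB>label` line per token, blank line between sentences.
#'
#' @param sentences List of `list(tokens, labels)` as produced by
#'   [project_mentions_to_bio()].
#' @param path Output path.
#' @export
write_conll <- function(sentences, path) {
  out <- character(0)
  first <- TRUE
  for (s in sentences) {
    if (!first) out <- c(out, "")
    first <- FALSE
    if (nrow(s$tokens) > 0L) {
      out <- c(out, paste(s$tokens$text, s$labels, sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read CoNLL-style TSV back into token/label lists
#'
#' Offsets are not recoverable from the TSV; tokens get placeholder spans.
#'
#' @param path Input path.
#' @return List of `list(tokens, labels)`.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sentences <- list()
  cur_tok <- character(0); cur_lab <- character(0)
  flush <- function() {
    if (length(cur_tok) == 0L) return(NULL)
    toks <- data.frame(text = cur_tok, start = NA_integer_, end = NA_integer_,
                       norm = cur_tok, stringsAsFactors = FALSE)
    list(tokens = normalize_numbers(toks), labels = cur_lab)
  }
  for (line in lines) {
    if (!nzchar(line)) {
      s <- flush(); if (!is.null(s)) sentences[[length(sentences) + 1L]] <- s
      cur_tok <- character(0); cur_lab <- character(0)
      next
    }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    cur_tok <- c(cur_tok, parts[1])
    cur_lab <- c(cur_lab, parts[2])
  }
  s <- flush(); if (!is.null(s)) sentences[[length(sentences) + 1L]] <- s
  sentences
}
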