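test_that("read_pubtator parses documents, offsets and annotation types", {
  docs <- read_pubtator(pubtator_fixture())
  expect_length(docs, 2L)
  expect_equal(docs[[1]]$doc_id, "1001")
  expect_equal(nrow(docs[[1]]$mentions), 3L)
  expect_equal(nrow(docs[[2]]$mentions), 3L)
  # offsets resolve over title + " " + abstract
  m <- docs[[1]]$mentions
  expect_equal(substring(docs[[1]]$text, m$start + 1L, m$end), m$text)
})

test_that("read_pubtator handles empty files and malformed/mismatched lines", {
  empty <- tempfile()
  writeLines(character(0), empty)
  expect_length(read_pubtator(empty), 0L)

  expect_warning(read_pubtator(pubtator_fixture_offbyone()),
                 "do not match")
  # the mismatched mention is kept
  docs <- suppressWarnings(read_pubtator(pubtator_fixture_offbyone()))
  expect_equal(nrow(docs[[1]]$mentions), 1L)

  bad <- tempfile()
  writeLines(c("3001|t|Title.", "3001|a|Abstract.",
               "3001\tnotanumber\t5\tx\tDisease", ""), bad)
  expect_error(read_pubtator(bad), "line 3")
})

test_that("BIO projection labels overlapping tokens with B I...I", {
  docs <- read_pubtator(pubtator_fixture())
  lab <- project_mentions_to_bio(docs[[1]])
  all_labels <- unlist(lapply(lab, `[[`, "labels"))
  expect_true(all(all_labels %in% c("B", "I", "O")))
  # sentence with no mention is all O
  has_b <- vapply(lab, function(s) any(s$labels == "B"), logical(1))
  expect_equal(sum(vapply(lab, function(s) sum(s$labels == "B"), integer(1))),
               3L)
  # no orphan I in projected gold
  for (s in lab) {
    expect_false(illegal_oracle(s$labels))
  }
})

test_that("two adjacent single-token mentions project as B B", {
  # brute-force per-character construction: two mentions sharing a boundary
  txt <- "Title. anemia cancer seen."
  doc <- list(doc_id = "d", text = txt,
              mentions = data.frame(
                doc_id = "d", start = c(7L, 14L), end = c(13L, 20L),
                text = c("anemia", "cancer"), type = "Disease"))
  expect_equal(substr(txt, 8, 13), "anemia")
  expect_equal(substr(txt, 15, 20), "cancer")
  doc <- preprocess_document(doc)
  lab <- project_mentions_to_bio(doc)
  labels <- unlist(lapply(lab, `[[`, "labels"))
  toks <- do.call(rbind, doc$sentences)
  expect_equal(labels[toks$text == "anemia"], "B")
  expect_equal(labels[toks$text == "cancer"], "B")
})

test_that("overlapping gold mentions resolve leftmost-longest with a warning", {
  txt <- "Title. colorectal cancer risk."
  doc <- list(doc_id = "d", text = txt,
              mentions = data.frame(
                doc_id = "d", start = c(7L, 18L), end = c(24L, 24L),
                text = c("colorectal cancer", "cancer"), type = "Disease"))
  doc <- preprocess_document(doc)
  expect_warning(lab <- project_mentions_to_bio(doc), "overlapping")
  labels <- unlist(lapply(lab, `[[`, "labels"))
  toks <- do.call(rbind, doc$sentences)
  expect_equal(labels[toks$text == "colorectal"], "B")
  expect_equal(labels[toks$text == "cancer"], "I")
})

test_that("CoNLL writing is lossless and separates sentences by blank lines", {
  docs <- read_pubtator(pubtator_fixture())
  lab <- c(project_mentions_to_bio(docs[[1]]),
           project_mentions_to_bio(docs[[2]]))
  path <- tempfile(fileext = ".conll")
  write_conll(lab, path)
  lines <- readLines(path)
  expect_equal(sum(!nzchar(lines)), length(lab) - 1L)  # internal separators
  back <- read_conll(path)
  expect_equal(lapply(back, `[[`, "labels"), lapply(lab, `[[`, "labels"))
  expect_equal(lapply(back, function(s) s$tokens$text),
               lapply(lab, function(s) s$tokens$text))

  write_conll(list(), path)
  expect_equal(readLines(path), character(0))
})

test_that("projection then decoding recovers token-aligned gold mentions", {
  docs <- read_pubtator(pubtator_fixture())
  for (d in docs) {
    lab <- project_mentions_to_bio(d)
    rec <- do.call(rbind, lapply(lab, function(s) {
      bio_to_mentions(s$tokens, s$labels, doc_id = d$doc_id, text = d$text)
    }))
    gold <- d$mentions[order(d$mentions$start), ]
    expect_equal(rec$start, gold$start)
    expect_equal(rec$end, gold$end)
    expect_equal(rec$text, gold$text)
  }
})
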