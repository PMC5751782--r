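test_that("repair_illegal fixes orphan I labels left-to-right", {
  r <- repair_illegal(c("O", "I", "O"))
  expect_equal(r$labels, c("O", "O", "O"))
  expect_equal(r$n_fixed, 1L)

  r <- repair_illegal(c("B", "I", "O"))
  expect_equal(r$labels, c("B", "I", "O"))
  expect_equal(r$n_fixed, 0L)

  # a leading I cascade collapses to O
  expect_equal(repair_illegal(c("I", "I", "B"))$labels, c("O", "O", "B"))

  expect_equal(repair_illegal(character(0))$n_fixed, 0L)
  expect_error(repair_illegal(c("B", "X")), "unknown label")
})

test_that("strict mode also repairs the B,B pattern", {
  expect_equal(repair_illegal(c("B", "B", "O"))$labels, c("B", "B", "O"))
  r <- repair_illegal(c("B", "B", "I"), strict_bb = TRUE)
  expect_equal(r$labels, c("B", "O", "O"))
  expect_equal(r$n_fixed, 2L)
})

test_that("repair_illegal is idempotent and eliminates every orphan I", {
  set.seed(99)
  for (i in 1:500) {
    labels <- random_bio(sample(1:12, 1L))
    r1 <- repair_illegal(labels)
    expect_false(illegal_oracle(r1$labels))
    r2 <- repair_illegal(r1$labels)
    expect_identical(r2$labels, r1$labels)
    expect_equal(r2$n_fixed, 0L)
    # strict mode is idempotent too
    s1 <- repair_illegal(labels, strict_bb = TRUE)
    s2 <- repair_illegal(s1$labels, strict_bb = TRUE)
    expect_identical(s2$labels, s1$labels)
  }
})

test_that("Schwartz-Hearst alignment finds textbook abbreviation pairs", {
  doc <- list(doc_id = "d",
              text = paste("Title here.",
                           "Patients with inflammatory bowel disease (IBD)",
                           "and standard deviation (SD) values (81.6) rose."),
              mentions = empty_fixture_mentions())
  doc <- preprocess_document(doc)
  pairs <- extract_abbreviations(doc)
  expect_true("IBD" %in% pairs$short)
  expect_equal(pairs$long[pairs$short == "IBD"], "inflammatory bowel disease")
  expect_true("SD" %in% pairs$short)
  expect_equal(pairs$long[pairs$short == "SD"], "standard deviation")
  # a parenthesized number is not a short form
  expect_false(any(grepl("81", pairs$short)))
  # offsets resolve
  expect_equal(substring(doc$text, pairs$long_start + 1L, pairs$long_end),
               pairs$long)
})

test_that("abbreviation propagation adds uncovered short-form occurrences", {
  txt <- paste("Title.",
               "Severe inflammatory bowel disease (IBD) is chronic.",
               "IBD recurs. Patients without IBD differ.")
  doc <- preprocess_document(list(doc_id = "d", text = txt,
                                  mentions = empty_fixture_mentions()))
  pairs <- extract_abbreviations(doc)
  lf_start <- pairs$long_start[pairs$short == "IBD"]
  lf_end <- pairs$long_end[pairs$short == "IBD"]
  recognized <- data.frame(doc_id = "d", start = lf_start, end = lf_end,
                           text = "inflammatory bowel disease",
                           type = "Disease", stringsAsFactors = FALSE)
  out <- propagate_abbreviations(doc, recognized, pairs)
  # 3 occurrences of IBD added, original mention kept
  expect_equal(nrow(out), 4L)
  expect_equal(sum(out$text == "IBD"), 3L)

  # already-covered occurrences are not duplicated
  out2 <- propagate_abbreviations(doc, out, pairs)
  expect_equal(nrow(out2), nrow(out))

  # unrecognized long form: no change
  none <- recognized[0, ]
  expect_equal(nrow(propagate_abbreviations(doc, none, pairs)), 0L)
})

test_that("bio_to_mentions converts runs and rejects orphan I", {
  toks <- normalize_numbers(tokenize("severe aplastic anemia seen"))
  m <- bio_to_mentions(toks, c("O", "B", "I", "O"), doc_id = "d",
                       text = "severe aplastic anemia seen")
  expect_equal(nrow(m), 1L)
  expect_equal(m$text, "aplastic anemia")
  expect_equal(c(m$start, m$end), c(7L, 22L))

  expect_equal(nrow(bio_to_mentions(toks[1:2, ], c("O", "O"))), 0L)
  # two adjacent B's are two single-token mentions
  m2 <- bio_to_mentions(toks[1:2, ], c("B", "B"))
  expect_equal(nrow(m2), 2L)
  expect_error(bio_to_mentions(toks[1:2, ], c("O", "I")), "orphan")
})
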