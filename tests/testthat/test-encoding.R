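sent_from_text <- function(txt, labels = NULL) {
  toks <- normalize_numbers(tokenize(txt))
  list(tokens = toks,
       labels = if (is.null(labels)) rep("O", nrow(toks)) else labels)
}

test_that("vocabulary building is deterministic with reserved ids", {
  s <- sent_from_text("a b a")
  v <- build_vocabs(list(s))
  expect_equal(v$words, c("<pad>", "<unk>", "a", "b"))
  expect_equal(v$words[1:2], c("<pad>", "<unk>"))
  # unseen word maps to the unknown id
  expect_equal(mcnn:::word_ids("zzz", v), mcnn:::UNK_ID)
  expect_error(build_vocabs(list()), "empty")

  # char vocab equals the set of unique characters plus reserved entries
  s2 <- sent_from_text("Abc d1-e")
  v2 <- build_vocabs(list(s2))
  expect_setequal(setdiff(v2$chars, c("<pad>", "<unk>")),
                  unique(strsplit("Abcd1-e", "")[[1]]))
})

test_that("word-vector loading copies known rows and errors on bad dims", {
  v <- build_vocabs(list(sent_from_text("alpha beta gamma delta")))
  p <- tempfile()
  writeLines(c("2 4",
               "alpha 1 2 3 4",
               "gamma 5 6 7 8"), p)
  tab <- load_word_vectors(p, v, dim = 4L, seed = 3L)
  expect_equal(dim(tab), c(length(v$words), 4L))
  expect_equal(tab[match("alpha", v$words), ], c(1, 2, 3, 4))
  expect_equal(tab[match("gamma", v$words), ], c(5, 6, 7, 8))
  # missing words random but bounded and reproducible
  miss <- tab[match("beta", v$words), ]
  expect_true(all(abs(miss) <= 0.05))
  expect_identical(tab, load_word_vectors(p, v, dim = 4L, seed = 3L))
  expect_false(identical(miss, load_word_vectors(p, v, 4L, seed = 4L)[
    match("beta", v$words), ]))

  expect_error(load_word_vectors(p, v, dim = 200L), "dimension")
  p2 <- tempfile()
  writeLines("alpha 1 2", p2)
  expect_error(load_word_vectors(p2, v, dim = 4L), "dimension")

  # absent file: fully random, reproducible
  expect_identical(load_word_vectors(NULL, v, 4L, seed = 5L),
                   load_word_vectors(NULL, v, 4L, seed = 5L))
})

test_that("window encoding yields one padded instance per token", {
  s <- sent_from_text("x", labels = "B")
  v <- build_vocabs(list(s))
  enc <- encode_windows(s, v, window = 13L)
  expect_equal(enc$n, 1L)
  expect_equal(sum(enc$W == mcnn:::PAD_ID), 12L)
  expect_equal(enc$y, mcnn:::label_id("B"))
  # out-of-sentence neighbours count as O
  expect_equal(enc$y_prev, mcnn:::label_id("O"))
  expect_equal(enc$y_next, mcnn:::label_id("O"))

  s3 <- sent_from_text("a b c", labels = c("B", "I", "O"))
  enc3 <- encode_windows(s3, build_vocabs(list(s3)), window = 5L)
  expect_equal(enc3$n, 3L)
  expect_equal(enc3$y, mcnn:::label_id(c("B", "I", "O")))
  expect_equal(enc3$y_prev, mcnn:::label_id(c("O", "B", "I")))
  expect_equal(enc3$y_next, mcnn:::label_id(c("I", "O", "O")))

  expect_error(encode_windows(s3, build_vocabs(list(s3)), window = 4L), "odd")

  # instance count equals token count on a longer fixture
  txt <- paste(rep("word", 40L), collapse = " ")
  s40 <- sent_from_text(txt)
  enc40 <- encode_windows(s40, build_vocabs(list(s40)))
  expect_equal(enc40$n, 40L)
})

test_that("window features ignore tokens beyond the window radius", {
  words <- letters[1:15]
  s_a <- sent_from_text(paste(words, collapse = " "))
  words_far <- words
  words_far[15] <- "zz"                 # beyond radius 2 of token 8
  s_b <- sent_from_text(paste(words_far, collapse = " "))
  v <- build_vocabs(list(s_a, s_b))
  ea <- encode_windows(s_a, v, window = 5L)
  eb <- encode_windows(s_b, v, window = 5L)
  centre <- 8L
  expect_equal(ea$W[centre, ], eb$W[centre, ])
  expect_equal(ea$L[centre, ], eb$L[centre, ])
})

test_that("the joint auxiliary encoding is a bijection on label pairs", {
  pairs <- expand.grid(prev = 1:3, nxt = 1:3)
  ids <- mcnn:::aux_joint_id(pairs$prev, pairs$nxt)
  expect_setequal(ids, 1:9)
  expect_equal(anyDuplicated(ids), 0L)
})
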