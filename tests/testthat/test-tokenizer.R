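test_that("pair counting and merge order follow corpus frequencies", {
  # ("a","b") occurs 4 times across the corpus, ("b","a") twice
  bp <- bpe_train(c("abab", "abab"), threshold = 1)
  expect_identical(bp$merges, list(c("a", "b")))

  expect_identical(bpe_train("abc", threshold = 0)$merges, list())

  # repeated self-merge; the second merge pair occurs only once, so it is
  # reachable only without the default frequency floor
  expect_identical(bpe_train("aaaa", threshold = 2, min_frequency = 1)$merges,
                   list(c("a", "a"), c("aa", "aa")))
  expect_identical(bpe_train("aaaa", threshold = 2)$merges,
                   list(c("a", "a")))

  expect_error(bpe_train(character(0), 1), "non-empty")
  expect_error(bpe_train(c("ab", ""), 1), "empty")
  expect_error(bpe_train("ab", -1), "non-negative")
})

test_that("frequency ties break to the byte-order smallest pair", {
  # "ba" and "ab" both occur twice; ("a","b") sorts first
  bp <- bpe_train(c("bab", "bab"), threshold = 1)
  expect_identical(bp$merges[[1L]], c("a", "b"))
})

test_that("segmentation reproduces the input and applies merges greedily", {
  empty <- bpe_train("CCO", threshold = 0)
  expect_identical(bpe_segment("CCO", empty)[[1L]], c("C", "C", "O"))

  bp <- bpe_train(c("abab", "abab"), threshold = 1)
  expect_identical(bpe_segment("abab", bp)[[1L]], c("ab", "ab"))

  # characters unseen in training pass through as single tokens
  expect_identical(bpe_segment("axb", bp)[[1L]], c("a", "x", "b"))
})

test_that("segment/join round-trips and token counts shrink with merges", {
  set.seed(11)
  alphabet <- c("C", "N", "O", "(", ")", "=", "1", "c", "l", "[", "]", "@")
  for (rep in 1:20) {
    corpus <- vapply(1:8, function(i) {
      paste(sample(alphabet, sample(5:30, 1L), replace = TRUE), collapse = "")
    }, "")
    bp <- bpe_train(corpus, threshold = 12)
    segs <- bpe_segment(corpus, bp)
    expect_identical(vapply(segs, paste, "", collapse = ""), corpus)
    # monotonicity: every merge prefix gives at least as many tokens
    probe <- corpus[1L]
    counts <- vapply(0:length(bp$merges), function(k) {
      prefix <- bp
      prefix$merges <- bp$merges[seq_len(k)]
      length(bpe_segment(probe, prefix)[[1L]])
    }, 0L)
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("training equals the naive reference merge by merge", {
  set.seed(23)
  for (rep in 1:25) {
    corpus <- vapply(seq_len(sample(2:6, 1L)), function(i) {
      paste(sample(letters[1:4], sample(4:20, 1L), replace = TRUE),
            collapse = "")
    }, "")
    t_max <- sample(1:8, 1L)
    expect_identical(bpe_train(corpus, t_max)$merges,
                     naive_bpe(corpus, t_max),
                     info = paste(corpus, collapse = " "))
  }
})

test_that("identical corpus and threshold give byte-identical vocabularies", {
  corpus <- c("CCOc1ccccc1", "CC(=O)NCC", "Clc1ccc(Cl)cc1")
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_bpe_vocab(bpe_vocabulary(bpe_train(corpus, 10)), f1)
  write_bpe_vocab(bpe_vocabulary(bpe_train(corpus, 10)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("vocabulary ids follow sorted alphabet then merge order", {
  v0 <- bpe_vocabulary(bpe_train("OC", threshold = 0))
  expect_identical(v0$token_to_id, c(C = 1L, O = 2L))

  bp <- bpe_train(c("abab", "abab"), threshold = 1)
  v <- bpe_vocabulary(bp)
  expect_identical(v$token_to_id, c(a = 1L, b = 2L, ab = 3L))
  expect_identical(v$pad_id, 0L)
  expect_identical(v$unk_id, 4L)
  # one new token per merge
  expect_identical(v$size, length(bp$alphabet) + length(bp$merges))
})

test_that("encoding pads with zeros, truncates right, maps unknowns", {
  v <- bpe_vocabulary(bpe_train("CCO", threshold = 0))
  enc <- bpe_encode(c("C", "O"), v, maxlen = 5)
  expect_identical(as.vector(enc), c(1L, 2L, 0L, 0L, 0L))
  expect_identical(attr(enc, "true_length"), 2L)

  expect_identical(as.vector(bpe_encode(character(0), v, maxlen = 3)),
                   c(0L, 0L, 0L))

  long <- bpe_encode(rep("C", 10), v, maxlen = 4)
  expect_identical(as.vector(long), rep(1L, 4L))

  unk <- bpe_encode(c("C", "Z"), v, maxlen = 3)
  expect_identical(as.vector(unk), c(1L, v$unk_id, 0L))
})

test_that("vocabulary JSON round-trips and replays identically", {
  corpus <- c("CCOc1ccccc1", "CC(=O)NCC", "Clc1ccc(Cl)cc1")
  v <- bpe_vocabulary(bpe_train(corpus, 8))
  f <- tempfile(fileext = ".json")
  write_bpe_vocab(v, f)
  v2 <- read_bpe_vocab(f)
  expect_identical(v2$token_to_id, v$token_to_id)
  expect_identical(v2$merges, v$merges)
  expect_identical(bpe_segment(corpus, v2), bpe_segment(corpus, v))
})

test_that("corpus reader handles plain text and FASTA", {
  txt <- tempfile(); writeLines(c("CCO", "", "CCN "), txt)
  expect_identical(read_corpus(txt), c("CCO", "CCN"))

  fa <- tempfile()
  writeLines(c(">sp|P1|first", "MKKFF", "DSRRE", ">P2", "MALW"), fa)
  expect_identical(read_corpus(fa), c("MKKFFDSRRE", "MALW"))
  expect_identical(read_corpus(fa, format = "fasta"),
                   c("MKKFFDSRRE", "MALW"))
  expect_error(read_corpus(tempfile()), "no such corpus")
})
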