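test_that("vocabulary respects min_count and vectors have the configured size", {
  corpus <- list(make_seq(c("fever", "cough", "fever", "tongue_red")),
                 make_seq(c("cough", "fever", "night_sweats")))
  m <- train_embeddings(corpus, embed_config(min_count = 2L, vector_size = 12L,
                                             epochs = 2L, seed = 1L))
  expect_setequal(m$vocab, c("fever", "cough"))       # singletons excluded
  expect_false("tongue_red" %in% m$vocab)
  expect_equal(ncol(m$vectors), 12L)
  expect_true(all(is.finite(m$vectors)))
  expect_error(train_embeddings(list(), embed_config()), "empty corpus")
})

test_that("training is reproducible for a fixed seed", {
  ch <- small_cohort(seed = 5L, n = 10L)
  corpus <- lapply(ch$records, extract_tokens)
  cfg <- embed_config(vector_size = 8L, epochs = 2L, seed = 99L)
  m1 <- train_embeddings(corpus, cfg)
  m2 <- train_embeddings(corpus, cfg)
  expect_identical(m1$vocab, m2$vocab)
  expect_identical(m1$vectors, m2$vectors)
})

test_that("co-occurring tokens end up closer than unrelated ones", {
  # two 'syndromes' of tokens that only ever appear together
  set.seed(8)
  mk <- function(pool) make_seq(sample(pool, 6, replace = TRUE))
  corpus <- c(replicate(40, mk(c("a1", "a2", "a3")), simplify = FALSE),
              replicate(40, mk(c("b1", "b2", "b3")), simplify = FALSE))
  m <- train_embeddings(corpus, embed_config(vector_size = 8L, epochs = 10L,
                                             seed = 2L))
  cossim <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  within <- cossim(m$vectors["a1", ], m$vectors["a2", ])
  across <- cossim(m$vectors["a1", ], m$vectors["b2", ])
  expect_gt(within, across)
})

test_that("vectorize pads, clips oldest-first, and masks out-of-vocabulary", {
  vocab <- sprintf("t%03d", 1:900)
  m <- fake_embedding(vocab, d = 6L)

  # padding
  s <- make_seq(vocab[1:10])
  em <- vectorize(s, m, 759L)
  expect_equal(dim(em$values), c(759L, 6L))
  expect_equal(em$mask, c(rep(TRUE, 10), rep(FALSE, 749)))
  expect_true(all(em$values[11:759, ] == 0))

  # clipping: 800 tokens, cap 759 -> 41 oldest dropped
  s8 <- make_seq(vocab[1:800], t_hours = 1:800)
  em8 <- vectorize(s8, m, 759L)
  expect_equal(sum(em8$mask), 759L)
  expect_equal(em8$values[1, ], m$vectors["t042", ])  # oldest kept token
  expect_equal(em8$values[759, ], m$vectors["t800", ])

  # boundary: exactly the cap
  s7 <- make_seq(vocab[1:759])
  em7 <- vectorize(s7, m, 759L)
  expect_true(all(em7$mask))
  expect_equal(em7$values, m$vectors[vocab[1:759], ], ignore_attr = TRUE)

  # OOV -> zero row, mask FALSE, position preserved
  so <- make_seq(c("t001", "UNSEEN", "t002"))
  emo <- vectorize(so, m, 5L)
  expect_equal(emo$mask, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_true(all(emo$values[2, ] == 0))
})

test_that("clipping matches the sort-by-time drop-earliest oracle", {
  vocab <- sprintf("t%03d", 1:200)
  m <- fake_embedding(vocab, d = 4L)
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:120, 1); cap <- sample(3:60, 1)
    tt <- round(runif(n, 0, 100), 2)
    toks <- sample(vocab, n, replace = TRUE)
    s <- make_seq(toks, t_hours = tt)
    em <- vectorize(s, m, cap)
    # oracle: stable sort by timestamp, drop the earliest n - cap
    ord <- order(tt)
    keep <- if (n > cap) sort(ord[(n - cap + 1):n]) else seq_len(n)
    expect_equal(dim(em$values), c(cap, 4L))
    expect_equal(em$mask[seq_along(keep)], rep(TRUE, length(keep)))
    expect_equal(em$values[seq_along(keep), , drop = FALSE],
                 m$vectors[toks[keep], , drop = FALSE], ignore_attr = TRUE)
  }
})

test_that("word2vec text format round-trips", {
  ch <- small_cohort(seed = 15L, n = 8L)
  m <- train_embeddings(lapply(ch$records, extract_tokens),
                        embed_config(vector_size = 6L, epochs = 2L, seed = 4L))
  tf <- withr::local_tempfile(fileext = ".txt")
  write_word2vec(m, tf)
  m2 <- read_word2vec(tf)
  expect_identical(m2$vocab, m$vocab)
  expect_equal(m2$vectors, m$vectors, tolerance = 1e-6)
  s <- extract_tokens(ch$records[[1]], 24)
  expect_equal(vectorize(s, m2, 32L)$mask, vectorize(s, m, 32L)$mask)
})
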