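test_that("match counts roll up before comparing", {
  onto <- tiny_ontology()
  # different herbs under one parent category count as a hit
  mc <- match_counts(onto, predicted = "a", reference = "b")
  expect_equal(unclass(mc), c(tp = 1L, fp = 0L, fn = 0L))
  # nothing predicted: all reference categories are misses
  mc2 <- match_counts(onto, character(), c("a", "c", "west"))
  expect_equal(unclass(mc2), c(tp = 0L, fp = 0L, fn = 3L))
  # identical sets: tp equals the rolled-up size
  mc3 <- match_counts(onto, c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(unclass(mc3), c(tp = 2L, fp = 0L, fn = 0L))
  expect_error(match_counts(onto, "nope", "a"), "unknown drug id")
})

test_that("precision and recall follow the defining ratios and conventions", {
  expect_equal(precision_recall(c(tp = 3, fp = 1, fn = 2)),
               c(precision = 0.75, recall = 0.6))
  expect_equal(precision_recall(c(tp = 0, fp = 0, fn = 0)),
               c(precision = 1, recall = 1))
  expect_equal(precision_recall(c(tp = 6, fp = 0, fn = 6)),
               c(precision = 1, recall = 0.5))
})

test_that("match_counts equals a brute-force set oracle on random instances", {
  set.seed(77)
  for (i in 1:1000) {
    onto <- random_ontology(n_cat = sample(2:5, 1), leaves_per = sample(1:4, 1))
    pool <- onto$nodes$id
    pred <- sample(pool, sample(0:6, 1), replace = TRUE)
    ref <- sample(pool, sample(0:6, 1), replace = TRUE)
    mc <- match_counts(onto, pred, ref)
    # oracle: explicit double loop over rolled-up label sets
    rp <- unique(vapply(pred, function(id) first_category(onto, id), character(1)))
    rr <- unique(vapply(ref, function(id) first_category(onto, id), character(1)))
    tp <- 0L
    for (a in rp) for (b in rr) if (a == b) tp <- tp + 1L
    fp <- 0L
    for (a in rp) if (!any(rr == a)) fp <- fp + 1L
    fn <- 0L
    for (b in rr) if (!any(rp == b)) fn <- fn + 1L
    expect_identical(unclass(mc), c(tp = tp, fp = fp, fn = fn))
    # precision/recall from the oracle counts agree too
    pr <- precision_recall(mc)
    expect_equal(pr[["precision"]], if (tp + fp == 0) 1 else tp / (tp + fp))
    expect_equal(pr[["recall"]], if (tp + fn == 0) 1 else tp / (tp + fn))
  }
})

test_that("swapping predicted and reference exchanges fp and fn", {
  set.seed(5)
  onto <- random_ontology(4, 3)
  for (i in 1:50) {
    pred <- sample(onto$nodes$id, sample(0:5, 1))
    ref <- sample(onto$nodes$id, sample(0:5, 1))
    a <- match_counts(onto, pred, ref)
    b <- match_counts(onto, ref, pred)
    expect_equal(a[["tp"]], b[["tp"]])
    expect_equal(a[["fp"]], b[["fn"]])
    expect_equal(a[["fn"]], b[["fp"]])
  }
})

test_that("timeline evaluation scores an oracle predictor perfectly", {
  ch <- small_cohort(seed = 30L, n = 12L)
  emb <- train_embeddings(lapply(ch$records, extract_tokens),
                          embed_config(vector_size = 8L, epochs = 2L, seed = 1L))
  ids <- category_ids(ch$onto)
  # hand-built "model" whose forward pass is replaced via its params:
  # instead, check the aggregation path using match_counts directly and
  # compare against evaluate_timeline on a trivially trained memorizer.
  # Here: a perfect predictor is emulated by feeding reference rollups in.
  counts <- c(tp = 0L, fp = 0L, fn = 0L)
  for (r in ch$records) for (o in r$orders) {
    mc <- match_counts(ch$onto, o$drug_ids, o$drug_ids)
    counts <- counts + mc
  }
  pr <- precision_recall(counts)
  expect_equal(unname(pr), c(1, 1))
  # an empty predictor has precision 1 by convention and recall 0
  counts0 <- c(tp = 0L, fp = 0L, fn = 0L)
  for (r in ch$records) for (o in r$orders) {
    counts0 <- counts0 + match_counts(ch$onto, character(), o$drug_ids)
  }
  pr0 <- precision_recall(counts0)
  expect_equal(pr0[["precision"]], 1)
  expect_equal(pr0[["recall"]], 0)
})

test_that("evaluate_timeline skips cells without a reference order", {
  ch <- small_cohort(seed = 31L, n = 6L)
  emb <- train_embeddings(lapply(ch$records, extract_tokens),
                          embed_config(vector_size = 8L, epochs = 2L, seed = 1L))
  ts <- make_training_set(ch$records, ch$onto, emb, 32L, cutoffs = 0)
  cfg <- desk_transformer_config(n_labels = ch$onto$n_category1,
                                 model_dim = 8L, ffn_dim = 16L,
                                 hidden_dim = 8L, max_num_tokens = 32L,
                                 multi_heads = 2L, head_dim = 4L)
  fit <- fit_transformer(ts$x, ts$y, cfg,
                         train_config(batch_size = 4L, epochs = 1L, seed = 1L))
  # cutoff 300 h is beyond every order time
  ev <- evaluate_timeline(fit, ch$records, ch$onto, emb, cutoffs = c(0, 300))
  expect_equal(ev$n_skipped, c(0L, 6L))
  expect_equal(ev$n, c(6L, 0L))
})
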