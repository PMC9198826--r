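cfg_small <- function(...) {
  desk_transformer_config(n_labels = 5L, model_dim = 8L, ffn_dim = 16L,
                          hidden_dim = 8L, max_num_tokens = 12L,
                          multi_heads = 2L, head_dim = 4L, ...)
}

fit_tiny <- function(x, y, cfg, epochs = 5L, seed = 1L, ...) {
  fit_transformer(x, y, cfg,
                  train_config(batch_size = 4L, epochs = epochs,
                               seed = seed, ...))
}

test_that("forward pass yields probabilities in (0,1), even on empty input", {
  cfg <- cfg_small()
  p <- local_seed(3, tcmrx:::init_transformer_params(cfg))
  em <- random_embedding_matrix(k = 12L, d = 8L, n_valid = 7L, seed = 1)
  out <- tcmrx:::transformer_fwd(p, cfg, em)$probs
  expect_length(out, 5L)
  expect_true(all(out > 0 & out < 1))
  # all-padding input still yields a valid probability vector
  em0 <- random_embedding_matrix(k = 12L, d = 8L, n_valid = 0L)
  out0 <- tcmrx:::transformer_fwd(p, cfg, em0)$probs
  expect_true(all(is.finite(out0)))
  expect_true(all(out0 > 0 & out0 < 1))
  # inference is deterministic
  expect_identical(out, tcmrx:::transformer_fwd(p, cfg, em)$probs)
  # shape mismatch errors
  bad <- random_embedding_matrix(k = 12L, d = 9L, n_valid = 3L)
  expect_error(tcmrx:::transformer_fwd(p, cfg, bad), "model_dim")
})

test_that("padded row content never changes the output", {
  cfg <- cfg_small()
  p <- local_seed(4, tcmrx:::init_transformer_params(cfg))
  set.seed(9)
  for (i in 1:10) {
    em <- random_embedding_matrix(k = 12L, d = 8L, n_valid = sample(1:11, 1))
    out1 <- tcmrx:::transformer_fwd(p, cfg, em)$probs
    em2 <- em
    em2$values[!em2$mask, ] <- matrix(rnorm(sum(!em2$mask) * 8, 0, 10),
                                      ncol = 8)
    out2 <- tcmrx:::transformer_fwd(p, cfg, em2)$probs
    expect_identical(out1, out2)
  }
})

test_that("decode thresholds correctly, monotonically, and symmetrically", {
  expect_equal(decode(c(0.9, 0.2, 0.6), 0.5), c(1L, 3L))
  expect_equal(decode(c(0.3, 0.4), 1 - 1e-9), integer())
  expect_error(decode(c(0.5), 1.5), "threshold")
  # shrinking the threshold can only grow the decoded set
  set.seed(21)
  for (i in 1:200) {
    p <- runif(8)
    t1 <- runif(1, 0.05, 0.95); t2 <- runif(1, 0.05, 0.95)
    lo <- min(t1, t2); hi <- max(t1, t2)
    expect_true(all(decode(p, hi) %in% decode(p, lo)))
    # permutation symmetry
    perm <- sample(8)
    expect_equal(sort(perm[decode(p[perm], lo)]), decode(p, lo))
  }
})

test_that("training memorizes a single sample and regularization shrinks weights", {
  cfg <- cfg_small(input_dropout = 0, hidden_dropout = 0)
  em <- random_embedding_matrix(k = 12L, d = 8L, n_valid = 9L, seed = 5)
  y <- matrix(c(1, 0, 1, 0, 0), 1)
  fit <- fit_tiny(list(em), y, cfg, epochs = 60L, learning_rate = 3e-3)
  # loss decreases on average and the sample is reproduced
  n <- nrow(fit$trace)
  expect_lt(mean(fit$trace$loss[(n - 9):n]), mean(fit$trace$loss[1:10]))
  expect_equal(unname(predict(fit, em)[1, ] >= 0.5), c(TRUE, FALSE, TRUE, FALSE, FALSE))

  # larger l2 penalty -> smaller weight norm on the same data
  xs <- lapply(1:6, function(i) random_embedding_matrix(12L, 8L, 6L, seed = i))
  ys <- matrix(rbinom(30, 1, 0.4), 6, 5)
  norm_of <- function(l2) {
    f <- fit_transformer(xs, ys, cfg,
                         train_config(batch_size = 3L, epochs = 15L, seed = 2L,
                                      l2_rate = l2))
    sqrt(sum(vapply(coef(f)[tcmrx:::wd_names(coef(f))],
                    function(w) sum(w^2), numeric(1))))
  }
  expect_lt(norm_of(0.01), norm_of(0))
})

test_that("training is deterministic given a seed and aborts on divergence", {
  cfg <- cfg_small()
  xs <- lapply(1:5, function(i) random_embedding_matrix(12L, 8L, 6L, seed = i))
  ys <- matrix(rbinom(25, 1, 0.4), 5, 5)
  f1 <- fit_tiny(xs, ys, cfg, epochs = 3L, seed = 7L)
  f2 <- fit_tiny(xs, ys, cfg, epochs = 3L, seed = 7L)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$trace, f2$trace)
})

test_that("predict returns labelled probabilities and decoded label ids", {
  cfg <- cfg_small()
  xs <- lapply(1:4, function(i) random_embedding_matrix(12L, 8L, 6L, seed = i))
  ys <- matrix(rbinom(20, 1, 0.4), 4, 5,
               dimnames = list(NULL, paste0("cat1_", 1:5)))
  fit <- fit_tiny(xs, ys, cfg, epochs = 2L)
  pr <- predict(fit, xs)
  expect_equal(dim(pr), c(4L, 5L))
  expect_equal(colnames(pr), paste0("cat1_", 1:5))
  labs <- predict(fit, xs[[1]], type = "labels", threshold = 0.3)
  expect_type(labs, "list")
  expect_true(all(labs[[1]] %in% paste0("cat1_", 1:5)))
})

test_that("grid search honours single points, ranges, and fold averaging", {
  cfg <- cfg_small()
  xs <- lapply(1:12, function(i) random_embedding_matrix(12L, 8L, 6L, seed = i))
  ys <- matrix(rbinom(60, 1, 0.4), 12, 5)
  tcfg <- train_config(batch_size = 4L, epochs = 1L, seed = 3L, cv_folds = 3L)

  # single-point grid returns that point
  out <- tune_transformer(xs, ys, list(multi_heads = 2L), cfg, tcfg)
  expect_equal(out$config$multi_heads, 2L)
  expect_equal(nrow(out$winners), 3L)

  # searched value stays inside the candidate range
  out2 <- tune_transformer(xs, ys,
                           list(learning_rate = c(1e-3, 3e-3)), cfg, tcfg)
  expect_gte(out2$train_config$learning_rate, 1e-3)
  expect_lte(out2$train_config$learning_rate, 3e-3)
  # averaging identical fold winners returns the winner unchanged
  expect_true(out2$train_config$learning_rate %in% c(1e-3, 3e-3) ||
                nrow(unique(out2$winners["learning_rate"])) > 1)

  expect_error(tune_transformer(xs, ys, list(), cfg, tcfg), "non-empty")
  expect_error(tune_transformer(xs, ys, list(bogus = 1), cfg, tcfg), "unknown")
})
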