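toy_embeddings <- function(n, k = 8L, d = 4L, mu = 0.5, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    structure(list(values = matrix(rnorm(k * d, mu, 1), k, d),
                   mask = rep(TRUE, k), t_hours = seq_len(k)),
              class = "embedding_matrix"))
}

toy_gan_config <- function(...) {
  desk_gan_config(lstm_size = 8L, resnorm_width = 8L, fc_width = 16L,
                  batch_size = 16L, max_epochs = 3L, ...)
}

test_that("generator preserves shape, mask, and zero padding", {
  xs <- toy_embeddings(20, seed = 2)
  gan <- fit_gan(xs, toy_gan_config(max_epochs = 1L, seed = 1L))
  x <- random_embedding_matrix(k = 8L, d = 4L, n_valid = 5L, seed = 3)
  g <- gan_generate(gan, x, noise_seed = 1L)
  expect_s3_class(g, "embedding_matrix")
  expect_equal(dim(g$values), dim(x$values))
  expect_identical(g$mask, x$mask)
  expect_true(all(g$values[!g$mask, ] == 0))
  # different noise seeds give distinct outputs
  g2 <- gan_generate(gan, x, noise_seed = 2L)
  expect_false(identical(g$values, g2$values))
})

test_that("a fresh generator with zero noise is the identity", {
  cfg <- toy_gan_config(noise_sd = 0, seed = 5L)
  pg <- local_seed(5, tcmrx:::init_generator(cfg, 4L))
  gan <- structure(list(params_g = pg, params_d = NULL, config = cfg,
                        dims = c(8L, 4L)), class = "tcm_gan")
  x <- random_embedding_matrix(k = 8L, d = 4L, n_valid = 6L, seed = 7)
  g <- gan_generate(gan, x, noise_seed = 1L)
  expect_equal(g$values, x$values, tolerance = 1e-12)
})

test_that("discriminator outputs a probability and is deterministic", {
  xs <- toy_embeddings(20, seed = 4)
  gan <- fit_gan(xs, toy_gan_config(max_epochs = 1L, seed = 2L))
  p1 <- discriminate(gan, xs[1:5])
  expect_length(p1, 5L)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, discriminate(gan, xs[1:5]))
  expect_identical(p1, predict(gan, xs[1:5]))
})

test_that("an untrained discriminator sits near chance on a balanced batch", {
  cfg <- toy_gan_config(seed = 9L)
  pd <- local_seed(9, tcmrx:::init_discriminator(cfg, 4L))
  gan <- structure(list(params_g = local_seed(9, tcmrx:::init_generator(cfg, 4L)),
                        params_d = pd, config = cfg, dims = c(8L, 4L)),
                   class = "tcm_gan")
  xs <- toy_embeddings(100, seed = 10)
  p <- discriminate(gan, xs)
  # raw sigmoid outputs of a random net cluster near 0.5
  expect_gt(mean(p), 0.2); expect_lt(mean(p), 0.8)
})

test_that("training history records alternating balanced phases", {
  xs <- toy_embeddings(40, seed = 6)
  cfg <- toy_gan_config(max_epochs = 2L, seed = 3L)
  gan <- fit_gan(xs, cfg)
  h <- gan$history
  expect_true(all(c("D", "G", "epoch") %in% h$phase))
  # each epoch contains a D segment then a G segment
  for (ep in unique(h$epoch)) {
    ph <- h$phase[h$epoch == ep]
    expect_equal(ph[1], "D")
    expect_true("G" %in% ph)
    expect_equal(ph[length(ph)], "epoch")
  }
  # losses are finite where recorded
  expect_true(all(is.finite(h$loss[h$phase %in% c("D", "G")])))
})

test_that("augmentation doubles the set, inherits labels, and keeps originals intact", {
  xs <- toy_embeddings(25, seed = 11)
  gan <- fit_gan(xs, toy_gan_config(max_epochs = 1L, seed = 4L))
  y <- matrix(rbinom(25 * 3, 1, 0.4), 25, 3)
  aug <- augment_dataset(xs, y, gan, seed = 8L)
  expect_length(aug$x, 50L)
  expect_equal(sum(aug$origin == "generated"), 25L)
  expect_identical(aug$x[1:25], xs)                    # originals bit-identical
  expect_identical(aug$y[1:25, ], aug$y[26:50, ])      # labels inherited
  expect_identical(aug$y[1:25, ], y)
  # generated differ from their sources
  expect_false(identical(aug$x[[26]]$values, xs[[1]]$values))
  # empty input
  aug0 <- augment_dataset(list(), y[0, , drop = FALSE], gan)
  expect_length(aug0$x, 0L)
})
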