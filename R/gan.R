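# LSTM-based generative adversarial augmenter.
#
# The generator receives an original training embedding with i.i.d.
# Gaussian noise injected into its token rows and produces a noise-added
# sample of identical shape; the discriminator scores whether a sample is
# original or generated. Generator: input projection -> two stacked LSTM
# layers, each followed by layer normalisation with a residual connection
# -> projection back to the embedding width, with a global residual from
# the (noised) input so that a freshly initialised generator reproduces
# its input exactly. Discriminator: input projection -> LSTM -> masked
# mean pooling -> residual + normalisation -> fully connected layer ->
# sigmoid scalar. Training alternates discriminator and generator phases
# until the discriminator's balanced accuracy settles around chance.
#
# LSTMs are batched: the time loop runs once per timestep over the whole
# minibatch. Padded rows are zeroed on entry, excluded from pooling, and
# zeroed on generator output, so their content never matters.

#' GAN configuration
#'
#' Full-scale defaults: LSTM width 279, discriminator residual/normalisation
#' width 100 and fully connected width 256, adversarial batch size 500.
#' `desk_gan_config()` shrinks these for one-CPU experiments.
#'
#' @param lstm_size Hidden width of every LSTM layer.
#' @param resnorm_width Width of the discriminator's residual +
#'   normalisation layer.
#' @param fc_width Width of the discriminator's fully connected layer.
#' @param batch_size Originals per adversarial batch; the discriminator
#'   phase sees `2 * batch_size` samples with balanced labels.
#' @param max_epochs Hard stop on alternating epochs.
#' @param patience Plateau length: a phase stops when its loss fails to
#'   improve by `plateau_tol` (relative) for `patience` consecutive steps;
#'   training stops when the discriminator's balanced accuracy stays inside
#'   `eq_band` for `patience` consecutive epochs.
#' @param noise_sd Standard deviation of the Gaussian noise injected into
#'   the generator's input rows.
#' @param plateau_tol Relative improvement below which a phase loss counts
#'   as plateaued.
#' @param d_steps_max,g_steps_max Hard caps on steps per phase.
#' @param eq_band Balanced-accuracy band treated as equilibrium.
#' @param learning_rate Adam step size for both networks.
#' @param seed Integer seed.
#' @return A list of class `gan_config`.
#' @export
gan_config <- function(lstm_size = 279L, resnorm_width = 100L,
                       fc_width = 256L, batch_size = 500L,
                       max_epochs = 20L, patience = 5L, noise_sd = 0.05,
                       plateau_tol = 1e-3, d_steps_max = 25L,
                       g_steps_max = 25L, eq_band = c(0.45, 0.55),
                       learning_rate = 2e-3, seed = 1L) {
  cfg <- list(lstm_size = assert_count(lstm_size, "lstm_size"),
              resnorm_width = assert_count(resnorm_width, "resnorm_width"),
              fc_width = assert_count(fc_width, "fc_width"),
              batch_size = assert_count(batch_size, "batch_size"),
              max_epochs = assert_count(max_epochs, "max_epochs"),
              patience = assert_count(patience, "patience"),
              noise_sd = noise_sd, plateau_tol = plateau_tol,
              d_steps_max = assert_count(d_steps_max, "d_steps_max"),
              g_steps_max = assert_count(g_steps_max, "g_steps_max"),
              eq_band = eq_band, learning_rate = learning_rate,
              seed = as.integer(seed))
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  class(cfg) <- "gan_config"
  cfg
}

#' Desk-scale GAN profile
#' @param ... Overrides passed to [gan_config()].
#' @return A `gan_config`.
#' @export
desk_gan_config <- function(...) {
  defaults <- list(lstm_size = 16L, resnorm_width = 16L, fc_width = 32L,
                   batch_size = 32L, max_epochs = 8L,
                   d_steps_max = 15L, g_steps_max = 15L)
  do.call(gan_config, utils::modifyList(defaults, list(...)))
}

# ---- batched LSTM ---------------------------------------------------------

slice_t <- function(X3, t) matrix(X3[, t, ], nrow = dim(X3)[1])

lstm3_init <- function(din, L) {
  list(W = glorot(din, 4L * L), U = glorot(L, 4L * L), b = numeric(4L * L))
}

lstm3_fwd <- function(X3, W, U, b) {
  B <- dim(X3)[1]; k <- dim(X3)[2]; L <- ncol(U) / 4L
  H3 <- array(0, c(B, k, L))
  gi <- array(0, c(B, k, L)); gf <- gi; go <- gi; gg <- gi
  C3 <- gi; T3 <- gi
  h <- matrix(0, B, L); cc <- matrix(0, B, L)
  i1 <- seq_len(L); i2 <- L + i1; i3 <- 2L * L + i1; i4 <- 3L * L + i1
  for (t in seq_len(k)) {
    a <- sweep(slice_t(X3, t) %*% W + h %*% U, 2, b, "+")
    i <- sigmoid(a[, i1, drop = FALSE]); f <- sigmoid(a[, i2, drop = FALSE])
    o <- sigmoid(a[, i3, drop = FALSE]); g <- tanh(a[, i4, drop = FALSE])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    H3[, t, ] <- h; gi[, t, ] <- i; gf[, t, ] <- f; go[, t, ] <- o
    gg[, t, ] <- g; C3[, t, ] <- cc; T3[, t, ] <- tc
  }
  list(H3 = H3, cache = list(gi = gi, gf = gf, go = go, gg = gg,
                             C3 = C3, T3 = T3, X3 = X3, H3 = H3))
}

lstm3_bwd <- function(dH3, cache, W, U) {
  X3 <- cache$X3
  B <- dim(X3)[1]; k <- dim(X3)[2]; L <- dim(dH3)[3]
  dW <- W * 0; dU <- U * 0; db <- numeric(4L * L)
  dX3 <- array(0, dim(X3))
  dh_next <- matrix(0, B, L); dc_next <- dh_next
  for (t in rev(seq_len(k))) {
    i <- slice_t(cache$gi, t); f <- slice_t(cache$gf, t)
    o <- slice_t(cache$go, t); g <- slice_t(cache$gg, t)
    tc <- slice_t(cache$T3, t)
    c_prev <- if (t > 1) slice_t(cache$C3, t - 1L) else matrix(0, B, L)
    h_prev <- if (t > 1) slice_t(cache$H3, t - 1L) else matrix(0, B, L)
    dh <- slice_t(dH3, t) + dh_next
    do_ <- dh * tc
    dc <- dh * o * (1 - tc^2) + dc_next
    di <- dc * g; dg <- dc * i; df <- dc * c_prev
    dc_next <- dc * f
    da <- cbind(di * i * (1 - i), df * f * (1 - f),
                do_ * o * (1 - o), dg * (1 - g^2))
    xt <- slice_t(X3, t)
    dW <- dW + crossprod(xt, da)
    dU <- dU + crossprod(h_prev, da)
    db <- db + colSums(da)
    dX3[, t, ] <- da %*% t(W)
    dh_next <- da %*% t(U)
  }
  list(dX3 = dX3, dW = dW, dU = dU, db = db)
}

# apply a dense layer position-wise over a (B, k, din) array
dense3 <- function(X3, W, b) {
  B <- dim(X3)[1]; k <- dim(X3)[2]
  out <- sweep(matrix(X3, B * k) %*% W, 2, b, "+")
  array(out, c(B, k, ncol(W)))
}

dense3_bwd <- function(dY3, X3, W) {
  B <- dim(X3)[1]; k <- dim(X3)[2]
  dY <- matrix(dY3, B * k); X <- matrix(X3, B * k)
  list(dX3 = array(dY %*% t(W), dim(X3)),
       dW = crossprod(X, dY), db = colSums(dY))
}

ln3_fwd <- function(X3, g, b) {
  B <- dim(X3)[1]; k <- dim(X3)[2]; L <- dim(X3)[3]
  res <- layernorm_fwd(matrix(X3, B * k), g, b)
  list(Y3 = array(res$Y, c(B, k, L)), cache = res)
}

ln3_bwd <- function(dY3, cache, g, dims) {
  res <- layernorm_bwd(matrix(dY3, dims[1] * dims[2]), cache, g)
  list(dX3 = array(res$dX, dims), dg = res$dg, db = res$db)
}

# ---- parameter initialisation --------------------------------------------

init_generator <- function(cfg, d) {
  L <- cfg$lstm_size
  l1 <- lstm3_init(L, L); l2 <- lstm3_init(L, L)
  list(g_Pin = glorot(d, L), g_bin = numeric(L),
       g_W1 = l1$W, g_U1 = l1$U, g_b1 = l1$b,
       g_ln1g = rep(1, L), g_ln1b = numeric(L),
       g_W2 = l2$W, g_U2 = l2$U, g_b2 = l2$b,
       g_ln2g = rep(1, L), g_ln2b = numeric(L),
       # zero output projection + global residual: identity map at init
       g_Pout = matrix(0, L, d), g_bout = numeric(d))
}

init_discriminator <- function(cfg, d) {
  L <- cfg$lstm_size; R <- cfg$resnorm_width; Fw <- cfg$fc_width
  l <- lstm3_init(L, L)
  list(d_Pin = glorot(d, L), d_bin = numeric(L),
       d_W = l$W, d_U = l$U, d_b = l$b,
       d_Wr = glorot(L, R), d_Ws = glorot(L, R), d_br = numeric(R),
       d_g = rep(1, R), d_bb = numeric(R),
       d_Wf = glorot(R, Fw), d_bf = numeric(Fw),
       d_Wo = glorot(Fw, 1L), d_bo = 0)
}

# ---- forward / backward ---------------------------------------------------

stack_embeddings <- function(x) {
  stopifnot(length(x) > 0)
  k <- nrow(x[[1]]$values); d <- ncol(x[[1]]$values)
  B <- length(x)
  X3 <- array(0, c(B, k, d)); M <- matrix(FALSE, B, k)
  for (b in seq_len(B)) {
    if (nrow(x[[b]]$values) != k || ncol(x[[b]]$values) != d)
      stopf("all embedding matrices must share the same shape")
    X3[b, , ] <- x[[b]]$values
    M[b, ] <- x[[b]]$mask
  }
  list(X3 = X3, mask = M)
}

mask3 <- function(X3, M) X3 * array(M, dim(X3))

gen_fwd <- function(p, cfg, X3, M, E3) {
  Xn <- mask3(X3 + E3, M)
  P <- dense3(Xn, p$g_Pin, p$g_bin)
  l1 <- lstm3_fwd(P, p$g_W1, p$g_U1, p$g_b1)
  n1 <- ln3_fwd(P + l1$H3, p$g_ln1g, p$g_ln1b)
  l2 <- lstm3_fwd(n1$Y3, p$g_W2, p$g_U2, p$g_b2)
  n2 <- ln3_fwd(n1$Y3 + l2$H3, p$g_ln2g, p$g_ln2b)
  Y <- mask3(Xn + dense3(n2$Y3, p$g_Pout, p$g_bout), M)
  list(Y3 = Y, cache = list(Xn = Xn, P = P, l1 = l1, n1 = n1,
                            l2 = l2, n2 = n2, M = M))
}

gen_bwd <- function(p, cfg, cache, dY3) {
  dY3 <- mask3(dY3, cache$M)
  g <- list()
  pb <- dense3_bwd(dY3, cache$n2$Y3, p$g_Pout)
  g$g_Pout <- pb$dW; g$g_bout <- pb$db
  dims <- dim(cache$P)
  n2b <- ln3_bwd(pb$dX3, cache$n2$cache, p$g_ln2g, dims)
  g$g_ln2g <- n2b$dg; g$g_ln2b <- n2b$db
  l2b <- lstm3_bwd(n2b$dX3, cache$l2$cache, p$g_W2, p$g_U2)
  g$g_W2 <- l2b$dW; g$g_U2 <- l2b$dU; g$g_b2 <- l2b$db
  dN1 <- n2b$dX3 + l2b$dX3
  n1b <- ln3_bwd(dN1, cache$n1$cache, p$g_ln1g, dims)
  g$g_ln1g <- n1b$dg; g$g_ln1b <- n1b$db
  l1b <- lstm3_bwd(n1b$dX3, cache$l1$cache, p$g_W1, p$g_U1)
  g$g_W1 <- l1b$dW; g$g_U1 <- l1b$dU; g$g_b1 <- l1b$db
  dP <- n1b$dX3 + l1b$dX3
  pib <- dense3_bwd(dP, cache$Xn, p$g_Pin)
  g$g_Pin <- pib$dW; g$g_bin <- pib$db
  g
}

disc_fwd <- function(p, cfg, X3, M) {
  Xm <- mask3(X3, M)
  P <- dense3(Xm, p$d_Pin, p$d_bin)
  l <- lstm3_fwd(P, p$d_W, p$d_U, p$d_b)
  nv <- pmax(rowSums(M), 1L)
  W3 <- array(M, dim(l$H3)) / nv  # per-sample masked-mean weights
  hbar <- apply(l$H3 * W3, c(1, 3), sum)
  pbar <- apply(P * W3, c(1, 3), sum)
  pre <- sweep(hbar %*% p$d_Wr + pbar %*% p$d_Ws, 2, p$d_br, "+")
  ln <- layernorm_fwd(pre, p$d_g, p$d_bb)
  fpre <- sweep(ln$Y %*% p$d_Wf, 2, p$d_bf, "+")
  f <- pmax(fpre, 0)
  logit <- drop(f %*% p$d_Wo) + p$d_bo
  list(prob = sigmoid(logit),
       cache = list(Xm = Xm, P = P, l = l, W3 = W3, hbar = hbar,
                    pbar = pbar, ln = ln, fpre = fpre, f = f, M = M))
}

disc_bwd <- function(p, cfg, cache, dlogit, need_dX = FALSE) {
  g <- list()
  g$d_Wo <- crossprod(cache$f, matrix(dlogit)); g$d_bo <- sum(dlogit)
  df <- (matrix(dlogit) %*% t(p$d_Wo)) * (cache$fpre > 0)
  g$d_Wf <- crossprod(cache$ln$Y, df); g$d_bf <- colSums(df)
  dz <- df %*% t(p$d_Wf)
  lb <- layernorm_bwd(dz, cache$ln, p$d_g)
  g$d_g <- lb$dg; g$d_bb <- lb$db
  dpre <- lb$dX
  g$d_Wr <- crossprod(cache$hbar, dpre); g$d_Ws <- crossprod(cache$pbar, dpre)
  g$d_br <- colSums(dpre)
  dhbar <- dpre %*% t(p$d_Wr); dpbar <- dpre %*% t(p$d_Ws)
  dims <- dim(cache$P)
  dH3 <- array(dhbar[rep(seq_len(dims[1]), dims[2]), ], dims) * cache$W3
  dP_pool <- array(dpbar[rep(seq_len(dims[1]), dims[2]), ], dims) * cache$W3
  lb3 <- lstm3_bwd(dH3, cache$l$cache, p$d_W, p$d_U)
  g$d_W <- lb3$dW; g$d_U <- lb3$dU; g$d_b <- lb3$db
  dP <- lb3$dX3 + dP_pool
  pib <- dense3_bwd(dP, cache$Xm, p$d_Pin)
  g$d_Pin <- pib$dW; g$d_bin <- pib$db
  list(grads = g, dX3 = if (need_dX) mask3(pib$dX3, cache$M) else NULL)
}

# ---- public operations ----------------------------------------------------

#' Generate a noise-added embedding sample
#'
#' Runs one original embedding through the generator with fresh Gaussian
#' input noise. The output has the same shape and mask as the input and
#' zero padded rows.
#'
#' @param gan A fitted [fit_gan()] object (an untrained, freshly
#'   initialised generator acts as the identity plus input noise).
#' @param x An [embedding_matrix].
#' @param noise_seed Optional seed making the draw reproducible.
#' @return An [embedding_matrix] of identical shape.
#' @export
gan_generate <- function(gan, x, noise_seed = NULL) {
  stopifnot(inherits(gan, "tcm_gan"), inherits(x, "embedding_matrix"))
  st <- stack_embeddings(list(x))
  draw <- function() {
    E3 <- array(stats::rnorm(length(st$X3), 0, gan$config$noise_sd), dim(st$X3))
    gen_fwd(gan$params_g, gan$config, st$X3, st$mask, E3)$Y3
  }
  Y3 <- if (is.null(noise_seed)) draw() else local_seed(noise_seed, draw())
  structure(list(values = matrix(Y3[1, , ], dim(Y3)[2]),
                 mask = x$mask, t_hours = x$t_hours),
            class = "embedding_matrix")
}

#' Discriminator score of embedding samples
#'
#' @param gan A fitted [fit_gan()] object.
#' @param x An [embedding_matrix] or list of them.
#' @return Probability (per sample) that the input is an original rather
#'   than a generated sample, strictly in (0, 1).
#' @export
discriminate <- function(gan, x) {
  stopifnot(inherits(gan, "tcm_gan"))
  if (inherits(x, "embedding_matrix")) x <- list(x)
  st <- stack_embeddings(x)
  unname(disc_fwd(gan$params_d, gan$config, st$X3, st$mask)$prob)
}

#' @export
predict.tcm_gan <- function(object, newdata, ...) discriminate(object, newdata)

plateau_tracker <- function(patience, tol, direction = "min") {
  best <- if (direction == "min") Inf else -Inf
  stale <- 0L
  function(v) {
    improved <- if (!is.finite(best)) TRUE
    else if (direction == "min") v < best - abs(best) * tol - 1e-12
    else v > best + abs(best) * tol + 1e-12
    if (improved) { best <<- v; stale <<- 0L } else stale <<- stale + 1L
    stale >= patience
  }
}

#' Train the LSTM GAN on original training embeddings
#'
#' Alternates discriminator and generator phases. Per epoch the generator
#' produces `batch_size` noise-added samples; concatenated with
#' `batch_size` originals they form a balanced `2 * batch_size` batch on
#' which the discriminator trains by backpropagation until its binary
#' cross-entropy stops decreasing; the discriminator is then frozen and
#' the generator trains against it until its adversarial binary
#' cross-entropy stops increasing. Training ends when the discriminator's
#' balanced accuracy stays within `eq_band` for `patience` consecutive
#' epochs (operationalising equilibrium) or at `max_epochs`.
#'
#' @param x List of original [embedding_matrix] samples (all same shape).
#' @param cfg A [gan_config()].
#' @param verbose Print a line per epoch.
#' @return An object of class `tcm_gan`: `params_g`, `params_d`, `config`,
#'   `history` (data.frame of epoch/phase/step/loss/balanced accuracy) and
#'   `dims`.
#' @export
fit_gan <- function(x, cfg = gan_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "gan_config"))
  if (length(x) == 0L) stopf("empty training set")
  k <- nrow(x[[1]]$values); d <- ncol(x[[1]]$values)
  n <- length(x)

  local_seed(cfg$seed, {
    pg <- init_generator(cfg, d)
    pd <- init_discriminator(cfg, d)
    stg <- adam_init(pg); std <- adam_init(pd)
    hist <- list()
    eq_run <- 0L

    for (ep in seq_len(cfg$max_epochs)) {
      idx <- sample.int(n, cfg$batch_size, replace = n < cfg$batch_size)
      st <- stack_embeddings(x[idx])
      B <- cfg$batch_size

      # --- discriminator phase: fixed fakes, labels original=1 / fake=0
      E3 <- array(stats::rnorm(length(st$X3), 0, cfg$noise_sd), dim(st$X3))
      fake <- gen_fwd(pg, cfg, st$X3, st$mask, E3)$Y3
      X2 <- array(0, c(2L * B, k, d))
      X2[seq_len(B), , ] <- fake; X2[B + seq_len(B), , ] <- st$X3
      M2 <- rbind(st$mask, st$mask)
      yl <- c(rep(0, B), rep(1, B))
      stop_d <- plateau_tracker(cfg$patience, cfg$plateau_tol, "min")
      for (step in seq_len(cfg$d_steps_max)) {
        fw <- disc_fwd(pd, cfg, X2, M2)
        loss <- bce(fw$prob, yl)
        if (!is.finite(loss)) stopf("GAN diverged (non-finite D loss)")
        hist[[length(hist) + 1L]] <-
          data.frame(epoch = ep, phase = "D", step = step,
                     loss = loss, d_balanced_acc = NA_real_)
        dlogit <- (fw$prob - yl) / (2 * B)
        gr <- disc_bwd(pd, cfg, fw$cache, dlogit)$grads
        res <- adam_step(pd, gr, std, cfg$learning_rate)
        pd <- res$p; std <- res$st
        if (stop_d(loss)) break
      }

      # --- generator phase: frozen D, fresh noise each step
      stop_g <- plateau_tracker(cfg$patience, cfg$plateau_tol, "max")
      for (step in seq_len(cfg$g_steps_max)) {
        E3 <- array(stats::rnorm(length(st$X3), 0, cfg$noise_sd), dim(st$X3))
        gf <- gen_fwd(pg, cfg, st$X3, st$mask, E3)
        fw <- disc_fwd(pd, cfg, gf$Y3, st$mask)
        adv_bce <- bce(fw$prob, rep(0, B))  # D's loss on fakes: G drives it up
        if (!is.finite(adv_bce)) stopf("GAN diverged (non-finite G loss)")
        hist[[length(hist) + 1L]] <-
          data.frame(epoch = ep, phase = "G", step = step,
                     loss = adv_bce, d_balanced_acc = NA_real_)
        # non-saturating generator update: minimise -log D(fake)
        dlogit <- -(1 - fw$prob) / B
        db <- disc_bwd(pd, cfg, fw$cache, dlogit, need_dX = TRUE)
        gr <- gen_bwd(pg, cfg, gf$cache, db$dX3)
        res <- adam_step(pg, gr, stg, cfg$learning_rate)
        pg <- res$p; stg <- res$st
        if (stop_g(adv_bce)) break
      }

      # --- equilibrium diagnostic on fresh fakes
      E3 <- array(stats::rnorm(length(st$X3), 0, cfg$noise_sd), dim(st$X3))
      fake <- gen_fwd(pg, cfg, st$X3, st$mask, E3)$Y3
      p_real <- disc_fwd(pd, cfg, st$X3, st$mask)$prob
      p_fake <- disc_fwd(pd, cfg, fake, st$mask)$prob
      bacc <- (mean(p_real >= 0.5) + mean(p_fake < 0.5)) / 2
      hist[[length(hist) + 1L]] <-
        data.frame(epoch = ep, phase = "epoch", step = NA_integer_,
                   loss = NA_real_, d_balanced_acc = bacc)
      if (verbose)
        cat(sprintf("epoch %2d  D balanced accuracy %.3f\n", ep, bacc))
      eq_run <- if (bacc >= cfg$eq_band[1] && bacc <= cfg$eq_band[2])
        eq_run + 1L else 0L
      if (eq_run >= cfg$patience) break
    }

    structure(list(params_g = pg, params_d = pd, config = cfg,
                   history = do.call(rbind, hist),
                   dims = c(max_num_tokens = k, vector_size = d), n = n),
              class = "tcm_gan")
  })
}

#' @export
print.tcm_gan <- function(x, ...) {
  last <- x$history$d_balanced_acc
  last <- last[!is.na(last)]
  cat(sprintf(
    "LSTM GAN augmenter: lstm %d, input %d x %d, %d epochs, final D balanced accuracy %.3f\n",
    x$config$lstm_size, x$dims[1], x$dims[2],
    max(x$history$epoch), last[length(last)]))
  invisible(x)
}

#' Held-out discriminator balanced accuracy
#'
#' Generates one fresh fake per held-out original and scores both sets,
#' returning `(true positive rate + true negative rate) / 2` at 0.5. Near
#' 0.5 indicates the adversarial game reached equilibrium.
#'
#' @param gan A fitted [fit_gan()] object.
#' @param x Held-out originals (list of [embedding_matrix]).
#' @param seed Seed for the noise draws.
#' @return A single number in `[0, 1]`.
#' @export
discriminator_accuracy <- function(gan, x, seed = 1L) {
  st <- stack_embeddings(x)
  local_seed(seed, {
    E3 <- array(stats::rnorm(length(st$X3), 0, gan$config$noise_sd), dim(st$X3))
    fake <- gen_fwd(gan$params_g, gan$config, st$X3, st$mask, E3)$Y3
    p_real <- disc_fwd(gan$params_d, gan$config, st$X3, st$mask)$prob
    p_fake <- disc_fwd(gan$params_d, gan$config, fake, st$mask)$prob
    (mean(p_real >= 0.5) + mean(p_fake < 0.5)) / 2
  })
}

#' Double a training set with generated samples
#'
#' Produces exactly one noise-added sample per original via the trained
#' generator; every generated sample inherits its source's label vector.
#' Originals are passed through untouched.
#'
#' @param x List of original [embedding_matrix] samples.
#' @param y Binary label matrix, one row per original.
#' @param gan A fitted [fit_gan()] object.
#' @param seed Seed for the noise draws.
#' @return List with `x` (length `2N`: originals then generated), `y`
#'   (`2N` rows) and `origin` (`"original"` / `"generated"`).
#' @export
augment_dataset <- function(x, y, gan, seed = 1L) {
  stopifnot(inherits(gan, "tcm_gan"))
  if (!is.matrix(y)) y <- as.matrix(y)
  if (length(x) != nrow(y)) stopf("`y` must have one row per sample in `x`")
  if (length(x) == 0L)
    return(list(x = list(), y = y[0, , drop = FALSE], origin = character()))
  fakes <- local_seed(seed, {
    st <- stack_embeddings(x)
    E3 <- array(stats::rnorm(length(st$X3), 0, gan$config$noise_sd), dim(st$X3))
    Y3 <- gen_fwd(gan$params_g, gan$config, st$X3, st$mask, E3)$Y3
    lapply(seq_along(x), function(b)
      structure(list(values = matrix(Y3[b, , ], dim(Y3)[2]),
                     mask = x[[b]]$mask, t_hours = x[[b]]$t_hours),
                class = "embedding_matrix"))
  })
  list(x = c(x, fakes),
       y = rbind(y, y),
       origin = rep(c("original", "generated"), each = length(x)))
}
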