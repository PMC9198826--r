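# Skip-gram word embeddings and fixed-size embedding matrices.
#
# Tokens are embedded with a skip-gram model trained on the cohort's token
# corpus. At the vocabulary sizes of structured clinical tokens the exact
# softmax over the vocabulary is tractable, so the trainer optimises it
# directly (it is the objective that the usual hierarchical-softmax and
# negative-sampling schemes approximate), with the classic dynamic context
# window: for each center token the effective window is drawn uniformly
# from 1..window.

#' Skip-gram embedding configuration
#'
#' @param min_count Minimum corpus frequency; rarer tokens are dropped from
#'   the vocabulary and treated as out-of-vocabulary downstream.
#' @param vector_size Embedding dimension.
#' @param window Maximum context window (dynamic: each center position
#'   samples its window size uniformly from `1:window`).
#' @param epochs Passes over the corpus.
#' @param learning_rate Initial SGD step size, decayed linearly to 10% over
#'   training.
#' @param max_pairs_per_epoch Cap on (center, context) pairs sampled per
#'   epoch; keeps training time bounded on large corpora.
#' @param seed Integer seed (initialisation and window sampling).
#' @return A list of class `embed_config`.
#' @export
embed_config <- function(min_count = 2L, vector_size = 100L, window = 5L,
                         epochs = 50L, learning_rate = 0.05,
                         max_pairs_per_epoch = 100000L, seed = 1L) {
  cfg <- list(min_count = assert_count(min_count, "min_count"),
              vector_size = assert_count(vector_size, "vector_size"),
              window = assert_count(window, "window"),
              epochs = assert_count(epochs, "epochs"),
              learning_rate = learning_rate,
              max_pairs_per_epoch = assert_count(max_pairs_per_epoch,
                                                 "max_pairs_per_epoch"),
              seed = as.integer(seed))
  class(cfg) <- "embed_config"
  cfg
}

corpus_tokens <- function(corpus) {
  lapply(corpus, function(s) {
    if (inherits(s, "token_sequence")) s$tokens else as.character(s)
  })
}

#' Train skip-gram embeddings on a token corpus
#'
#' @param corpus List of [token_sequence] objects (or plain character
#'   vectors), one per patient/document.
#' @param cfg An [embed_config()].
#' @return An object of class `skipgram`: `vocab` (character), `vectors`
#'   (|V| x vector_size matrix, rownames = tokens), `counts`, `cfg`.
#' @export
train_embeddings <- function(corpus, cfg = embed_config()) {
  stopifnot(inherits(cfg, "embed_config"))
  sents <- corpus_tokens(corpus)
  all_tokens <- unlist(sents, use.names = FALSE)
  if (length(all_tokens) == 0L) stopf("empty corpus")
  counts <- table(all_tokens)
  vocab <- sort(names(counts)[counts >= cfg$min_count])
  if (length(vocab) == 0L)
    stopf("no token reaches min_count = %d", cfg$min_count)
  index <- stats::setNames(seq_along(vocab), vocab)
  V <- length(vocab); d <- cfg$vector_size

  # Sentences as index vectors, out-of-vocabulary tokens removed before
  # windowing (so context windows skip over dropped tokens).
  sent_idx <- lapply(sents, function(s) unname(index[s[s %in% vocab]]))
  sent_idx <- sent_idx[lengths(sent_idx) >= 2L]

  local_seed(cfg$seed, {
    W_in <- matrix(stats::runif(V * d, -0.5, 0.5) / d, V, d)
    W_out <- matrix(0, V, d)
    if (length(sent_idx)) {
      # Adam keeps the updates well-scaled regardless of chunk averaging,
      # so the vectors reach their natural magnitude within a few epochs.
      st <- adam_init(list(W_in = W_in, W_out = W_out))
      for (ep in seq_len(cfg$epochs)) {
        pairs <- sample_pairs(sent_idx, cfg$window, cfg$max_pairs_per_epoch)
        if (!nrow(pairs)) next
        nchunk <- ceiling(nrow(pairs) / 4096)
        splits <- split(seq_len(nrow(pairs)),
                        rep(seq_len(nchunk), each = 4096, length.out = nrow(pairs)))
        for (ix in splits) {
          ctr <- pairs[ix, 1L]; ctx <- pairs[ix, 2L]
          X <- W_in[ctr, , drop = FALSE]
          logits <- X %*% t(W_out)
          logits <- logits - apply(logits, 1L, max)
          P <- exp(logits); P <- P / rowSums(P)
          P[cbind(seq_along(ctx), ctx)] <- P[cbind(seq_along(ctx), ctx)] - 1
          gW_out <- crossprod(P, X) / length(ctx)
          gX <- (P %*% W_out) / length(ctx)
          gW_in <- matrix(0, V, d)
          acc <- rowsum(gX, ctr)
          gW_in[as.integer(rownames(acc)), ] <- as.matrix(acc) / length(ctx)
          res <- adam_step(list(W_in = W_in, W_out = W_out),
                           list(W_in = gW_in, W_out = gW_out),
                           st, cfg$learning_rate)
          W_in <- res$p$W_in; W_out <- res$p$W_out; st <- res$st
        }
      }
    }
    rownames(W_in) <- vocab
    structure(list(vocab = vocab, vectors = W_in,
                   counts = as.integer(counts[vocab]), cfg = cfg),
              class = "skipgram")
  })
}

# Enumerate (center, context) index pairs with dynamic windows; subsample
# uniformly if over the per-epoch cap.
sample_pairs <- function(sent_idx, window, max_pairs) {
  acc <- vector("list", length(sent_idx))
  for (si in seq_along(sent_idx)) {
    s <- sent_idx[[si]]
    n <- length(s)
    b <- sample.int(window, n, replace = TRUE)
    lo <- pmax(1L, seq_len(n) - b); hi <- pmin(n, seq_len(n) + b)
    reps <- hi - lo  # window size minus the center itself
    centers <- rep.int(seq_len(n), reps)
    ctxpos <- unlist(lapply(seq_len(n), function(i) setdiff(lo[i]:hi[i], i)),
                     use.names = FALSE)
    acc[[si]] <- cbind(s[centers], s[ctxpos])
  }
  pairs <- do.call(rbind, acc)
  if (is.null(pairs)) return(matrix(integer(), 0, 2))
  if (nrow(pairs) > max_pairs)
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
  pairs
}

#' @export
print.skipgram <- function(x, ...) {
  cat("<skipgram> vocabulary ", length(x$vocab), " tokens, ",
      x$cfg$vector_size, "-dimensional vectors\n", sep = "")
  invisible(x)
}

#' Turn a token sequence into a fixed-size embedding matrix
#'
#' In-vocabulary tokens are mapped to their vectors in chronological order.
#' Sequences shorter than `max_num_tokens` are zero-padded (mask `FALSE`);
#' longer sequences are clipped by dropping the tokens with the oldest
#' timestamps until the cap is met, keeping the most recent
#' `max_num_tokens`. Out-of-vocabulary tokens keep their position but get a
#' zero row with mask `FALSE`.
#'
#' @param seq A [token_sequence] (or character vector, taken as equally
#'   spaced in time).
#' @param model A trained [skipgram] model.
#' @param max_num_tokens Row count of the output matrix.
#' @return An object of class `embedding_matrix`: `values`
#'   (`max_num_tokens` x `vector_size` matrix), `mask` (logical vector,
#'   `TRUE` = real in-vocabulary token) and `t_hours` (`NA` on padding).
#' @export
vectorize <- function(seq, model, max_num_tokens) {
  stopifnot(inherits(model, "skipgram"))
  max_num_tokens <- assert_count(max_num_tokens, "max_num_tokens")
  if (!inherits(seq, "token_sequence"))
    seq <- structure(list(tokens = as.character(seq),
                          t_hours = seq_along(seq)), class = "token_sequence")
  toks <- seq$tokens; tt <- seq$t_hours
  n <- length(toks)
  if (n > max_num_tokens) {
    ord <- order(tt, method = "radix")  # stable: ties keep original order
    keep <- sort(ord[(n - max_num_tokens + 1L):n])
    toks <- toks[keep]; tt <- tt[keep]
    n <- max_num_tokens
  }
  d <- ncol(model$vectors)
  values <- matrix(0, max_num_tokens, d)
  mask <- rep(FALSE, max_num_tokens)
  t_hours <- rep(NA_real_, max_num_tokens)
  if (n) {
    inv <- toks %in% model$vocab
    if (any(inv)) values[seq_len(n)[inv], ] <- model$vectors[toks[inv], , drop = FALSE]
    mask[seq_len(n)] <- inv
    t_hours[seq_len(n)] <- tt
  }
  structure(list(values = values, mask = mask, t_hours = t_hours),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat("<embedding_matrix> ", nrow(x$values), " x ", ncol(x$values),
      ", ", sum(x$mask), " real tokens\n", sep = "")
  invisible(x)
}

#' Write embeddings in the word2vec text format
#'
#' First line `"<vocab size> <dim>"`, then one `token v1 ... vd` line per
#' vocabulary entry.
#'
#' @param model A [skipgram] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(model, path) {
  stopifnot(inherits(model, "skipgram"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(length(model$vocab), ncol(model$vectors)), con)
  for (i in seq_along(model$vocab)) {
    writeLines(paste(model$vocab[i],
                     paste(sprintf("%.8g", model$vectors[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Read embeddings from the word2vec text format
#'
#' @param path Path written by [write_word2vec()] (or any tool emitting the
#'   same format).
#' @return A [skipgram]-classed model usable by [vectorize()].
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  V <- hdr[1]; d <- hdr[2]
  parts <- strsplit(trimws(lines[1 + seq_len(V)]), "\\s+")
  vocab <- vapply(parts, `[[`, character(1), 1L)
  vectors <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(vectors) <- vocab
  structure(list(vocab = vocab, vectors = vectors,
                 counts = rep(NA_integer_, V),
                 cfg = embed_config(vector_size = d)),
            class = "skipgram")
}
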