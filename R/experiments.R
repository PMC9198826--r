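# Packaged reproduction experiments.
#
# These bundle the package's headline desk-scale studies so the test suite
# and the acceptance script run the identical protocol. Sizes are chosen to
# complete on one CPU in minutes; the methods vignette discusses them.

#' Parameter recovery on a noiseless planted cohort
#'
#' Generates a noiseless synthetic cohort (10 first categories, 5 leaves
#' each, 500 patients), trains the desk-scale transformer on the admission
#' slice of 90% of patients, and scores the held-out 10% by category
#' rollup. On noiseless data the admission symptoms determine the planted
#' categories exactly, so a correctly working pipeline recovers them with
#' high precision and recall.
#'
#' @param seed Integer seed for every stochastic stage.
#' @param n_patients,epochs Scale knobs (defaults are the packaged study).
#' @return List with `precision`, `recall`, `n_test`, and the underlying
#'   [evaluate_timeline()] row.
#' @export
recovery_experiment <- function(seed = 1L, n_patients = 500L, epochs = 30L) {
  seed <- as.integer(seed)
  cc <- cohort_config(n_patients = n_patients, n_syndromes = 10L,
                      n_category1 = 10L, leaves_per_category = 5L,
                      symptoms_per_syndrome = 4L, facts_per_day = 6,
                      horizon_days = 7L, label_noise = 0, symptom_noise = 0,
                      seed = seed)
  onto <- synth_ontology(cc)
  recs <- generate_cohort(cc, onto)
  n_test <- max(1L, round(0.1 * n_patients))
  test_idx <- local_seed(seed + 500L, sample.int(n_patients, n_test))
  trn <- recs[-test_idx]; tst <- recs[test_idx]
  emb <- train_embeddings(lapply(trn, extract_tokens),
                          embed_config(vector_size = 32L, epochs = 5L,
                                       learning_rate = 0.01, seed = seed + 1L))
  ts <- make_training_set(trn, onto, emb, 64L, cutoffs = 0)
  fit <- fit_transformer(ts$x, ts$y, desk_transformer_config(n_labels = 10L),
                         train_config(batch_size = 32L, epochs = epochs,
                                      learning_rate = 2e-3, seed = seed + 2L))
  ev <- evaluate_timeline(fit, tst, onto, emb, cutoffs = 0)
  list(precision = ev$precision[1], recall = ev$recall[1],
       n_test = ev$n[1], eval = ev)
}

#' Time-sliced evaluation on a cohort whose facts accrue signal
#'
#' Generates a cohort with noisy admission symptoms (spurious complaints
#' injected at rate 0.6) whose distinctive laboratory findings arrive over
#' the stay, trains one desk-scale transformer on all five decision-time
#' slices, and evaluates the held-out patients per slice. Because chart
#' prefixes only grow, test precision and recall are expected to be
#' non-decreasing from admission to one week.
#'
#' @param seed Integer seed.
#' @param n_patients,epochs Scale knobs.
#' @return A [evaluate_timeline()] data.frame over the five slices.
#' @export
timeslice_experiment <- function(seed = 1L, n_patients = 300L, epochs = 12L) {
  seed <- as.integer(seed)
  cc <- cohort_config(n_patients = n_patients, n_syndromes = 10L,
                      n_category1 = 10L, leaves_per_category = 5L,
                      symptoms_per_syndrome = 4L, facts_per_day = 3,
                      horizon_days = 7L, label_noise = 0, symptom_noise = 0.6,
                      seed = seed)
  onto <- synth_ontology(cc)
  recs <- generate_cohort(cc, onto)
  n_test <- max(1L, round(0.13 * n_patients))
  test_idx <- local_seed(seed + 501L, sample.int(n_patients, n_test))
  trn <- recs[-test_idx]; tst <- recs[test_idx]
  emb <- train_embeddings(lapply(trn, extract_tokens),
                          embed_config(vector_size = 32L, epochs = 4L,
                                       learning_rate = 0.01, seed = seed + 1L))
  cuts <- c(0, 24, 48, 72, 168)
  ts <- make_training_set(trn, onto, emb, 128L, cutoffs = cuts)
  cfg <- desk_transformer_config(n_labels = 10L, max_num_tokens = 128L)
  fit <- fit_transformer(ts$x, ts$y, cfg,
                         train_config(batch_size = 32L, epochs = epochs,
                                      learning_rate = 2e-3, seed = seed + 2L))
  evaluate_timeline(fit, tst, onto, emb, cutoffs = cuts)
}

#' GAN augmentation ablation on a small noisy cohort
#'
#' For each seed: generates a small (150-patient) cohort with 20% label
#' noise, trains the desk-scale transformer on the admission and 24-hour
#' slices of 80% of patients, then trains the LSTM GAN on those
#' embeddings, doubles the training set, retrains, and scores both models
#' on the held-out patients. Averaged over seeds, augmentation is expected
#' to match or improve both precision and recall — the overfitting-relief
#' effect the augmenter exists for.
#'
#' @param seeds Integer vector of seeds (one replicate each).
#' @param epochs Transformer epochs per fit.
#' @return List with the per-seed matrix `runs` (columns
#'   `precision_noaug`, `recall_noaug`, `precision_aug`, `recall_aug`) and
#'   the column `means`.
#' @export
ablation_experiment <- function(seeds = 1:5, epochs = 20L) {
  runs <- t(vapply(as.integer(seeds), function(seed) {
    cc <- cohort_config(n_patients = 150L, n_syndromes = 10L,
                        n_category1 = 10L, leaves_per_category = 5L,
                        symptoms_per_syndrome = 4L, facts_per_day = 3,
                        horizon_days = 7L, label_noise = 0.2,
                        symptom_noise = 0.3, seed = seed)
    onto <- synth_ontology(cc)
    recs <- generate_cohort(cc, onto)
    test_idx <- local_seed(seed + 502L, sample.int(150L, 30L))
    trn <- recs[-test_idx]; tst <- recs[test_idx]
    emb <- train_embeddings(lapply(trn, extract_tokens),
                            embed_config(vector_size = 32L, epochs = 3L,
                                         learning_rate = 0.01, seed = seed + 1L))
    cuts <- c(0, 24)
    ts <- make_training_set(trn, onto, emb, 64L, cutoffs = cuts)
    cfg <- desk_transformer_config(n_labels = 10L)
    tcfg <- train_config(batch_size = 32L, epochs = epochs,
                         learning_rate = 2e-3, seed = seed + 2L)
    micro <- function(ev) precision_recall(c(tp = sum(ev$tp), fp = sum(ev$fp),
                                             fn = sum(ev$fn)))
    fit0 <- fit_transformer(ts$x, ts$y, cfg, tcfg)
    pr0 <- micro(evaluate_timeline(fit0, tst, onto, emb, cutoffs = cuts))
    gan <- fit_gan(ts$x, desk_gan_config(max_epochs = 3L, seed = seed + 3L))
    aug <- augment_dataset(ts$x, ts$y, gan, seed = seed + 4L)
    fit1 <- fit_transformer(aug$x, aug$y, cfg, tcfg)
    pr1 <- micro(evaluate_timeline(fit1, tst, onto, emb, cutoffs = cuts))
    c(precision_noaug = pr0[["precision"]], recall_noaug = pr0[["recall"]],
      precision_aug = pr1[["precision"]], recall_aug = pr1[["recall"]])
  }, numeric(4)))
  list(runs = runs, means = colMeans(runs))
}

#' Discriminator equilibrium diagnostic on a toy distribution
#'
#' Trains the GAN on samples from a simple Gaussian embedding
#' distribution and reports the discriminator's held-out balanced
#' accuracy; values near one half indicate the adversarial game settled
#' at equilibrium rather than one side winning.
#'
#' @param seed Integer seed.
#' @return List with `balanced_accuracy` and the fitted `gan`.
#' @export
gan_equilibrium_experiment <- function(seed = 1L) {
  seed <- as.integer(seed)
  mk <- function(n, s) local_seed(s, lapply(seq_len(n), function(i)
    structure(list(values = matrix(stats::rnorm(8L * 4L, 0.5, 1), 8L, 4L),
                   mask = rep(TRUE, 8L), t_hours = 1:8),
              class = "embedding_matrix")))
  xs <- mk(120L, seed + 1L)
  held <- mk(40L, seed + 2L)
  gan <- fit_gan(xs, desk_gan_config(lstm_size = 8L, resnorm_width = 8L,
                                     fc_width = 16L, batch_size = 32L,
                                     max_epochs = 8L, seed = seed + 3L))
  list(balanced_accuracy = discriminator_accuracy(gan, held, seed = seed + 4L),
       gan = gan)
}
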