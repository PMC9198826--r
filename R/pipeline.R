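# End-to-end orchestration: synthesis -> QC -> tokenisation -> embedding ->
# (optional GAN augmentation) -> training -> time-sliced evaluation, with
# every artifact written next to a manifest recording the configuration
# hash and seed, so a rerun with the same configuration reproduces the
# artifacts exactly.

#' Assemble a full pipeline configuration
#'
#' @param preset `"demo"` (desk-scale: completes end-to-end in minutes on
#'   one CPU) or `"full"` (full-scale architecture constants; only
#'   sensible with a corpus of comparable size).
#' @param seed Global seed; each stochastic stage derives its own seed
#'   from it.
#' @param use_gan Train the GAN and double the training set before fitting.
#' @param cohort,embed,transformer,train,gan Optional replacement configs
#'   (see [cohort_config()], [embed_config()], [transformer_config()],
#'   [train_config()], [gan_config()]); `transformer` may omit `n_labels`,
#'   which is filled from the generated ontology.
#' @param cutoffs Evaluation time slices in hours.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("demo", "full"), seed = 1L,
                            use_gan = TRUE, cohort = NULL, embed = NULL,
                            transformer = NULL, train = NULL, gan = NULL,
                            cutoffs = c(0, 24, 48, 72, 168)) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  if (preset == "demo") {
    cohort <- cohort %||% cohort_config(
      n_patients = 80L, n_syndromes = 6L, n_category1 = 6L,
      leaves_per_category = 3L, symptoms_per_syndrome = 3L,
      facts_per_day = 4, horizon_days = 7L, label_noise = 0.05,
      symptom_noise = 0.2, qc_corrupt_frac = 0.05, seed = seed)
    embed <- embed %||% embed_config(vector_size = 32L, epochs = 3L,
                                     max_pairs_per_epoch = 50000L,
                                     seed = seed + 1L)
    transformer <- transformer %||% desk_transformer_config(
      n_labels = cohort$n_category1)
    train <- train %||% train_config(batch_size = 32L, epochs = 8L,
                                     seed = seed + 2L)
    gan <- gan %||% desk_gan_config(max_epochs = 4L, seed = seed + 3L)
  } else {
    cohort <- cohort %||% cohort_config(seed = seed)
    embed <- embed %||% embed_config(seed = seed + 1L)
    transformer <- transformer %||% transformer_config(
      n_labels = cohort$n_category1)
    train <- train %||% train_config(seed = seed + 2L)
    gan <- gan %||% gan_config(seed = seed + 3L)
  }
  structure(list(preset = preset, seed = seed, use_gan = isTRUE(use_gan),
                 cohort = cohort, embed = embed, transformer = transformer,
                 train = train, gan = gan, cutoffs = cutoffs),
            class = "pipeline_config")
}

label_matrix <- function(cat_sets, label_ids) {
  y <- matrix(0L, length(cat_sets), length(label_ids),
              dimnames = list(NULL, label_ids))
  for (i in seq_along(cat_sets)) y[i, match(cat_sets[[i]], label_ids)] <- 1L
  y
}

#' Build a supervised training set from records
#'
#' One sample per (patient, cutoff) cell that has a reference order: the
#' chart truncated at the cutoff becomes the input embedding, the rollup
#' of the order at the cutoff becomes the binary label vector.
#'
#' @param records Patient records (post-QC).
#' @param onto A [drug_ontology].
#' @param embedding A [skipgram] model.
#' @param max_num_tokens Input cap for [vectorize()].
#' @param cutoffs Cutoffs to sample.
#' @param level Rollup level for the labels.
#' @param include_prior_orders Passed to [extract_tokens()].
#' @return List with `x` (embedding matrices), `y` (binary matrix with
#'   category-id column names), `patient_id` and `cutoff_hours`.
#' @export
make_training_set <- function(records, onto, embedding, max_num_tokens,
                              cutoffs = c(0, 24, 48, 72, 168),
                              level = "category1",
                              include_prior_orders = TRUE) {
  ids <- category_ids(onto)
  x <- list(); cats <- list(); pid <- character(); cut <- numeric()
  for (r in records) {
    for (o in r$orders) {
      if (!any(vapply(cutoffs, function(co)
        isTRUE(all.equal(co, o$t_hours)), logical(1)))) next
      seq <- extract_tokens(r, o$t_hours,
                            include_prior_orders = include_prior_orders)
      x[[length(x) + 1L]] <- vectorize(seq, embedding, max_num_tokens)
      cats[[length(cats) + 1L]] <- rollup(onto, o$drug_ids, level)
      pid <- c(pid, r$patient_id); cut <- c(cut, o$t_hours)
    }
  }
  list(x = x, y = label_matrix(cats, ids), patient_id = pid,
       cutoff_hours = cut)
}

#' Run the full pipeline
#'
#' Executes generate -> corrupt -> QC filter -> tokenise -> embed ->
#' (optional GAN train + augment) -> train -> evaluate, writing artifacts
#' and a manifest under `out_dir`. The manifest records the configuration
#' hash and seed; rerunning with the same configuration reproduces it.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Artifacts directory (created if missing).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the fitted `model`, optional `gan`,
#'   `embedding`, `ontology`, evaluation tables `eval_train` / `eval_test`,
#'   QC summary and artifact `paths`.
#' @export
run_pipeline <- function(cfg, out_dir, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  paths <- list()

  say("[synth seed=%d] generating ontology and cohort", cfg$cohort$seed)
  onto <- synth_ontology(cfg$cohort)
  paths$ontology <- file.path(out_dir, "ontology.csv")
  write_drug_ontology(onto, paths$ontology)
  records <- generate_cohort(cfg$cohort, onto)
  records <- corrupt_records(records, cfg$cohort)
  paths$records <- file.path(out_dir, "records.jsonl")
  write_records_jsonl(records, paths$records)

  say("[qc] filtering")
  qc <- qc_filter(records)
  qc_summary <- data.frame(reason = c("kept", QC_DEFECTS),
                           n = c(length(qc$kept),
                                 vapply(QC_DEFECTS, function(d)
                                   sum(qc$reasons == d), integer(1))))
  paths$qc <- file.path(out_dir, "qc_report.csv")
  utils::write.csv(qc_summary, paths$qc, row.names = FALSE)
  records <- qc$kept

  # patient-level train/test split
  n <- length(records)
  n_test <- max(1L, round(cfg$train$holdout_frac * n))
  test_idx <- local_seed(cfg$seed + 10L, sample.int(n, n_test))
  train_rec <- records[-test_idx]; test_rec <- records[test_idx]

  say("[embed seed=%d] training skip-gram on %d charts",
      cfg$embed$seed, length(train_rec))
  corpus <- lapply(train_rec, extract_tokens)
  embedding <- train_embeddings(corpus, cfg$embed)
  paths$embedding <- file.path(out_dir, "embeddings.w2v.txt")
  write_word2vec(embedding, paths$embedding)

  tcfg_model <- cfg$transformer
  if (is.null(tcfg_model$n_labels) || tcfg_model$n_labels != onto$n_category1) {
    tcfg_model$n_labels <- onto$n_category1
  }
  if (tcfg_model$model_dim != cfg$embed$vector_size)
    stopf("transformer model_dim (%d) must equal embedding vector_size (%d)",
          tcfg_model$model_dim, cfg$embed$vector_size)

  train_set <- make_training_set(train_rec, onto, embedding,
                                 tcfg_model$max_num_tokens, cfg$cutoffs)
  gan <- NULL
  x <- train_set$x; y <- train_set$y
  if (cfg$use_gan) {
    say("[gan seed=%d] adversarial training on %d embeddings",
        cfg$gan$seed, length(x))
    gan <- fit_gan(x, cfg$gan)
    saveRDS(gan, paths$gan <- file.path(out_dir, "gan.rds"))
    aug <- augment_dataset(x, y, gan, seed = cfg$seed + 20L)
    x <- aug$x; y <- aug$y
    say("[augment] training set doubled to %d samples", length(x))
  }

  say("[train seed=%d] fitting transformer on %d samples",
      cfg$train$seed, length(x))
  model <- fit_transformer(x, y, tcfg_model, cfg$train)
  saveRDS(model, paths$model <- file.path(out_dir, "model.rds"))
  model_meta <- list(config = unclass(tcfg_model),
                     train_config = unclass(cfg$train),
                     n_train = length(x), augmented = cfg$use_gan)
  jsonlite::write_json(model_meta, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(model$trace, file.path(out_dir, "training_log.csv"),
                   row.names = FALSE)

  say("[evaluate] time slices: %s", paste(cfg$cutoffs, collapse = ", "))
  eval_train <- evaluate_timeline(model, train_rec, onto, embedding,
                                  cutoffs = cfg$cutoffs)
  eval_test <- evaluate_timeline(model, test_rec, onto, embedding,
                                 cutoffs = cfg$cutoffs)
  paths$eval_train <- file.path(out_dir, "eval_train.csv")
  paths$eval_test <- file.path(out_dir, "eval_test.csv")
  utils::write.csv(as.data.frame(eval_train), paths$eval_train, row.names = FALSE)
  utils::write.csv(as.data.frame(eval_test), paths$eval_test, row.names = FALSE)

  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  cfg_json <- jsonlite::toJSON(strip(cfg), auto_unbox = TRUE, digits = 12)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(package = "tcmrx",
                   version = as.character(utils::packageVersion("tcmrx")),
                   seed = cfg$seed, preset = cfg$preset,
                   config_md5 = unname(tools::md5sum(tf)),
                   n_patients = length(records) + length(qc$discarded),
                   n_kept = length(records),
                   artifacts = lapply(paths, basename))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- file.path(out_dir, "manifest.json")

  invisible(list(model = model, gan = gan, embedding = embedding,
                 ontology = onto, eval_train = eval_train,
                 eval_test = eval_test, qc_summary = qc_summary,
                 paths = paths))
}
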