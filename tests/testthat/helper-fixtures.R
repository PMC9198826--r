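# Shared fixtures, all built in code.

# minimal hand-written ontology: two leaves under one category, plus a
# second category with its own leaf, plus a parentless (Western) leaf
tiny_ontology <- function() {
  drug_ontology(data.frame(
    id = c("X", "Y", "x2", "y2", "a", "b", "c", "west"),
    name = c("clearing heat", "nourishing kidney", "formula X", "formula Y",
             "herb a", "herb b", "herb c", "aspirin"),
    level = c("category1", "category1", "category2", "category2",
              "leaf", "leaf", "leaf", "leaf"),
    parent_id = c(NA, NA, "X", "Y", "x2", "x2", "y2", NA)
  ))
}

# random 3-level ontology for property tests
random_ontology <- function(n_cat = 3L, leaves_per = 3L) {
  cfg <- cohort_config(n_patients = 1L, n_category1 = n_cat,
                       leaves_per_category = leaves_per)
  synth_ontology(cfg)
}

# deterministic fake skip-gram model over a fixed vocabulary
fake_embedding <- function(vocab, d = 8L, seed = 1L) {
  vec <- local({
    set.seed(seed)
    matrix(stats::rnorm(length(vocab) * d, 0, 0.5), length(vocab), d,
           dimnames = list(vocab, NULL))
  })
  structure(list(vocab = vocab, vectors = vec,
                 counts = rep(2L, length(vocab)),
                 cfg = embed_config(vector_size = d)),
            class = "skipgram")
}

# a token sequence with chosen tokens and times
make_seq <- function(tokens, t_hours = seq_along(tokens)) {
  structure(list(tokens = tokens, t_hours = as.numeric(t_hours)),
            class = "token_sequence")
}

# random embedding_matrix fixtures for model/gan tests
random_embedding_matrix <- function(k = 8L, d = 4L, n_valid = k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  values <- matrix(stats::rnorm(k * d), k, d)
  mask <- rep(FALSE, k); mask[seq_len(n_valid)] <- TRUE
  values[!mask, ] <- 0
  structure(list(values = values, mask = mask,
                 t_hours = c(seq_len(n_valid), rep(NA, k - n_valid))),
            class = "embedding_matrix")
}

small_cohort <- function(seed = 1L, n = 20L, ...) {
  cfg <- cohort_config(n_patients = n, n_syndromes = 4L, n_category1 = 4L,
                       leaves_per_category = 3L, symptoms_per_syndrome = 3L,
                       facts_per_day = 4, horizon_days = 7L, seed = seed, ...)
  list(cfg = cfg, onto = synth_ontology(cfg),
       records = generate_cohort(cfg, synth_ontology(cfg)))
}
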