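test_that("generated ontology has the configured shape", {
  cfg <- cohort_config(n_category1 = 10L, leaves_per_category = 5L)
  onto <- synth_ontology(cfg)
  expect_equal(onto$n_category1, 10L)
  expect_equal(sum(onto$level == "leaf"), 50L)
  # at hospital scale: 819 first categories x 7 leaves
  cfg2 <- cohort_config(n_category1 = 819L, leaves_per_category = 7L)
  onto2 <- synth_ontology(cfg2)
  expect_equal(sum(onto2$level == "leaf"), 5733L)
  expect_equal(onto2$n_category1, 819L)
})

test_that("same seed gives a byte-identical ontology CSV and cohort", {
  cfg <- cohort_config(n_patients = 5L, seed = 7L)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_drug_ontology(synth_ontology(cfg), f1)
  write_drug_ontology(synth_ontology(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # and the RNG state of the session is untouched
  set.seed(1); before <- .Random.seed
  invisible(generate_cohort(cfg))
  expect_identical(.Random.seed, before)
})

test_that("noiseless single-syndrome prescriptions roll up to the planted rule", {
  cfg <- cohort_config(n_patients = 30L, n_syndromes = 5L, n_category1 = 5L,
                       label_noise = 0, symptom_noise = 0, seed = 3L)
  onto <- synth_ontology(cfg)
  rules <- syndrome_rules(cfg)
  recs <- generate_cohort(cfg, onto, max_syndromes = 1L)
  for (r in recs) {
    target <- sort(unique(unlist(
      lapply(rules[r$latent$syndromes], `[[`, "target_categories"))))
    for (o in r$orders) {
      expect_equal(rollup(onto, o$drug_ids), target)
    }
  }
})

test_that("two order draws may differ in leaves but share a rollup (noiseless)", {
  cfg <- cohort_config(n_patients = 60L, n_syndromes = 3L, n_category1 = 3L,
                       leaves_per_category = 5L, seed = 11L)
  onto <- synth_ontology(cfg)
  recs <- generate_cohort(cfg, onto, max_syndromes = 1L)
  # orders at different times of one patient are independent leaf draws
  differing <- 0L
  for (r in recs) {
    d1 <- sort(r$orders[[1]]$drug_ids); d2 <- sort(r$orders[[2]]$drug_ids)
    expect_equal(rollup(onto, d1), rollup(onto, d2))
    if (!identical(d1, d2)) differing <- differing + 1L
  }
  expect_gt(differing, 0L)  # physician substitution actually happens
})

test_that("facts carry timestamps within the stay horizon", {
  ch <- small_cohort(seed = 9L)
  for (r in ch$records) {
    expect_true(all(r$facts$t_hours >= 0))
    expect_true(all(r$facts$t_hours <= ch$cfg$horizon_days * 24))
  }
})

test_that("corrupt_records flags a binomial fraction with one defect each", {
  cfg <- cohort_config(n_patients = 100L, n_syndromes = 4L, n_category1 = 4L,
                       qc_corrupt_frac = 0.25, seed = 21L)
  onto <- synth_ontology(cfg)
  recs <- generate_cohort(cfg, onto)
  out <- corrupt_records(recs, cfg)
  k <- length(attr(out, "defective"))
  # 99% binomial interval for n=100, p=0.25
  expect_gte(k, qbinom(0.005, 100, 0.25))
  expect_lte(k, qbinom(0.995, 100, 0.25))
  # every defective record trips exactly one discard reason
  qc <- qc_filter(out)
  expect_equal(length(qc$discarded), k)
  expect_true(all(qc$reasons %in% c("incomplete", "inconsistent",
                                    "nonstandard", "special_circumstance")))
  # zero fraction is the identity
  cfg0 <- cohort_config(n_patients = 100L, n_syndromes = 4L, n_category1 = 4L,
                        qc_corrupt_frac = 0, seed = 21L)
  out0 <- corrupt_records(recs, cfg0)
  attr(out0, "defective") <- NULL
  expect_identical(out0, recs)
})

test_that("records survive a JSONL round trip", {
  ch <- small_cohort(seed = 13L, n = 4L)
  tf <- withr::local_tempfile(fileext = ".jsonl")
  write_records_jsonl(ch$records, tf)
  back <- read_records_jsonl(tf)
  expect_length(back, 4L)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$patient_id, ch$records[[i]]$patient_id)
    expect_equal(back[[i]]$demographics, ch$records[[i]]$demographics)
    expect_identical(extract_tokens(back[[i]], 48)$tokens,
                     extract_tokens(ch$records[[i]], 48)$tokens)
  }
})
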