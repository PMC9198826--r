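test_that("qc_filter keeps clean cohorts and tags discard reasons", {
  ch <- small_cohort(seed = 2L)
  qc <- qc_filter(ch$records)
  expect_length(qc$kept, length(ch$records))
  expect_length(qc$discarded, 0L)

  r <- ch$records[[1]]
  r$demographics$age <- NA
  expect_equal(qc_filter(list(r))$reasons, "incomplete")

  r2 <- ch$records[[2]]
  r2$facts <- rbind(r2$facts, data.frame(t_hours = 0, section = "treatment_process",
                                         name = "special_circumstance",
                                         value = "chemotherapy", unit = NA))
  expect_equal(qc_filter(list(r2))$reasons, "special_circumstance")

  r3 <- ch$records[[3]]
  r3$facts$value[r3$facts$name == "tongue_coating"] <- "mixed up value!"
  expect_equal(qc_filter(list(r3))$reasons, "nonstandard")

  r4 <- ch$records[[4]]
  dup <- r4$facts[r4$facts$name == "tongue_coating", ][1, ]
  dup$value <- "coat_99"
  r4$facts <- rbind(r4$facts, dup)
  expect_equal(qc_filter(list(r4))$reasons, "inconsistent")

  # idempotent
  qc2 <- qc_filter(qc$kept)
  expect_identical(qc2$kept, qc$kept)
})

test_that("extract_tokens truncates at the cutoff and counts tokens", {
  ch <- small_cohort(seed = 4L)
  r <- ch$records[[1]]
  s0 <- extract_tokens(r, 0, include_prior_orders = FALSE)
  expect_true(all(s0$t_hours <= 0))
  # full record: demographics (5) + 1-3 tokens per fact
  sInf <- extract_tokens(r, Inf, include_prior_orders = FALSE)
  per_fact <- 1L + (!is.na(r$facts$value)) + (!is.na(r$facts$unit))
  expect_length(sInf$tokens, 5L + sum(per_fact))
  expect_false(is.unsorted(sInf$t_hours))
  # the order issued at the cutoff is never in its own input
  s24 <- extract_tokens(r, 24)
  expect_false(any(grepl("^rx_", s24$tokens) & s24$t_hours > 24))
  expect_true(any(startsWith(s24$tokens, "rx_")))     # admission order visible
  expect_false(any(startsWith(extract_tokens(r, 0)$tokens, "rx_")))
})

test_that("simultaneous facts are ordered by section listing order, then name", {
  rec <- list(
    patient_id = "T1",
    demographics = list(sex = "female", age = 40, height = 160,
                        weight = 55, bmi = 21.5),
    facts = data.frame(
      t_hours = c(5, 5, 5, 0),
      section = c("laboratory_reports", "chief_complaints", "nursing_notes", "body_check"),
      name = c("lab_01", "zz_sym", "heart_rate", "temperature"),
      value = c("25", NA, "80", "36.5"),
      unit = c("U_L", NA, "bpm", "C")),
    orders = list())
  s <- extract_tokens(rec)
  # oracle: stable sort on (t, section rank, name)
  at5 <- s$tokens[s$t_hours == 5]
  expect_equal(at5, c("zz_sym", "heart_rate", "heart_rate_normal", "u_bpm",
                      "lab_01", "lab_01_high", "u_U_L"))
  expect_error(extract_tokens(list(patient_id = "x",
                                   demographics = rec$demographics,
                                   facts = transform(rec$facts, section = "bogus"),
                                   orders = list())),
               "unknown section")
})

test_that("numeric values bin against reference ranges", {
  rec <- list(patient_id = "T2",
              demographics = list(sex = "male", age = 70, height = 145,
                                  weight = 70, bmi = 22),
              facts = data.frame(t_hours = 0, section = "body_check",
                                 name = "temperature", value = "39.0", unit = "C"),
              orders = list())
  s <- extract_tokens(rec)
  expect_true("temperature_high" %in% s$tokens)
  expect_true("age_high" %in% s$tokens)     # 70 is above the adult range
  expect_true("height_low" %in% s$tokens)
})

test_that("earlier cutoffs give prefixes of later cutoffs", {
  ch <- small_cohort(seed = 6L)
  cuts <- c(0, 24, 48, 72, 168, Inf)
  for (r in ch$records[1:8]) {
    seqs <- lapply(cuts, function(co) extract_tokens(r, co))
    for (i in seq_len(length(cuts) - 1L)) {
      a <- seqs[[i]]$tokens; b <- seqs[[i + 1L]]$tokens
      expect_lte(length(a), length(b))
      expect_identical(a, b[seq_along(a)])
    }
  }
})
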