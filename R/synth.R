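# Synthetic inpatient cohort generator.
#
# Real hospital corpora of this kind are proprietary, so the package ships a
# generator with the statistical structure the model assumes: each patient
# carries 1-3 latent TCM syndromes; a syndrome emits its characteristic
# symptom tokens at admission and abnormal laboratory values over the stay;
# the reference prescription at each order time contains, per target
# category, one uniformly chosen leaf drug of that category (two physicians
# may pick different herbs of the same parent category).

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients Number of patients to simulate.
#' @param n_syndromes Number of latent syndromes. Each syndrome is mapped
#'   injectively (cycling) onto a first category, emits
#'   `symptoms_per_syndrome` unique symptom tokens at admission, and has one
#'   distinctive laboratory analyte that runs high during the stay.
#' @param n_category1 Number of first-category medicines (the label space).
#' @param leaves_per_category Leaf drugs per first category (via one
#'   category-II node each).
#' @param symptoms_per_syndrome Symptom tokens emitted by each syndrome.
#' @param facts_per_day Expected number of time-stamped facts (labs, vitals)
#'   per day of stay (Poisson rate).
#' @param horizon_days Length of stay in days; all facts fall in
#'   `[0, 24 * horizon_days]` hours.
#' @param label_noise Probability that a target category in an order is
#'   swapped for a uniformly random other category.
#' @param symptom_noise Probability, per true symptom token, of additionally
#'   injecting one spurious symptom from an unrelated syndrome at admission.
#' @param qc_corrupt_frac Fraction of records given a quality-control defect
#'   by [corrupt_records()].
#' @param seed Integer seed; fixed seed reproduces the cohort exactly.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 500L, n_syndromes = 10L,
                          n_category1 = 10L, leaves_per_category = 5L,
                          symptoms_per_syndrome = 4L, facts_per_day = 6,
                          horizon_days = 7L, label_noise = 0,
                          symptom_noise = 0, qc_corrupt_frac = 0,
                          seed = 1L) {
  cfg <- list(
    n_patients = assert_count(n_patients, "n_patients"),
    n_syndromes = assert_count(n_syndromes, "n_syndromes"),
    n_category1 = assert_count(n_category1, "n_category1"),
    leaves_per_category = assert_count(leaves_per_category, "leaves_per_category"),
    symptoms_per_syndrome = assert_count(symptoms_per_syndrome, "symptoms_per_syndrome"),
    facts_per_day = facts_per_day,
    horizon_days = assert_count(horizon_days, "horizon_days"),
    label_noise = assert_prob(label_noise, "label_noise"),
    symptom_noise = assert_prob(symptom_noise, "symptom_noise"),
    qc_corrupt_frac = assert_prob(qc_corrupt_frac, "qc_corrupt_frac"),
    seed = as.integer(seed)
  )
  if (!is.numeric(facts_per_day) || facts_per_day < 0)
    stopf("`facts_per_day` must be a non-negative rate")
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate the synthetic drug ontology
#'
#' Builds a three-level hierarchy with `n_category1` first-category nodes,
#' one category-II node per first category, and `leaves_per_category` leaf
#' herbs under each category-II node. Fully deterministic (node ids and
#' names are derived from indices), so the same configuration always yields
#' a byte-identical CSV.
#'
#' @param cfg A [cohort_config()].
#' @return A [drug_ontology].
#' @export
synth_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  k <- cfg$n_category1
  m <- cfg$leaves_per_category
  cat1 <- data.frame(id = sprintf("cat1_%03d", seq_len(k)),
                     name = sprintf("first category %d", seq_len(k)),
                     level = "category1", parent_id = NA_character_)
  cat2 <- data.frame(id = sprintf("cat2_%03d", seq_len(k)),
                     name = sprintf("formula family %d", seq_len(k)),
                     level = "category2", parent_id = cat1$id)
  grid <- expand.grid(j = seq_len(m), i = seq_len(k))
  leaves <- data.frame(id = sprintf("herb_%03d_%02d", grid$i, grid$j),
                       name = sprintf("herb %d.%d", grid$i, grid$j),
                       level = "leaf",
                       parent_id = sprintf("cat2_%03d", grid$i))
  drug_ontology(rbind(cat1, cat2, leaves))
}

#' Latent syndrome rules of a configuration
#'
#' Syndrome `s` targets first category `((s - 1) %% n_category1) + 1`
#' (injective when `n_syndromes <= n_category1`, so the planted mapping is
#' identifiable), emits symptom tokens `sym_<s>_<1..k>`, and elevates the
#' analyte `lab_<s>`.
#'
#' @param cfg A [cohort_config()].
#' @return List of per-syndrome rules, each with `syndrome_id`, `symptoms`,
#'   `target_categories` and `lab`.
#' @export
syndrome_rules <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  lapply(seq_len(cfg$n_syndromes), function(s) {
    list(
      syndrome_id = s,
      symptoms = sprintf("sym_%02d_%02d", s, seq_len(cfg$symptoms_per_syndrome)),
      target_categories = sprintf("cat1_%03d", ((s - 1L) %% cfg$n_category1) + 1L),
      lab = sprintf("lab_%02d", s)
    )
  })
}

# Reference ranges shared by the generator (draws values in/out of range)
# and the featurizer (bins values into low/normal/high). Synthetic lab
# analytes follow the generic lab_* range.
ref_range <- function(name) {
  fixed <- list(
    temperature = c(36.1, 37.2), heart_rate = c(60, 100),
    systolic_bp = c(90, 140), respiration = c(12, 20),
    age = c(18, 65), height = c(150, 185), weight = c(50, 90),
    bmi = c(18.5, 25)
  )
  if (name %in% names(fixed)) return(fixed[[name]])
  if (grepl("^lab_", name)) return(c(10, 20))
  NULL
}

vital_units <- c(temperature = "C", heart_rate = "bpm",
                 systolic_bp = "mmHg", respiration = "per_min")

fact_row <- function(t, section, name, value = NA, unit = NA) {
  data.frame(t_hours = t, section = section, name = name,
             value = ifelse(is.na(value), NA_character_, as.character(value)),
             unit = ifelse(is.na(unit), NA_character_, as.character(unit)),
             stringsAsFactors = FALSE)
}

fmt_num <- function(x) sprintf("%.4f", x)

# One patient's record given their latent syndromes.
simulate_patient <- function(cfg, onto, rules, leaves_by_cat, pid, synd) {
  sex <- sample(c("male", "female"), 1L)
  age <- round(stats::runif(1, 25, 85))
  height <- round(stats::rnorm(1, if (sex == "male") 172 else 160, 7), 1)
  weight <- round(stats::rnorm(1, 70, 12), 1)
  bmi <- round(weight / (height / 100)^2, 1)
  demog <- list(sex = sex, age = age, height = height, weight = weight, bmi = bmi)

  primary <- synd[1L]
  facts <- list()
  # Chief complaints at admission: every active syndrome's symptom tokens,
  # plus spurious confusers under symptom_noise.
  for (s in synd) {
    for (sym in rules[[s]]$symptoms) {
      facts[[length(facts) + 1L]] <- fact_row(0, "chief_complaints", sym)
      if (cfg$symptom_noise > 0 && stats::runif(1) < cfg$symptom_noise) {
        other <- setdiff(seq_along(rules), synd)
        if (length(other)) {
          o <- if (length(other) == 1L) other else sample(other, 1L)
          spur <- rules[[o]]$symptoms
          facts[[length(facts) + 1L]] <-
            fact_row(0, "chief_complaints",
                     if (length(spur) == 1L) spur else sample(spur, 1L))
        }
      }
    }
  }
  # Tongue and pulse findings reflect the primary syndrome only.
  facts[[length(facts) + 1L]] <-
    fact_row(0, "present_illness", "tongue_coating", sprintf("coat_%02d", primary))
  facts[[length(facts) + 1L]] <-
    fact_row(0, "present_illness", "pulse_quality", sprintf("pulse_%02d", primary))
  # Admission vitals: in-range filler common to all patients.
  for (v in names(vital_units)) {
    r <- ref_range(v)
    facts[[length(facts) + 1L]] <-
      fact_row(0, "body_check", v, fmt_num(stats::runif(1, r[1], r[2])),
               vital_units[[v]])
  }
  # Time-stamped facts over the stay: syndrome labs run high, generic
  # vitals stay in range.
  n_facts <- stats::rpois(1, cfg$facts_per_day * cfg$horizon_days)
  if (n_facts > 0) {
    times <- sort(stats::runif(n_facts, 0, cfg$horizon_days * 24))
    for (t in times) {
      if (stats::runif(1) < 0.6) {
        s <- if (length(synd) == 1L) synd else sample(synd, 1L)
        r <- ref_range(rules[[s]]$lab)
        facts[[length(facts) + 1L]] <-
          fact_row(t, "laboratory_reports", rules[[s]]$lab,
                   fmt_num(stats::runif(1, r[2] * 1.1, r[2] * 1.6)), "U_L")
      } else {
        v <- sample(names(vital_units), 1L)
        r <- ref_range(v)
        facts[[length(facts) + 1L]] <-
          fact_row(t, "nursing_notes", v, fmt_num(stats::runif(1, r[1], r[2])),
                   vital_units[[v]])
      }
    }
  }
  facts <- do.call(rbind, facts)
  facts <- facts[order(facts$t_hours), , drop = FALSE]
  rownames(facts) <- NULL

  # Reference prescriptions at the standard order times within the horizon.
  all_cats <- category_ids(onto)
  target <- unique(unlist(lapply(rules[synd], `[[`, "target_categories")))
  order_times <- c(0, 24, 48, 72, 168)
  order_times <- order_times[order_times <= cfg$horizon_days * 24]
  orders <- lapply(order_times, function(t) {
    cats <- vapply(target, function(cc) {
      if (cfg$label_noise > 0 && stats::runif(1) < cfg$label_noise) {
        pool <- setdiff(all_cats, cc)
        if (length(pool) == 1L) pool else sample(pool, 1L)
      } else cc
    }, character(1))
    drugs <- vapply(unique(cats), function(cc) {
      lv <- leaves_by_cat[[cc]]
      if (length(lv) == 1L) lv else sample(lv, 1L)
    }, character(1))
    list(t_hours = t, drug_ids = unname(drugs))
  })

  list(patient_id = pid, demographics = demog, facts = facts,
       orders = orders, latent = list(syndromes = synd))
}

#' Generate a synthetic cohort
#'
#' Draws `n_patients` records under the latent-syndrome model described in
#' [cohort_config()]. With `label_noise = 0` and one syndrome per patient,
#' every reference prescription's category rollup equals the syndrome's
#' target categories exactly; fixed seeds reproduce the cohort.
#'
#' @param cfg A [cohort_config()].
#' @param onto Ontology from [synth_ontology()] (regenerated if omitted).
#' @param max_syndromes Upper bound on syndromes per patient (1-3 by
#'   default, as admissions typically present one primary and up to two
#'   secondary patterns).
#' @return List of patient records. Each record is a list with
#'   `patient_id`, `demographics`, `facts` (data.frame with columns
#'   `t_hours`, `section`, `name`, `value`, `unit`), `orders` (list of
#'   `t_hours` + `drug_ids`) and `latent` (ground-truth syndromes, for
#'   evaluation only — the featurizer never reads it).
#' @export
generate_cohort <- function(cfg, onto = NULL, max_syndromes = 3L) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (is.null(onto)) onto <- synth_ontology(cfg)
  rules <- syndrome_rules(cfg)
  leaves_by_cat <- category_leaves(onto)
  local_seed(cfg$seed, {
    lapply(seq_len(cfg$n_patients), function(i) {
      k <- sample(seq_len(min(max_syndromes, cfg$n_syndromes)), 1L)
      synd <- sort(sample(cfg$n_syndromes, k))
      simulate_patient(cfg, onto, rules, leaves_by_cat,
                       sprintf("P%05d", i), synd)
    })
  })
}

QC_DEFECTS <- c("incomplete", "inconsistent", "nonstandard", "special_circumstance")

#' Inject quality-control defects into records
#'
#' Flags each record independently with probability `cfg$qc_corrupt_frac`
#' and gives every flagged record exactly one of the four discard
#' conditions recognised by [qc_filter()]: a missing demographic field, an
#' inconsistent duplicated fact, a nonstandard token, or a
#' special-circumstance marker (chemotherapy, post-operation, fracture
#' setting).
#'
#' @param records Cohort from [generate_cohort()].
#' @param cfg A [cohort_config()]; uses `qc_corrupt_frac` and `seed`.
#' @return The records, with defects applied; the integer attribute
#'   `"defective"` lists the corrupted indices.
#' @export
corrupt_records <- function(records, cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$qc_corrupt_frac == 0) {
    attr(records, "defective") <- integer()
    return(records)
  }
  local_seed(cfg$seed + 104729L, {
    flag <- which(stats::runif(length(records)) < cfg$qc_corrupt_frac)
    for (i in flag) {
      defect <- sample(QC_DEFECTS, 1L)
      r <- records[[i]]
      if (defect == "incomplete") {
        r$demographics[[sample(names(r$demographics), 1L)]] <- NA
      } else if (defect == "inconsistent") {
        cand <- which(!is.na(r$facts$value))
        j <- if (length(cand) == 1L) cand else sample(cand, 1L)
        dup <- r$facts[j, , drop = FALSE]
        dup$value <- paste0(dup$value, "_conflict")
        r$facts <- rbind(r$facts, dup)
        r$facts <- r$facts[order(r$facts$t_hours), , drop = FALSE]
        rownames(r$facts) <- NULL
      } else if (defect == "nonstandard") {
        r$facts <- rbind(r$facts,
                         fact_row(0, "chief_complaints", "?? unrecognised term !!"))
      } else {
        r$facts <- rbind(
          r$facts,
          fact_row(0, "treatment_process", "special_circumstance",
                   sample(c("chemotherapy", "post_operation", "fracture_setting"), 1L)))
      }
      records[[i]] <- r
    }
    attr(records, "defective") <- flag
    records
  })
}

#' Write patient records as JSON Lines
#'
#' One patient per line:
#' `{"patient_id", "demographics", "facts": [...], "orders": [...]}`.
#'
#' @param records Cohort list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records_jsonl <- function(records, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in records) {
    out <- list(patient_id = r$patient_id, demographics = r$demographics,
                facts = r$facts, orders = r$orders)
    if (!is.null(r$latent)) out$latent <- r$latent
    writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = 8,
                                na = "null", dataframe = "rows"), con)
  }
  invisible(path)
}

#' Read patient records from JSON Lines
#'
#' @param path Path to a JSONL file written by [write_records_jsonl()].
#' @return List of patient records.
#' @export
read_records_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE, simplifyDataFrame = TRUE)
    facts <- x$facts
    if (is.null(facts) || (is.data.frame(facts) && nrow(facts) == 0)) {
      facts <- fact_row(numeric(), character(), character())[0, ]
    }
    for (col in c("value", "unit")) {
      if (!col %in% names(facts)) facts[[col]] <- NA_character_
      facts[[col]] <- as.character(facts[[col]])
    }
    orders <- x$orders
    if (is.data.frame(orders)) {
      orders <- lapply(seq_len(nrow(orders)), function(i)
        list(t_hours = orders$t_hours[i],
             drug_ids = unlist(orders$drug_ids[i])))
    }
    out <- list(patient_id = x$patient_id,
                demographics = as.list(x$demographics),
                facts = facts, orders = orders)
    if (!is.null(x$latent)) out$latent <- lapply(x$latent, unlist)
    out
  })
}
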