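# Quality-control filtering and record -> token-sequence conversion.

#' Chart sections recognised by the featurizer, in canonical order
#'
#' The eleven section kinds of a structured inpatient chart. The listing
#' order is also the tie-breaking order for facts sharing a timestamp.
#'
#' @return Character vector of section identifiers.
#' @export
box1_sections <- function() {
  c("demography", "chief_complaints", "recent_medical_history",
    "past_medical_history", "present_illness", "body_check",
    "treatment_process", "physician_orders", "nursing_notes",
    "examination_reports", "laboratory_reports")
}

# Tokens must come from the standardized registry; anything with characters
# outside this set is a nonstandard description.
STANDARD_TOKEN_RE <- "^[A-Za-z0-9_.:=-]+$"

qc_reason <- function(record) {
  d <- record$demographics
  need <- c("sex", "age", "height", "weight", "bmi")
  if (any(!need %in% names(d)) ||
      any(vapply(need, function(k) is.null(d[[k]]) || is.na(d[[k]]), logical(1))))
    return("incomplete")
  f <- record$facts
  if (is.null(f) || nrow(f) == 0 || !any(f$t_hours <= 0))
    return("incomplete")
  if (any(f$name == "special_circumstance"))
    return("special_circumstance")
  bad <- !grepl(STANDARD_TOKEN_RE, f$name) |
    (!is.na(f$value) & !grepl(STANDARD_TOKEN_RE, f$value))
  if (any(bad)) return("nonstandard")
  key <- paste(f$t_hours, f$section, f$name, sep = "\r")
  vals <- split(f$value, key)
  if (any(vapply(vals, function(v) length(unique(v[!is.na(v)])) > 1L, logical(1))))
    return("inconsistent")
  NA_character_
}

#' Quality-control filter for patient records
#'
#' Discards records that would have been excluded at chart review: charts
#' missing basic pages (demographics or admission-time facts), charts with
#' inconsistent duplicated information, charts using nonstandard
#' descriptions, and charts carrying a special-circumstance marker such as
#' chemotherapy. Filtering is idempotent.
#'
#' @param records List of patient records.
#' @return List with `kept` (clean records), `discarded` (the rest) and
#'   `reasons` (character vector parallel to `discarded`, each one of
#'   `"incomplete"`, `"inconsistent"`, `"nonstandard"`,
#'   `"special_circumstance"`).
#' @export
qc_filter <- function(records) {
  reasons <- vapply(records, qc_reason, character(1))
  bad <- !is.na(reasons)
  list(kept = records[!bad], discarded = records[bad],
       reasons = unname(reasons[bad]))
}

bin_value <- function(name, value) {
  if (is.na(value)) return(NA_character_)
  r <- ref_range(name)
  num <- suppressWarnings(as.numeric(value))
  if (is.null(r) || is.na(num)) return(as.character(value))
  if (num < r[1]) "low" else if (num > r[2]) "high" else "normal"
}

# Prior orders are featurized as medicines taken; administration follows the
# order by a small lag so that the order being predicted at a cutoff is
# never part of its own input, and so that sequences remain prefixes of one
# another as the cutoff grows.
ORDER_LAG_HOURS <- 1e-3

#' Convert a patient record into a chronological token sequence
#'
#' Emits demographics first (at time 0), then every clinical fact with
#' `t_hours <= cutoff_hours` as 1-3 tokens: the fact name, the value binned
#' into low/normal/high against reference ranges (non-numeric values are
#' kept verbatim, prefixed by the name), and the unit. Prescriptions issued
#' strictly before the cutoff are included as medicines-taken tokens
#' (`rx_<drug id>`); the order at the cutoff itself — the prediction target
#' — is excluded. Tokens are sorted by time, ties broken by section order
#' as listed in [box1_sections()], then by name.
#'
#' @param record A patient record (see [generate_cohort()] for the shape).
#' @param cutoff_hours Evaluation time slice in hours since admission
#'   (`Inf` for the full record). The conventional slices are 0 (admission),
#'   24, 48, 72 and 168.
#' @param include_prior_orders Feed previously issued prescriptions back as
#'   input tokens (default `TRUE`).
#' @return An object of class `token_sequence`: list with parallel `tokens`
#'   (character) and `t_hours` (non-decreasing numeric).
#' @export
extract_tokens <- function(record, cutoff_hours = Inf,
                           include_prior_orders = TRUE) {
  if (!is.numeric(cutoff_hours) || length(cutoff_hours) != 1L ||
      is.na(cutoff_hours) || cutoff_hours < 0)
    stopf("`cutoff_hours` must be a single number >= 0")
  sections <- box1_sections()

  toks <- character(); times <- numeric(); sect <- character()
  nm <- character(); sub <- integer()
  push <- function(t, section, name, token, k) {
    toks[[length(toks) + 1L]] <<- token
    times[[length(times) + 1L]] <<- t
    sect[[length(sect) + 1L]] <<- section
    nm[[length(nm) + 1L]] <<- name
    sub[[length(sub) + 1L]] <<- k
  }

  d <- record$demographics
  push(0, "demography", "sex", paste0("sex_", d$sex), 1L)
  for (v in c("age", "height", "weight", "bmi"))
    push(0, "demography", v, paste0(v, "_", bin_value(v, d[[v]])), 1L)

  f <- record$facts
  if (!is.null(f) && nrow(f)) {
    unknown <- setdiff(unique(f$section), sections)
    if (length(unknown))
      stopf("unknown section(s): %s", paste(unknown, collapse = ", "))
    keep <- f$t_hours <= cutoff_hours
    f <- f[keep, , drop = FALSE]
    for (i in seq_len(nrow(f))) {
      push(f$t_hours[i], f$section[i], f$name[i], f$name[i], 1L)
      if (!is.na(f$value[i])) {
        b <- bin_value(f$name[i], f$value[i])
        push(f$t_hours[i], f$section[i], f$name[i],
             paste0(f$name[i], "_", b), 2L)
      }
      if (!is.na(f$unit[i]))
        push(f$t_hours[i], f$section[i], f$name[i],
             paste0("u_", f$unit[i]), 3L)
    }
  }

  if (include_prior_orders && length(record$orders)) {
    for (o in record$orders) {
      t_eff <- o$t_hours + ORDER_LAG_HOURS
      if (t_eff <= cutoff_hours) {
        for (drug in o$drug_ids)
          push(t_eff, "physician_orders", drug, paste0("rx_", drug), 1L)
      }
    }
  }

  ord <- order(times, match(sect, sections), nm, sub, method = "radix")
  structure(list(tokens = toks[ord], t_hours = times[ord]),
            class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat("<token_sequence> ", length(x$tokens), " tokens, t in [",
      if (length(x$t_hours)) min(x$t_hours) else NA, ", ",
      if (length(x$t_hours)) max(x$t_hours) else NA, "] h\n", sep = "")
  if (length(x$tokens))
    cat(" ", paste(utils::head(x$tokens, 8), collapse = " "),
        if (length(x$tokens) > 8) "..." else "", "\n")
  invisible(x)
}
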