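# Rollup-based prescription matching, precision/recall, and time-sliced
# evaluation reports.
#
# A recommended drug counts as correct when it belongs to the same parent
# category as a drug in the physician's prescription, so both sets are
# rolled up to first categories before counting. True positives are the
# categories present in both rolled-up sets; false positives those only in
# the machine's; false negatives those only in the physician's.

#' Rolled-up match counts between two prescriptions
#'
#' @param onto A [drug_ontology].
#' @param predicted Character vector of drug ids recommended by the model
#'   (may already be category ids — rollup is idempotent).
#' @param reference Character vector of drug ids in the physician's order.
#' @param level Rollup level, as in [rollup()].
#' @return Named integer vector `c(tp, fp, fn)` of class `match_counts`.
#' @export
match_counts <- function(onto, predicted, reference,
                         level = c("category1", "category2")) {
  level <- match.arg(level)
  p <- rollup(onto, predicted, level)
  r <- rollup(onto, reference, level)
  structure(c(tp = length(intersect(p, r)),
              fp = length(setdiff(p, r)),
              fn = length(setdiff(r, p))),
            class = "match_counts")
}

#' Precision and recall from match counts
#'
#' Precision = TP / (TP + FP); recall = TP / (TP + FN). An empty
#' denominator scores 1: a model that recommends nothing when nothing is
#' due is perfect, not undefined.
#'
#' @param counts Anything with named elements `tp`, `fp`, `fn` (e.g. a
#'   [match_counts()] result, possibly summed over patients).
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  fn <- as.numeric(counts[["fn"]])
  if (any(c(tp, fp, fn) < 0)) stopf("counts must be non-negative")
  c(precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn))
}

#' Time-sliced evaluation against reference orders
#'
#' For each evaluation cutoff, each patient's chart is truncated at the
#' cutoff, tokenised, vectorised and classified; the decoded category set
#' is matched against the rollup of the reference order issued at that
#' cutoff. Patients lacking a reference order at a cutoff are skipped (and
#' counted in `n_skipped`). Counts are micro-aggregated (summed over
#' patients before dividing) by default; `agg = "macro"` averages
#' per-patient precision/recall instead.
#'
#' @param model A fitted [fit_transformer()] whose label ids are category
#'   ids of `onto`.
#' @param records Patient records.
#' @param onto A [drug_ontology].
#' @param embedding A [skipgram] model for [vectorize()].
#' @param cutoffs Evaluation times in hours (default: admission, 24 h,
#'   48 h, 72 h, 1 week).
#' @param threshold Decoding threshold (default: the model's).
#' @param agg `"micro"` or `"macro"`.
#' @param level Rollup level for matching.
#' @param include_prior_orders Passed to [extract_tokens()].
#' @return A data.frame of class `timeline_eval` with one row per cutoff:
#'   `cutoff_hours`, `n`, `n_skipped`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`.
#' @export
evaluate_timeline <- function(model, records, onto, embedding,
                              cutoffs = c(0, 24, 48, 72, 168),
                              threshold = NULL, agg = c("micro", "macro"),
                              level = c("category1", "category2"),
                              include_prior_orders = TRUE) {
  stopifnot(inherits(model, "tcm_transformer"))
  agg <- match.arg(agg); level <- match.arg(level)
  threshold <- threshold %||% model$config$decode_threshold
  cap <- model$config$max_num_tokens

  rows <- lapply(cutoffs, function(co) {
    tp <- fp <- fn <- 0L; n <- 0L; skipped <- 0L
    pr_acc <- c(0, 0)
    for (r in records) {
      ref <- NULL
      for (o in r$orders)
        if (isTRUE(all.equal(o$t_hours, co))) { ref <- o$drug_ids; break }
      if (is.null(ref)) { skipped <- skipped + 1L; next }
      seq <- extract_tokens(r, co, include_prior_orders = include_prior_orders)
      em <- vectorize(seq, embedding, cap)
      probs <- transformer_fwd(model$params, model$config, em)$probs
      pred <- model$label_ids[decode(probs, threshold)]
      mc <- match_counts(onto, pred, ref, level)
      tp <- tp + mc[["tp"]]; fp <- fp + mc[["fp"]]; fn <- fn + mc[["fn"]]
      pr_acc <- pr_acc + precision_recall(mc)
      n <- n + 1L
    }
    pr <- if (agg == "micro") precision_recall(c(tp = tp, fp = fp, fn = fn))
          else if (n > 0) pr_acc / n else c(precision = NA_real_, recall = NA_real_)
    data.frame(cutoff_hours = co, n = n, n_skipped = skipped,
               tp = tp, fp = fp, fn = fn,
               precision = unname(pr[1]), recall = unname(pr[2]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("timeline_eval", "data.frame")
  attr(out, "agg") <- agg
  out
}

slice_label <- function(h) {
  if (h == 0) "Admission"
  else if (h < 72) sprintf("In %d hours", as.integer(h))
  else if (h < 168) sprintf("In %d days", as.integer(h / 24))
  else if (h == 168) "In 1 week"
  else sprintf("In %d weeks", as.integer(round(h / 168)))
}

#' @export
print.timeline_eval <- function(x, ...) {
  cat(sprintf("Time-sliced evaluation (%s-averaged)\n", attr(x, "agg") %||% "micro"))
  cat(sprintf("%-14s %6s %14s %12s\n", "Time", "n", "Precision (%)", "Recall (%)"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-14s %6d %14.2f %12.2f\n",
                slice_label(x$cutoff_hours[i]), x$n[i],
                100 * x$precision[i], 100 * x$recall[i]))
  }
  if (any(x$n_skipped > 0))
    cat(sprintf("(%d patient-cutoff cells skipped: no reference order)\n",
                sum(x$n_skipped)))
  invisible(x)
}
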