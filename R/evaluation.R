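# Quality-control evaluation: sample patients, compare predicted profiles
# against gold labels, and compute per-domain precision/recall/F1.

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * p * r / (p + r)`; symmetric in its arguments and never
#' above `max(p, r)`.  When both precision and recall are 0 the score is
#' defined as 0 (flagged degenerate rather than producing `NaN`).
#'
#' @param precision,recall fractions in `[0, 1]` (vectorized).
#' @return Numeric F1 in `[0, 1]`.
#' @export
#' @examples
#' f1_score(0.6, 0.9)
f1_score <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1, na.rm = TRUE),
            all(recall >= 0 & recall <= 1, na.rm = TRUE))
  denom <- precision + recall
  ifelse(is.na(denom) | denom == 0, 0, 2 * precision * recall / denom)
}

#' Draw the quality-control patient sample
#'
#' Simple random sample without replacement, reproducible under the seed.
#' The caller's RNG state is left untouched.
#'
#' @param patient_ids character vector (or a `cog_profiles` object, whose
#'   roster is used).
#' @param n sample size; must not exceed the population size.
#' @param seed integer seed.
#' @return Character vector of sampled patient ids.
#' @export
sample_qc_patients <- function(patient_ids, n, seed = 1L) {
  if (inherits(patient_ids, "cog_profiles"))
    patient_ids <- patient_ids$profiles$patient_id
  patient_ids <- as.character(patient_ids)
  if (n > length(patient_ids))
    stop_cogehr("QC sample size %d exceeds population size %d",
                n, length(patient_ids))
  with_local_seed(seed, sample(patient_ids, n))
}

#' Score predicted impairment profiles against gold labels
#'
#' Patient-level confusion counts per domain (the scoring unit is the
#' patient-domain pair), plus an overall any-impairment row.  Precision with
#' `tp + fp = 0` (or recall with `tp + fn = 0`) is reported as `NA` and
#' flagged, never fabricated; F1 is then 0 with the flag set.
#'
#' @param pred a `cog_profiles` object (or its `profiles` data frame with
#'   domain flag columns and `any_impairment`).
#' @param gold gold-label data frame with `patient_id`, `impaired`, and
#'   `domains` (semicolon-joined domain ids), as emitted by
#'   [generate_dataset()].
#' @param subset patient ids to score (default: everyone in `pred`).
#' @return Data frame with one row per domain plus `"any"`: `tp`, `fp`,
#'   `fn`, `tn`, `precision`, `recall`, `f1`, `precision_defined`,
#'   `recall_defined`.
#' @export
score_domains <- function(pred, gold, subset = NULL) {
  p <- if (inherits(pred, "cog_profiles")) pred$profiles else pred
  if (is.null(subset)) subset <- p$patient_id
  subset <- as.character(subset)
  miss <- setdiff(subset, p$patient_id)
  if (length(miss))
    stop_cogehr("patient(s) missing from predictions: %s",
                paste(utils::head(miss, 5), collapse = ", "))
  miss <- setdiff(subset, gold$patient_id)
  if (length(miss))
    stop_cogehr("patient(s) missing from gold labels: %s",
                paste(utils::head(miss, 5), collapse = ", "))
  p <- p[match(subset, p$patient_id), , drop = FALSE]
  g <- gold[match(subset, gold$patient_id), , drop = FALSE]
  gold_dom <- strsplit(ifelse(is.na(g$domains), "", g$domains), ";",
                       fixed = TRUE)

  rows <- list()
  for (d in c(cog_domains(), "any")) {
    pred_f <- if (d == "any") p$any_impairment else p[[d]]
    gold_f <- if (d == "any") g$impaired
              else vapply(gold_dom, function(x) d %in% x, logical(1))
    tp <- sum(pred_f & gold_f); fp <- sum(pred_f & !gold_f)
    fn <- sum(!pred_f & gold_f); tn <- sum(!pred_f & !gold_f)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (is.na(prec) || is.na(rec)) 0 else f1_score(prec, rec)
    rows[[d]] <- data.frame(
      domain = d, tp = tp, fp = fp, fn = fn, tn = tn,
      precision = prec, recall = rec, f1 = f1,
      precision_defined = tp + fp > 0, recall_defined = tp + fn > 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
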