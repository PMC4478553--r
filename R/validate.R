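# Call-reliability accounting: false-positive rate from sex-mismatched
# hybridizations, 2^-ddCt relative copy-number quantification from qPCR
# Ct tables, and positive/negative predictive-rate bookkeeping of qPCR
# confirmations against aCGH carrier predictions.

#' False-positive rate from sex-mismatched arrays
#'
#' On a male-test vs female-reference array every true chrX segment is a
#' loss, so chrX segments with positive mean log2 are false positives.
#' FPR = 100 * (total false-segment length summed over arrays) /
#' (chrX length * number of arrays).
#'
#' @param calls segment data.frame (`chrom`, `start`, `end`, `mean_log2`),
#'   pooled over the sex-mismatched arrays; or NULL when `false_length_bp`
#'   is given directly.
#' @param chrx_length chrX length in bp.
#' @param n_arrays number of sex-mismatched arrays.
#' @param chrx_name chromosome name treated as X (default "X").
#' @param false_length_bp optional pre-summed false-call length in bp,
#'   used instead of `calls`.
#' @return list: `false_length_bp`, `n_false_segments`, `fpr_percent`.
#' @export
sex_mismatch_fpr <- function(calls = NULL, chrx_length, n_arrays,
                             chrx_name = "X", false_length_bp = NULL) {
  if (n_arrays < 1) .stopf("n_arrays must be >= 1")
  n_false <- NA_integer_
  if (is.null(false_length_bp)) {
    cx <- calls[norm_chrom(calls$chrom) == norm_chrom(chrx_name) &
                  calls$mean_log2 > 0, , drop = FALSE]
    false_length_bp <- sum(cx$end - cx$start)
    n_false <- nrow(cx)
  }
  list(false_length_bp = false_length_bp, n_false_segments = n_false,
       fpr_percent = 100 * false_length_bp / (chrx_length * n_arrays))
}

.mean_ct <- function(ct, sample, target) {
  v <- ct$ct[ct$sample_id == sample & ct$target_id == target]
  v <- v[is.finite(v)]
  if (length(v) == 0)
    .stopf("no usable wells for sample %s at amplicon %s", sample, target)
  mean(v)
}

#' Relative copy number by the 2^-ddCt method
#'
#' Duplicate wells are averaged on the Ct scale. dCt = mean Ct(target) -
#' mean Ct(control amplicon) within a sample; ddCt = dCt(sample) -
#' dCt(reference sample); the returned ratio 2^-ddCt estimates copy
#' number relative to the reference (1 = two copies at baseline ploidy).
#'
#' @param ct a `ct_table` (with `reference_sample` and `control_target`
#'   attributes, overridable).
#' @param target_id target amplicon.
#' @param sample_id sample to quantify.
#' @param reference_sample,control_target override the table attributes.
#' @return the copy-number ratio 2^-ddCt.
#' @export
ddct_copy_ratio <- function(ct, target_id, sample_id,
                            reference_sample = attr(ct, "reference_sample"),
                            control_target = attr(ct, "control_target")) {
  if (is.null(reference_sample))
    .stopf("no reference sample defined for the Ct table")
  for (s in c(sample_id, reference_sample)) {
    if (!any(ct$sample_id == s & ct$target_id == control_target))
      .stopf("missing control-amplicon wells for sample %s", s)
  }
  dct <- .mean_ct(ct, sample_id, target_id) -
    .mean_ct(ct, sample_id, control_target)
  dct_ref <- .mean_ct(ct, reference_sample, target_id) -
    .mean_ct(ct, reference_sample, control_target)
  2^(-(dct - dct_ref))
}

#' Classify a qPCR copy-number ratio
#'
#' gain if ratio >= `gain_cutoff` (inclusive), loss if <= `loss_cutoff`
#' (inclusive), otherwise normal. Defaults sit midway between the
#' expected 3-copy (1.5) and 2-copy (1.0) ratios and between the 1-copy
#' (0.5) and 2-copy ratios.
#'
#' @param cn_ratio positive copy-number ratio(s).
#' @param gain_cutoff default 1.4.
#' @param loss_cutoff default 0.7.
#' @return character vector in \{gain, loss, normal\}.
#' @export
classify_qpcr <- function(cn_ratio, gain_cutoff = 1.4, loss_cutoff = 0.7) {
  if (loss_cutoff >= gain_cutoff)
    .stopf("loss_cutoff must be below gain_cutoff")
  if (any(cn_ratio <= 0)) .stopf("cn_ratio must be positive")
  ifelse(cn_ratio >= gain_cutoff, "gain",
         ifelse(cn_ratio <= loss_cutoff, "loss", "normal"))
}

#' Positive and negative predictive rates for one qPCR assay
#'
#' Positive samples are those predicted by aCGH to carry the CNVR; a
#' positive is confirmed iff its qPCR call matches the predicted
#' direction (for "both"-type CNVRs, each sample's own predicted
#' direction). Negative samples are predicted non-carriers; following the
#' confirmation-table convention, a negative is "confirmed" when qPCR
#' nevertheless detects variation (a non-normal call) — i.e. the negative
#' rate counts apparent aCGH false negatives.
#'
#' @param predicted logical vector (named by sample) of aCGH carrier
#'   status.
#' @param qpcr_calls character vector (same samples) of qPCR calls in
#'   \{gain, loss, normal\}.
#' @param expected_direction "gain", "loss", or "both".
#' @param sample_direction optional per-sample predicted direction, used
#'   for "both"-type CNVRs.
#' @return list with counts and rates (`positive_rate`/`negative_rate`
#'   are NA when their denominator is zero, the printed-table "—").
#' @export
predictive_rates <- function(predicted, qpcr_calls, expected_direction,
                             sample_direction = NULL) {
  stopifnot(length(predicted) == length(qpcr_calls))
  want <- if (expected_direction == "both") {
    if (is.null(sample_direction))
      .stopf("sample_direction is required for both-type CNVRs")
    sample_direction
  } else rep(expected_direction, length(predicted))
  pos <- which(predicted)
  neg <- which(!predicted)
  pos_conf <- sum(qpcr_calls[pos] == want[pos])
  neg_conf <- sum(qpcr_calls[neg] != "normal")
  list(n_positive = length(pos), n_positive_confirmed = pos_conf,
       positive_rate = if (length(pos)) pos_conf / length(pos) else NA_real_,
       n_negative = length(neg), n_negative_confirmed = neg_conf,
       negative_rate = if (length(neg)) neg_conf / length(neg) else NA_real_)
}

#' Recompute per-assay predictive rates from an assay count table
#'
#' @param assays data.frame with columns `pos_n`, `pos_confirmed`,
#'   `neg_n`, `neg_confirmed` (one row per qPCR assay).
#' @return the table with `positive_rate` and `negative_rate` columns
#'   appended (NA where the denominator is zero).
#' @export
assay_rate_table <- function(assays) {
  assays$positive_rate <- ifelse(assays$pos_n > 0,
                                 assays$pos_confirmed / assays$pos_n,
                                 NA_real_)
  assays$negative_rate <- ifelse(assays$neg_n > 0,
                                 assays$neg_confirmed / assays$neg_n,
                                 NA_real_)
  assays
}

#' Summarize a qPCR confirmation campaign
#'
#' Row-averages the per-assay positive and negative predictive rates
#' (negatives over assays with a defined rate), and computes overall
#' assay agreement and per-CNVR confirmation (a CNVR is confirmed when at
#' least one of its assays agrees with the aCGH prediction).
#'
#' @param assays an [assay_rate_table()] result (confirmed assays only,
#'   with a `cnvr` column).
#' @param n_assays_total total assays performed (confirmed + disagreeing).
#' @param n_cnvrs_tested total CNVRs assayed.
#' @return list of summary rates.
#' @export
qpcr_campaign_summary <- function(assays, n_assays_total, n_cnvrs_tested) {
  list(mean_positive_rate = mean(assays$positive_rate, na.rm = TRUE),
       mean_negative_rate = mean(assays$negative_rate, na.rm = TRUE),
       n_assays_agreeing = nrow(assays),
       assay_agreement_pct = 100 * nrow(assays) / n_assays_total,
       n_cnvrs_confirmed = length(unique(assays$cnvr)),
       cnvr_confirmation_pct = 100 * length(unique(assays$cnvr)) /
         n_cnvrs_tested)
}
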