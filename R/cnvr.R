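# Aggregation of per-sample CNV calls into cross-sample CNV regions
# (CNVRs), catalog summaries, and comparison against external CNVR
# catalogs. The overlap criterion everywhere is >= 1 shared base pair
# (half-open intervals); abutting intervals do not overlap.

.chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom)
}

#' Merge CNV calls across samples into CNVRs
#'
#' CNVRs are the transitive union of calls that overlap by at least 1 bp
#' on the same chromosome. Frequency is the percent of test samples
#' contributing at least one member call; type is "loss"/"gain" when all
#' members agree and "both" when a region carries members of both
#' directions. chrY is excluded by default (sex-mismatch control calls are
#' handled by the validation module, not the catalog).
#'
#' @param calls a `cnv_calls` data.frame across all samples (filtered
#'   calls only).
#' @param n_test_samples denominator for carrier frequency.
#' @param exclude_chroms chromosomes left out of the catalog (default "Y").
#' @return a `cnvr_catalog` data.frame: `id`, `chrom`, `start`, `end`,
#'   `length`, `n_calls`, `n_samples`, `samples`, `frequency`, `type`,
#'   with member calls retained in `attr(, "calls")` and per-CNVR member
#'   row indices in `attr(, "members")`.
#' @export
merge_cnvrs <- function(calls, n_test_samples, exclude_chroms = "Y") {
  if (n_test_samples < 1) .stopf("n_test_samples must be >= 1")
  calls <- as.data.frame(calls)
  calls <- calls[!(norm_chrom(calls$chrom) %in% norm_chrom(exclude_chroms)), ,
                 drop = FALSE]
  if (nrow(calls) == 0) {
    out <- data.frame(id = character(), chrom = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      n_calls = integer(), n_samples = integer(),
                      samples = character(), frequency = numeric(),
                      type = character(), stringsAsFactors = FALSE)
    attr(out, "calls") <- calls
    attr(out, "members") <- list()
    attr(out, "n_test_samples") <- n_test_samples
    class(out) <- c("cnvr_catalog", "data.frame")
    return(out)
  }
  calls$chrom <- norm_chrom(calls$chrom)
  # transitive union per chromosome by sort-and-sweep (>= 1 bp overlap)
  regions <- list()
  for (chrom in unique(calls$chrom)) {
    cc <- calls[calls$chrom == chrom, , drop = FALSE]
    cc <- cc[order(cc$start, cc$end), , drop = FALSE]
    cur_s <- cc$start[1]; cur_e <- cc$end[1]
    for (i in seq_len(nrow(cc))[-1]) {
      if (cc$start[i] < cur_e) cur_e <- max(cur_e, cc$end[i])
      else {
        regions[[length(regions) + 1]] <- list(chrom = chrom, start = cur_s,
                                               end = cur_e)
        cur_s <- cc$start[i]; cur_e <- cc$end[i]
      }
    }
    regions[[length(regions) + 1]] <- list(chrom = chrom, start = cur_s,
                                           end = cur_e)
  }
  reg <- do.call(rbind, lapply(regions, as.data.frame))
  reg <- reg[.chrom_order(reg$chrom), , drop = FALSE]
  reg <- reg[order(match(reg$chrom, unique(reg$chrom)), reg$start), ,
             drop = FALSE]
  # assign member calls by >= 1 bp overlap
  hits <- GenomicRanges::findOverlaps(.as_granges(calls), .as_granges(reg))
  members <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  members <- lapply(seq_len(nrow(reg)), function(i)
    as.integer(members[[as.character(i)]]))
  info <- lapply(members, function(m) {
    dirs <- unique(calls$direction[m])
    samp <- sort(unique(calls$sample_id[m]))
    list(n_calls = length(m), n_samples = length(samp),
         samples = paste(samp, collapse = ","),
         type = if (length(dirs) > 1) "both" else dirs)
  })
  out <- data.frame(id = sprintf("CNVR%d", seq_len(nrow(reg))),
                    chrom = reg$chrom, start = reg$start, end = reg$end,
                    length = reg$end - reg$start,
                    n_calls = vapply(info, `[[`, 0L, "n_calls"),
                    n_samples = vapply(info, `[[`, 0L, "n_samples"),
                    samples = vapply(info, `[[`, "", "samples"),
                    frequency = 100 * vapply(info, `[[`, 0L, "n_samples") /
                      n_test_samples,
                    type = vapply(info, `[[`, "", "type"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "calls") <- calls
  attr(out, "members") <- members
  attr(out, "n_test_samples") <- n_test_samples
  class(out) <- c("cnvr_catalog", "data.frame")
  out
}

#' @export
print.cnvr_catalog <- function(x, ...) {
  cat(sprintf("cnvr_catalog: %d CNVRs from %d calls across %d test samples\n",
              nrow(x), nrow(attr(x, "calls")), attr(x, "n_test_samples")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

.size_bins_kb <- c(0, 10, 20, 50, 100, 500, Inf)
.size_labels <- c("<10", "10-20", "20-50", "50-100", "100-500", ">=500")

#' Summarize a CNVR catalog
#'
#' Count, total/mean/median length, per-chromosome counts and
#' length-percent of chromosome, the size histogram (bins <10, 10-20,
#' 20-50, 50-100, 100-500, >=500 kb), per-type counts and percentages,
#' and the frequency spectrum (singleton fraction, fraction at >= 50%
#' carrier frequency).
#'
#' @param cnvrs a `cnvr_catalog`.
#' @param genome a [genome_spec()] covering all catalog chromosomes.
#' @return a `cnvr_summary` list.
#' @export
summarize_catalog <- function(cnvrs, genome) {
  stopifnot(inherits(genome, "genome_spec"))
  glen <- genome$length[match(cnvrs$chrom, genome$chrom)]
  if (any(is.na(glen)) || any(cnvrs$end > glen))
    .stopf("catalog contains a CNVR beyond its chromosome end")
  len <- cnvrs$end - cnvrs$start
  per_chrom <- do.call(rbind, lapply(split(seq_len(nrow(cnvrs)), cnvrs$chrom),
    function(i) data.frame(chrom = cnvrs$chrom[i[1]], n = length(i),
                           length_bp = sum(len[i]),
                           pct_of_chrom = 100 * sum(len[i]) /
                             genome$length[match(cnvrs$chrom[i[1]],
                                                 genome$chrom)])))
  type_counts <- table(factor(cnvrs$type, levels = c("loss", "gain", "both")))
  type_pct <- 100 * as.numeric(type_counts) / max(nrow(cnvrs), 1)
  names(type_pct) <- names(type_counts)
  size_hist <- table(cut(len / 1000, breaks = .size_bins_kb,
                         labels = .size_labels, right = FALSE))
  out <- list(
    n_cnvrs = nrow(cnvrs),
    total_length_bp = sum(len),
    pct_of_genome = 100 * sum(len) / sum(genome$length),
    mean_length_kb = mean(len) / 1000,
    median_length_kb = stats::median(len) / 1000,
    per_chrom = if (is.null(per_chrom)) data.frame() else
      per_chrom[.chrom_order(per_chrom$chrom), , drop = FALSE],
    size_hist = size_hist,
    type_counts = type_counts,
    type_pct = type_pct,
    loss_gain_ratio = unname(type_counts["loss"] / type_counts["gain"]),
    pct_singleton = 100 * mean(cnvrs$n_samples == 1),
    pct_freq_ge_50 = 100 * mean(cnvrs$frequency >= 50))
  class(out) <- "cnvr_summary"
  out
}

#' @export
print.cnvr_summary <- function(x, ...) {
  cat(sprintf("CNVRs: %d covering %.2f Mb (%.2f%% of genome)\n",
              x$n_cnvrs, x$total_length_bp / 1e6, x$pct_of_genome))
  cat(sprintf("length: mean %.2f kb, median %.2f kb\n",
              x$mean_length_kb, x$median_length_kb))
  cat(sprintf("types: loss %d (%.2f%%), gain %d (%.2f%%), both %d (%.2f%%); loss/gain = %.2f\n",
              x$type_counts["loss"], x$type_pct["loss"],
              x$type_counts["gain"], x$type_pct["gain"],
              x$type_counts["both"], x$type_pct["both"], x$loss_gain_ratio))
  cat(sprintf("frequency: %.2f%% singletons, %.2f%% at >= 50%%\n",
              x$pct_singleton, x$pct_freq_ge_50))
  cat("size distribution (kb):\n")
  print(x$size_hist)
  invisible(x)
}

#' Summarize per-sample CNV counts
#'
#' @param counts named integer vector of per-sample CNV call counts.
#' @return list with `n_samples`, `total`, `mean` (mean rounded as
#'   reported, 2 decimals, in `mean_2dp`).
#' @export
summarize_sample_counts <- function(counts) {
  list(n_samples = length(counts), total = sum(counts), mean = mean(counts),
       mean_2dp = round(mean(counts), 2))
}

#' CNVR type breakdown from counts
#'
#' @param counts named vector with elements `loss`, `gain`, `both`.
#' @return list with per-type percentages (2 decimals) and the loss/gain
#'   fold ratio.
#' @export
type_breakdown <- function(counts) {
  total <- sum(counts)
  pct <- 100 * counts / total
  list(pct = pct, pct_2dp = round(pct, 2),
       loss_gain_ratio = unname(counts["loss"] / counts["gain"]))
}

#' Compare a CNVR catalog with a reference catalog
#'
#' A query CNVR "overlaps" when it shares >= 1 bp with any reference
#' CNVR. `overlap_length` is the summed full length of the overlapping
#' query CNVRs; `length_percent` uses the query catalog's own total
#' length as denominator.
#'
#' @param query,reference interval data.frames (`chrom`, `start`, `end`),
#'   e.g. `cnvr_catalog`s.
#' @return a `catalog_comparison` list: `n_query`, `n_overlapping`,
#'   `count_percent`, `overlap_length_bp`, `length_percent`,
#'   `overlap_idx` (query row indices).
#' @export
compare_catalogs <- function(query, reference) {
  query <- as.data.frame(query)
  reference <- as.data.frame(reference)
  if (nrow(query) == 0) .stopf("empty query catalog")
  idx <- if (nrow(reference) == 0) integer() else
    sort(unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(.as_granges(query),
                                  .as_granges(reference)))))
  qlen <- query$end - query$start
  out <- list(n_query = nrow(query), n_overlapping = length(idx),
              count_percent = 100 * length(idx) / nrow(query),
              overlap_length_bp = sum(qlen[idx]),
              length_percent = 100 * sum(qlen[idx]) / sum(qlen),
              overlap_idx = idx)
  class(out) <- "catalog_comparison"
  out
}

#' @export
print.catalog_comparison <- function(x, ...) {
  cat(sprintf("%d/%d query CNVRs overlap a reference CNVR (%.2f%%); %.1f kb (%.2f%% of query length)\n",
              x$n_overlapping, x$n_query, x$count_percent,
              x$overlap_length_bp / 1000, x$length_percent))
  invisible(x)
}

#' Union of overlap sets across several reference catalogs
#'
#' Counts query CNVRs overlapping at least one reference catalog overall
#' (the union of per-reference overlap sets, not their sum).
#'
#' @param comparisons list of `catalog_comparison` objects over the same
#'   query catalog.
#' @return list with `n_overlapping_union` and the union `overlap_idx`.
#' @export
multi_catalog_union <- function(comparisons) {
  if (length(comparisons) == 0) .stopf("need at least one comparison")
  idx <- sort(unique(unlist(lapply(comparisons, `[[`, "overlap_idx"))))
  list(n_overlapping_union = length(idx), overlap_idx = idx)
}

#' Plot the CNVR size distribution
#'
#' @param x a `cnvr_summary`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.cnvr_summary <- function(x, ...) {
  graphics::barplot(x$size_hist, xlab = "CNVR size (kb)",
                    ylab = "count", ...)
  invisible(x)
}
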