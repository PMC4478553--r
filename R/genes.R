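# Gene-content analysis: overlap of CNVRs with gene annotation, biotype
# tallies, the Wilcoxon rank-sum comparison of dN/dS between CNVR and
# non-CNVR genes, and flagging of conserved single-copy genes hit by
# CNVRs. dN/dS values are consumed as a prepared table.

#' Overlap genes with a CNVR catalog
#'
#' A gene is reported iff it shares at least 1 bp with any CNVR
#' (half-open intervals; an abutting gene is not reported). Containment
#' is "complete" when the gene interval lies entirely within a single
#' CNVR, else "partial".
#'
#' @param cnvrs a `cnvr_catalog` (or interval data.frame with `id`).
#' @param genes gene annotation from [read_gene_annotation()].
#' @return a `gene_overlap` data.frame: `gene_id`, `biotype`, `cnvr_ids`,
#'   `overlap_bp`, `containment`; biotype tallies in
#'   `attr(, "biotype_counts")`.
#' @export
annotate_cnvrs <- function(cnvrs, genes) {
  cnvrs <- as.data.frame(cnvrs)
  gr_c <- .as_granges(cnvrs)
  gr_g <- .as_granges(genes)
  hits <- GenomicRanges::findOverlaps(gr_g, gr_c)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(gr_g[qh], gr_c[sh]))
  ids <- if ("id" %in% names(cnvrs)) cnvrs$id else
    sprintf("CNVR%d", seq_len(nrow(cnvrs)))
  rows <- lapply(unique(qh), function(g) {
    k <- which(qh == g)
    complete <- any(genes$start[g] >= cnvrs$start[sh[k]] &
                      genes$end[g] <= cnvrs$end[sh[k]])
    data.frame(gene_id = genes$gene_id[g],
               biotype = if ("biotype" %in% names(genes))
                 genes$biotype[g] else "other",
               cnvr_ids = paste(ids[sh[k]], collapse = ","),
               overlap_bp = sum(ov[k]),
               containment = if (complete) "complete" else "partial",
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), biotype = character(),
               cnvr_ids = character(), overlap_bp = numeric(),
               containment = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "biotype_counts") <- table(factor(out$biotype,
    levels = c("protein_coding", "pseudo", "miscRNA", "other")))
  attr(out, "n_cnvrs_with_genes") <-
    length(unique(unlist(strsplit(out$cnvr_ids, ","))))
  class(out) <- c("gene_overlap", "data.frame")
  out
}

# exact one/two-sided rank-sum p by enumerating all C(n_a+n_b, n_a)
# group labelings (used when both groups are small)
.ranksum_exact_p <- function(a, b, alternative) {
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  idx <- utils::combn(n, length(a))
  w_obs <- sum(r[seq_along(a)])
  w_all <- apply(idx, 2, function(k) sum(r[k]))
  switch(alternative,
         greater = mean(w_all <= w_obs + 1e-9) , # one-sided: b greater <=> a's rank sum small
         two_sided = {
           mu <- length(a) * (n + 1) / 2
           mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
         })
}

#' Wilcoxon rank-sum test
#'
#' Mann-Whitney U on midranks with tie correction; p-value from the
#' normal approximation with continuity correction, or by exact
#' enumeration of all group labelings when both groups have at most
#' `exact_max` observations. `alternative = "greater"` tests whether
#' group b tends to exceed group a.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param alternative "two_sided" or "greater".
#' @param exact_max enumeration threshold per group (default 8).
#' @return list with `U` (for group a), `p_value`, `method`.
#' @export
rank_sum_test <- function(a, b, alternative = c("two_sided", "greater"),
                          exact_max = 8) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0) .stopf("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1)
    return(list(U = length(a) * length(b) / 2, p_value = 1,
                method = "degenerate (all values tied)"))
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  u <- w - na * (na + 1) / 2          # U for group a
  if (na <= exact_max && nb <= exact_max) {
    p <- .ranksum_exact_p(a, b, alternative)
    return(list(U = u, p_value = p, method = "exact enumeration"))
  }
  mu <- na * nb / 2
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_corr))
  z <- u - mu
  cc <- 0.5
  p <- switch(alternative,
              two_sided = 2 * stats::pnorm((abs(z) - cc) / sigma,
                                           lower.tail = FALSE),
              greater = stats::pnorm((z + cc) / sigma))  # b > a <=> small U_a
  list(U = u, p_value = min(p, 1), method = "normal approximation")
}

#' Compare dN/dS between CNVR genes and non-CNVR genes
#'
#' @param constraint data.frame with `gene_id`, `dnds`, `in_cnvr`
#'   (logical).
#' @param alternative passed to [rank_sum_test()]; "greater" tests
#'   whether CNVR genes have larger dN/dS.
#' @return the [rank_sum_test()] result plus group medians.
#' @export
dnds_comparison <- function(constraint, alternative = "greater") {
  a <- constraint$dnds[!constraint$in_cnvr]
  b <- constraint$dnds[constraint$in_cnvr]
  res <- rank_sum_test(a, b, alternative = alternative)
  res$median_non_cnvr <- stats::median(a)
  res$median_cnvr <- stats::median(b)
  res
}

#' Flag conserved single-copy genes affected by CNVRs
#'
#' Keeps genes with high orthology confidence and identity strictly above
#' `min_identity` percent in every listed species, then intersects with
#' the CNVR gene overlaps when provided.
#'
#' @param genes gene annotation data.frame.
#' @param orthology data.frame `gene_id`, `species`, `confidence`
#'   ("high"/"low"), `identity` (percent).
#' @param overlaps optional [annotate_cnvrs()] result to intersect with.
#' @param min_identity strict identity threshold (default 80).
#' @return subset of `genes` that are conserved single-copy (and, when
#'   `overlaps` is given, CNVR-affected).
#' @export
flag_conserved_single_copy <- function(genes, orthology, overlaps = NULL,
                                       min_identity = 80) {
  if (nrow(orthology) == 0) {
    .warnf("empty orthology table: no conserved single-copy genes")
    return(genes[0, , drop = FALSE])
  }
  by_gene <- split(orthology, orthology$gene_id)
  conserved <- names(by_gene)[vapply(by_gene, function(g)
    all(g$confidence == "high" & g$identity > min_identity), TRUE)]
  absent <- setdiff(genes$gene_id, orthology$gene_id)
  if (length(absent))
    message(length(absent), " gene(s) missing from the orthology table; treated as non-conserved")
  keep <- genes$gene_id %in% conserved
  if (!is.null(overlaps)) keep <- keep & genes$gene_id %in% overlaps$gene_id
  genes[keep, , drop = FALSE]
}
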