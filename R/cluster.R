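# CNVR-based clustering of samples: binary carrier profiles, Jaccard or
# simple-matching distances, UPGMA with a deterministic tie-break, and
# bootstrap branch support by resampling CNVR columns.

#' Binary CNVR carrier matrix
#'
#' @param cnvrs a `cnvr_catalog`.
#' @param samples sample ids for the rows.
#' @return samples x CNVRs 0/1 matrix; 1 iff the sample contributes at
#'   least one member call to the CNVR.
#' @export
presence_matrix <- function(cnvrs, samples) {
  if (length(samples) == 0) .stopf("samples must be non-empty")
  m <- matrix(0L, nrow = length(samples), ncol = nrow(cnvrs),
              dimnames = list(samples, cnvrs$id))
  carriers <- strsplit(cnvrs$samples, ",")
  for (j in seq_len(nrow(cnvrs)))
    m[samples %in% carriers[[j]], j] <- 1L
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty))
    .warnf("sample(s) with no CNVR calls: %s", paste(empty, collapse = ", "))
  m
}

#' Pairwise distances between binary carrier profiles
#'
#' Jaccard: d = 1 - |intersection| / |union| (0 when both rows are
#' empty). Simple matching: fraction of discordant columns.
#'
#' @param m 0/1 matrix, samples in rows (>= 2).
#' @param metric "jaccard" or "simple_matching".
#' @return a symmetric distance matrix with zero diagonal.
#' @export
binary_distance <- function(m, metric = c("jaccard", "simple_matching")) {
  metric <- match.arg(metric)
  if (nrow(m) < 2) .stopf("need >= 2 samples")
  if (length(unique(as.vector(m))) == 1)
    .stopf("constant presence matrix: all pairwise distances are zero, clustering is meaningless")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- m[i, ] > 0; b <- m[j, ] > 0
    d[i, j] <- d[j, i] <- if (metric == "jaccard") {
      u <- sum(a | b)
      if (u == 0) 0 else 1 - sum(a & b) / u
    } else mean(a != b)
  }
  d
}

#' UPGMA clustering
#'
#' Agglomerates the pair of clusters with the smallest size-weighted
#' average-linkage distance at each step; equal-distance ties break on
#' the lexicographically smallest pair of cluster representative labels
#' (each cluster represented by its smallest member label), making the
#' tree reproducible. Merge heights are ultrametric node heights (half
#' the average between-cluster distance).
#'
#' @param d symmetric distance matrix with labeled rows.
#' @return a `cnvr_dendrogram`: hclust-style `merge`, `height` (node
#'   heights, i.e. half-distances), `labels`, `order`, and the leaf set
#'   below each internal node in `clades`.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    .stopf("distance matrix is not symmetric")
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  active <- seq_len(n)
  node_id <- -seq_len(n)               # hclust convention: negatives = leaves
  members <- as.list(seq_len(n))
  rep_label <- labels
  size <- rep(1, n)
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  clades <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- NULL
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ai <- active[i]; aj <- active[j]
      dij <- D[ai, aj]
      pair <- sort(c(rep_label[ai], rep_label[aj]))
      if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 &&
           (pair[1] < best$pair[1] ||
            (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
        best <- list(d = dij, i = ai, j = aj, pair = pair)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- c(node_id[i], node_id[j])
    height[step] <- best$d / 2
    new_members <- c(members[[i]], members[[j]])
    clades[[step]] <- sort(labels[new_members])
    # size-weighted average linkage update
    for (a in setdiff(active, c(i, j)))
      D[i, a] <- D[a, i] <- (size[i] * D[i, a] + size[j] * D[j, a]) /
        (size[i] + size[j])
    members[[i]] <- new_members
    size[i] <- size[i] + size[j]
    rep_label[i] <- min(best$pair)
    node_id[i] <- step
    active <- setdiff(active, j)
  }
  # leaf order by traversal
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  out <- list(merge = merge, height = height, labels = labels,
              order = walk(n - 1), clades = clades, bp_support = NULL)
  class(out) <- "cnvr_dendrogram"
  out
}

#' @export
as.hclust.cnvr_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = 2 * x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "binary"),
            class = "hclust")
}

#' @export
print.cnvr_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram on %d samples\n", length(x$labels)))
  for (k in seq_along(x$height)) {
    cat(sprintf("  node %d: height %.4f {%s}%s\n", k, x$height[k],
                paste(x$clades[[k]], collapse = ","),
                if (!is.null(x$bp_support))
                  sprintf("  bp=%.0f", x$bp_support[k]) else ""))
  }
  invisible(x)
}

#' @export
plot.cnvr_dendrogram <- function(x, ...) {
  hc <- as.hclust.cnvr_dendrogram(x)
  graphics::plot(hc, ylab = "UPGMA distance", ...)
  invisible(x)
}

.clade_key <- function(members) paste(members, collapse = "|")

#' Bootstrap branch support for the UPGMA tree
#'
#' Resamples CNVR columns with replacement, reclusters each replicate,
#' and reports for every internal node of the original tree the percent
#' of replicates whose tree contains the same leaf set (bootstrap
#' proportion, BP). Seeded and reproducible.
#'
#' @param m presence matrix (>= 2 columns).
#' @param metric distance metric, see [binary_distance()].
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return the original `cnvr_dendrogram` with `bp_support` filled
#'   (percent per internal node, in merge order).
#' @export
bootstrap_support <- function(m, metric = "jaccard", n_boot = 1000L,
                              seed = 1L) {
  if (ncol(m) < 2) .stopf("need >= 2 CNVR columns to bootstrap")
  if (n_boot < 1) .stopf("n_boot must be >= 1")
  tree <- upgma(binary_distance(m, metric))
  keys <- vapply(tree$clades, .clade_key, "")
  counts <- numeric(length(keys))
  .with_seed(seed, {
    for (b in seq_len(n_boot)) {
      mb <- m[, sample.int(ncol(m), ncol(m), replace = TRUE), drop = FALSE]
      if (length(unique(as.vector(mb))) == 1) next  # uninformative replicate
      tb <- upgma(binary_distance(mb, metric))
      counts <- counts + (keys %in% vapply(tb$clades, .clade_key, ""))
    }
  })
  tree$bp_support <- 100 * counts / n_boot
  tree
}

#' Export a dendrogram as Newick with bootstrap labels
#'
#' Converts to an `ape` phylo tree and writes Newick, with BP values (if
#' present) as internal node labels.
#'
#' @param tree a `cnvr_dendrogram`.
#' @param path output path; if NULL the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
export_newick <- function(tree, path = NULL) {
  ph <- ape::as.phylo(as.hclust.cnvr_dendrogram(tree))
  if (!is.null(tree$bp_support)) {
    pp <- ape::prop.part(ph)
    tip_labels <- attr(pp, "labels")
    keys <- vapply(tree$clades, .clade_key, "")
    node_keys <- vapply(pp, function(tips)
      .clade_key(sort(tip_labels[tips])), "")
    ph$node.label <- ifelse(node_keys %in% keys,
                            sprintf("%.0f", tree$bp_support[
                              match(node_keys, keys)]), "")
  }
  nwk <- ape::write.tree(ph)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
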