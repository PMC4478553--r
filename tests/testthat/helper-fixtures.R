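# Shared fixtures and independent oracles used across the suite.

# Build a ratio_track directly from a log2 vector (uniform 1 kb probe
# grid per chromosome), with QC all-pass and a known noise sigma.
mk_track <- function(x, chrom = rep("1", length(x)), sample_id = "T",
                     sigma = NULL, spacing = 1000, probe_len = 60) {
  starts <- unlist(lapply(split(seq_along(x), factor(chrom, unique(chrom))),
                          function(i) (seq_along(i) - 1) * spacing),
                   use.names = FALSE)
  pm <- data.frame(probe_id = sprintf("P%05d", seq_along(x)),
                   chrom = chrom, start = starts, end = starts + probe_len,
                   stringsAsFactors = FALSE)
  class(pm) <- c("probe_map", "data.frame")
  tr <- arrayCNV:::new_ratio_track(sample_id = sample_id, probe_map = pm,
                                   log2_ratio = x,
                                   intensity_test = rep(1000, length(x)),
                                   intensity_ref = rep(1000, length(x)),
                                   snr_test = rep(100, length(x)),
                                   snr_ref = rep(100, length(x)))
  tr$noise_sigma <- sigma
  tr
}

# O(n^2) brute-force oracle for the best-|score| interval, straight from
# the score definition (independent of the compiled scan). Scans starts
# ascending and, within a start, ends ascending, keeping the first
# maximum — the same leftmost-then-shortest tie rule.
oracle_best_interval <- function(x, sigma, sigma_g) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  best <- list(score = 0, start = NA, end = NA, abs = -1)
  for (i in seq_len(n)) {
    m <- seq_len(n - i + 1)
    sc <- (cs[i + m] - cs[i]) / m / sqrt(sigma^2 / m + sigma_g^2)
    k <- which.max(abs(sc))          # first index at the max
    if (abs(sc[k]) > best$abs)
      best <- list(score = sc[k], start = i - 1, end = i - 1 + k,
                   abs = abs(sc[k]))
  }
  best
}

# union-find oracle for transitive interval merging (>= 1 bp overlap)
oracle_merge <- function(df) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (df$chrom[i] == df$chrom[j] &&
        df$start[i] < df$end[j] && df$start[j] < df$end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  out <- do.call(rbind, lapply(split(seq_len(n), roots), function(k)
    data.frame(chrom = df$chrom[k[1]], start = min(df$start[k]),
               end = max(df$end[k]))))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# all-pairs overlap oracle for catalog comparison
oracle_overlap_idx <- function(query, reference) {
  hit <- logical(nrow(query))
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(reference))) {
    if (query$chrom[i] == reference$chrom[j] &&
        query$start[i] < reference$end[j] &&
        reference$start[j] < query$end[i]) hit[i] <- TRUE
  }
  which(hit)
}

random_intervals <- function(n, chroms = c("1", "2"), max_pos = 1e5,
                             max_len = 5e3) {
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s <- sample.int(max_pos, n),
             end = s + sample.int(max_len, n),
             stringsAsFactors = FALSE)
}

# leaf sets below each internal node of an hclust tree, as canonical keys
hclust_clades <- function(hc) {
  labs <- hc$labels
  members <- function(node) {
    if (node < 0) return(labs[-node])
    sort(c(members(hc$merge[node, 1]), members(hc$merge[node, 2])))
  }
  vapply(seq_len(nrow(hc$merge)), function(k)
    paste(members(k), collapse = "|"), "")
}

extdata <- function(f) system.file("extdata", f, package = "arrayCNV")
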