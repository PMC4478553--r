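# CNVR aggregation, summaries, and catalog comparison against
# brute-force oracles.

mk_calls <- function(chrom, start, end, sample_id, direction = "loss") {
  data.frame(chrom = chrom, start = start, end = end, sample_id = sample_id,
             direction = direction,
             n_probes = 10, mean_log2 = ifelse(direction == "gain", 1, -1),
             score = 10, stringsAsFactors = FALSE)
}

test_that("overlapping calls union into one CNVR with the right frequency and type", {
  calls <- mk_calls("1", c(100, 150), c(200, 300), c("A", "B"))
  cat1 <- merge_cnvrs(calls, n_test_samples = 12)
  expect_equal(nrow(cat1), 1)
  expect_equal(cat1$start, 100)
  expect_equal(cat1$end, 300)
  expect_equal(cat1$frequency, 100 * 2 / 12, tolerance = 1e-9)
  expect_equal(round(cat1$frequency, 2), 16.67)
  expect_equal(cat1$type, "loss")
  # gain + loss in the same region -> both
  calls2 <- rbind(calls, mk_calls("1", 180, 250, "C", "gain"))
  expect_equal(merge_cnvrs(calls2, 12)$type, "both")
  # abutting intervals (0 bp shared) do not merge
  calls3 <- mk_calls("1", c(100, 200), c(200, 300), c("A", "B"))
  expect_equal(nrow(merge_cnvrs(calls3, 12)), 2)
})

test_that("merging is transitive across chains", {
  # a overlaps b, b overlaps c, a does not touch c
  calls <- mk_calls("1", c(0, 80, 160), c(100, 180, 260), c("A", "B", "C"))
  cat1 <- merge_cnvrs(calls, 12)
  expect_equal(nrow(cat1), 1)
  expect_equal(cat1$start, 0)
  expect_equal(cat1$end, 260)
  expect_equal(cat1$n_samples, 3)
})

test_that("merging equals the union-find oracle and is order-independent", {
  set.seed(31)
  for (rep in 1:5) {
    df <- random_intervals(40)
    df$sample_id <- sample(LETTERS[1:6], 40, replace = TRUE)
    df$direction <- sample(c("gain", "loss"), 40, replace = TRUE)
    got <- merge_cnvrs(df, 6)
    want <- oracle_merge(df)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start[order(match(want$chrom, unique(got$chrom)), want$start)])
    expect_equal(sort(got$end), sort(want$end))
    # shuffling call order yields the identical catalog (member indices
    # refer to the shuffled input, so compare the catalog columns)
    got2 <- merge_cnvrs(df[sample(nrow(df)), ], 6)
    cols <- c("id", "chrom", "start", "end", "n_calls", "n_samples",
              "samples", "frequency", "type")
    expect_equal(data.frame(got[, cols]), data.frame(got2[, cols]),
                 ignore_attr = TRUE)
    # every member call is contained in its CNVR
    for (k in seq_len(nrow(got))) {
      m <- attr(got, "members")[[k]]
      cc <- attr(got, "calls")[m, ]
      expect_true(all(cc$start >= got$start[k] & cc$end <= got$end[k]))
    }
  }
})

test_that("catalog summaries report lengths, types, and frequencies", {
  calls <- rbind(mk_calls("1", c(0, 20000, 50000), c(10000, 40000, 80000),
                          c("A", "B", "A")),
                 mk_calls("2", 0, 5000, "B", "gain"))
  cat1 <- merge_cnvrs(calls, 12)
  g <- genome_spec(c("1", "2"), c(1e6, 1e6))
  s <- summarize_catalog(cat1, g)
  expect_equal(s$n_cnvrs, 4)
  expect_equal(s$total_length_bp, 10000 + 20000 + 30000 + 5000)
  expect_equal(s$mean_length_kb, 65 / 4)
  expect_equal(sum(as.numeric(s$type_counts)), 4)
  expect_equal(sum(s$type_pct), 100, tolerance = 0.01)
  expect_equal(s$pct_singleton, 100)
  # three CNVRs of 10/20/30 kb: mean and median 20 kb
  cat2 <- merge_cnvrs(mk_calls("1", c(0, 1e5, 2e5), c(1e4, 1.2e5, 2.3e5), "A"),
                      12)
  s2 <- summarize_catalog(cat2, g)
  expect_equal(s2$mean_length_kb, 20)
  expect_equal(s2$median_length_kb, 20)
  # CNVR beyond the chromosome end is rejected
  expect_error(summarize_catalog(cat1, genome_spec(c("1", "2"), c(60000, 1e6))),
               "beyond")
})

test_that("per-sample count summaries and type breakdowns reproduce printed arithmetic", {
  counts <- read.csv(extdata("pig_acgh_sample_cnv_counts.csv"))
  s <- summarize_sample_counts(counts$cnv_count)
  expect_equal(s$total, 2276)
  expect_equal(s$mean_2dp, 189.67)
  tb <- type_breakdown(c(loss = 529, gain = 200, both = 29))
  expect_equal(unname(tb$pct_2dp), c(69.79, 26.39, 3.83))
  expect_equal(tb$loss_gain_ratio, 529 / 200)
  expect_lt(abs(tb$loss_gain_ratio - 2.65), 0.01)
})

test_that("catalog comparison matches the all-pairs oracle", {
  q <- data.frame(chrom = "1", start = 0, end = 100)
  r <- data.frame(chrom = "1", start = 50, end = 150)
  cmp <- compare_catalogs(q, r)
  expect_equal(cmp$n_overlapping, 1)
  expect_equal(cmp$count_percent, 100)
  expect_equal(cmp$overlap_length_bp, 100)
  expect_equal(cmp$length_percent, 100)
  # disjoint
  cmp2 <- compare_catalogs(q, data.frame(chrom = "1", start = 500, end = 600))
  expect_equal(cmp2$n_overlapping, 0)
  expect_equal(cmp2$length_percent, 0)
  # self-comparison is always 100/100
  set.seed(32)
  a <- random_intervals(200)
  self <- compare_catalogs(a, a)
  expect_equal(self$count_percent, 100)
  expect_equal(self$length_percent, 100)
  # random sets against the quadratic oracle
  b <- random_intervals(200)
  cmp3 <- compare_catalogs(a, b)
  expect_equal(cmp3$overlap_idx, oracle_overlap_idx(a, b))
  expect_error(compare_catalogs(a[0, ], b), "empty")
})

test_that("multi-catalog overlap counts the union, not the sum", {
  q <- data.frame(chrom = "1", start = c(0, 200, 400, 600, 800, 1000, 1200),
                  end = c(100, 300, 500, 700, 900, 1100, 1300))
  r1 <- data.frame(chrom = "1", start = c(0, 200, 400), end = c(50, 250, 450))
  r2 <- data.frame(chrom = "1", start = c(600, 800, 1000, 1200),
                   end = c(650, 850, 1050, 1250))
  c1 <- compare_catalogs(q, r1)
  c2 <- compare_catalogs(q, r2)
  expect_equal(multi_catalog_union(list(c1, c2))$n_overlapping_union, 7)
  # both references hitting the same single query CNVR
  r3 <- data.frame(chrom = "1", start = 10, end = 20)
  r4 <- data.frame(chrom = "1", start = 30, end = 40)
  cc <- lapply(list(r3, r4), compare_catalogs, query = q[1, , drop = FALSE])
  expect_equal(multi_catalog_union(cc)$n_overlapping_union, 1)
  set.seed(33)
  a <- random_intervals(100)
  refs <- replicate(3, random_intervals(50), simplify = FALSE)
  cmps <- lapply(refs, function(r) compare_catalogs(a, r))
  want <- sort(unique(unlist(lapply(refs, function(r) oracle_overlap_idx(a, r)))))
  expect_equal(multi_catalog_union(cmps)$overlap_idx, want)
})
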