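# Interval-score segmentation: closed forms, saturation, oracle
# equivalence, boundary recovery, and the post-filters.

test_that("interval score matches its closed form and is symmetric", {
  expect_equal(interval_score(rep(1, 4), sigma = 1), 2)
  expect_equal(interval_score(rep(0.05, 4), sigma = 0.1), 1)
  set.seed(1)
  x <- rnorm(50)
  expect_equal(interval_score(-x, 0.3, 0.05), -interval_score(x, 0.3, 0.05))
  # brute-force recomputation from the definition
  expect_equal(interval_score(x, 0.3, 0.05),
               mean(x) / sqrt(0.3^2 / 50 + 0.05^2))
  expect_error(interval_score(numeric(0), 1), "empty")
})

test_that("fuzzy zero saturates the score of a fixed mean at mean/sigma_g", {
  n <- 10000
  sc <- interval_score(rep(0.05, n), sigma = 0.1, sigma_g = 0.02)
  expect_lt(sc, 0.05 / 0.02)
  expect_gt(sc, 0.95 * 0.05 / 0.02)
  # without fuzzy zero the same mean grows unboundedly with n
  expect_gt(interval_score(rep(0.05, n), sigma = 0.1), 0.05 / 0.02)
})

test_that("the compiled scan equals the exhaustive oracle on random tracks", {
  set.seed(21)
  for (k in 1:20) {
    n <- sample(20:200, 1)
    x <- rnorm(n, 0, 0.15)
    if (k %% 2 == 0) {  # sometimes plant a segment
      i <- sample(n - 8, 1)
      x[i:(i + 7)] <- x[i:(i + 7)] + sample(c(-0.8, 0.8), 1)
    }
    sg <- sample(c(0, 0.03), 1)
    got <- arrayCNV:::best_interval_cpp(x, 0.15, sg)
    want <- oracle_best_interval(x, 0.15, sg)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("a noiseless aberration is recovered with exact boundaries", {
  x <- rep(0, 300)
  x[101:150] <- 1
  t1 <- mk_track(x, sigma = 0.01)
  segs <- detect_aberrations(t1, threshold = 6)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$probe_start, 100)
  expect_equal(segs$probe_end, 150)
  expect_equal(segs$n_probes, 50)
  expect_equal(segs$mean_log2, 1)
  expect_equal(segs$direction, "gain")
  expect_equal(segs$start, t1$probe_map$start[101])
  expect_equal(segs$end, t1$probe_map$end[150])
})

test_that("negating a track swaps gains and losses with identical boundaries", {
  set.seed(22)
  x <- rnorm(500, 0, 0.15)
  x[101:140] <- x[101:140] + 1
  x[301:320] <- x[301:320] - 0.9
  tp <- mk_track(x, sigma = 0.15)
  tn <- mk_track(-x, sigma = 0.15)
  sp <- detect_aberrations(tp)
  sn <- detect_aberrations(tn)
  expect_equal(sp$probe_start, sn$probe_start)
  expect_equal(sp$probe_end, sn$probe_end)
  expect_equal(sp$score, -sn$score, tolerance = 1e-12)
  expect_equal(ifelse(sp$direction == "gain", "loss", "gain"), sn$direction)
})

test_that("segments never span a chromosome junction", {
  x <- rep(0, 200)
  x[96:105] <- 1  # straddles the junction below
  t1 <- mk_track(x, chrom = rep(c("1", "2"), each = 100), sigma = 0.05)
  segs <- detect_aberrations(t1)
  expect_true(all(segs$chrom %in% c("1", "2")))
  expect_equal(nrow(segs), 2)  # one per chromosome side
  # the two sides have exact boundaries at their chromosome's edge probes
  s1 <- segs[segs$chrom == "1", ]
  s2 <- segs[segs$chrom == "2", ]
  expect_equal(s1$probe_start, 95)
  expect_equal(s1$probe_end, 100)
  expect_equal(s2$probe_start, 0)
  expect_equal(s2$probe_end, 5)
})

test_that("raising the threshold never adds segments; all survive at lower thresholds", {
  set.seed(23)
  x <- rnorm(800, 0, 0.15)
  x[101:130] <- x[101:130] + 0.8
  x[501:560] <- x[501:560] - 0.6
  t1 <- mk_track(x, sigma = 0.15)
  s_hi <- detect_aberrations(t1, threshold = 8)
  s_lo <- detect_aberrations(t1, threshold = 5)
  expect_lte(nrow(s_hi), nrow(s_lo))
  for (i in seq_len(nrow(s_hi))) {  # each high-threshold segment is covered at low threshold
    cover <- any(s_lo$probe_start <= s_hi$probe_start[i] &
                   s_lo$probe_end >= s_hi$probe_end[i])
    overlap <- any(s_lo$probe_start < s_hi$probe_end[i] &
                     s_hi$probe_start[i] < s_lo$probe_end)
    expect_true(cover || overlap)
  }
  expect_true(all(abs(s_hi$score) >= 8))
  expect_true(all(abs(s_lo$score) >= 5))
})

test_that("emitted segments never overlap", {
  set.seed(24)
  x <- rnorm(1000, 0, 0.15)
  for (i in seq(50, 900, by = 120)) x[i:(i + 15)] <- x[i:(i + 15)] + 0.9
  segs <- detect_aberrations(mk_track(x, sigma = 0.15))
  segs <- segs[order(segs$probe_start), ]
  if (nrow(segs) > 1)
    expect_true(all(segs$probe_start[-1] >= segs$probe_end[-nrow(segs)]))
})

test_that("seeded coarse-to-fine mode agrees with the exact scan", {
  set.seed(25)
  x <- rnorm(2000, 0, 0.15)
  x[301:340] <- x[301:340] + 1
  x[1201:1230] <- x[1201:1230] - 1
  t1 <- mk_track(x, sigma = 0.15)
  se <- detect_aberrations(t1, mode = "exact")
  ss <- detect_aberrations(t1, mode = "seeded", bin = 10)
  expect_equal(ss$probe_start, se$probe_start)
  expect_equal(ss$probe_end, se$probe_end)
  expect_equal(ss$score, se$score, tolerance = 1e-9)
})

test_that("the 5-probe / 0.5-log-ratio post-filter is enforced", {
  segs <- data.frame(sample_id = "S", chrom = "1",
                     start = c(0, 100, 200), end = c(50, 180, 280),
                     probe_start = c(0, 10, 20), probe_end = c(4, 30, 26),
                     n_probes = c(4, 20, 6),
                     mean_log2 = c(0.9, 0.45, -0.8),
                     score = c(8, 7, 9),
                     direction = c("gain", "gain", "loss"))
  calls <- filter_calls(segs)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$direction, "loss")
  expect_equal(calls$n_probes, 6)
  # boundary: exactly 5 probes kept, |mean| exactly 0.5 dropped
  segs2 <- segs
  segs2$n_probes <- c(5, 5, 5)
  segs2$mean_log2 <- c(0.51, 0.5, -0.5)
  expect_equal(nrow(filter_calls(segs2)), 1)
})

test_that("a QC-failing probe cannot carry a segment boundary", {
  x <- rep(0, 200)
  x[50:80] <- 1
  t1 <- mk_track(x, sigma = 0.05)
  t1$qc_pass[50] <- FALSE   # first aberrant probe flagged out
  segs <- detect_aberrations(t1)
  expect_equal(segs$start, t1$probe_map$start[51])
})
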