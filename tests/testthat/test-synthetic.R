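# Synthetic-data generators: determinism, truth-model arithmetic, and
# statistical consistency of the emitted noise.

test_that("probe maps hit the requested density, probe length, and are seeded", {
  g <- genome_spec("1", 1e6)
  pm <- simulate_probe_map(g, mean_spacing = 2632, probe_length = 60, seed = 5)
  expect_true(abs(nrow(pm) - 1e6 / 2632) < 0.2 * 1e6 / 2632)
  expect_true(all(pm$end - pm$start == 60))
  expect_false(is.unsorted(pm$start))
  pm2 <- simulate_probe_map(g, mean_spacing = 2632, probe_length = 60, seed = 5)
  expect_identical(pm, pm2)
  pm3 <- simulate_probe_map(g, mean_spacing = 2632, probe_length = 60, seed = 6)
  expect_false(identical(pm$start, pm3$start))
  expect_warning(simulate_probe_map(genome_spec("tiny", 500), 2632, 60),
                 "no probes fit")
})

test_that("truth segments carry log2(copy/ploidy), never the baseline, and stay in bounds", {
  g <- genome_spec(c("1", "2"), c(5e6, 3e6))
  tr <- simulate_truth(g, 20, c(1e4, 2e5),
                       state_weights = c("0" = 0.2, "1" = 0.3, "3" = 0.3,
                                         "4" = 0.2),
                       sample_ids = c("A", "B"), seed = 3)
  expect_equal(nrow(tr), 40)
  expect_false(any(tr$copy_state == 2))
  expect_equal(tr$expected_log2[tr$copy_state == 4], rep(1, sum(tr$copy_state == 4)))
  expect_equal(tr$expected_log2[tr$copy_state == 3],
               rep(log2(3 / 2), sum(tr$copy_state == 3)))
  expect_equal(tr$expected_log2[tr$copy_state == 0],
               rep(-4, sum(tr$copy_state == 0)))
  len <- g$length[match(tr$chrom, g$chrom)]
  expect_true(all(tr$start >= 0 & tr$start < tr$end & tr$end <= len))
  # non-overlap within each sample/chromosome
  for (s in c("A", "B")) for (ch in c("1", "2")) {
    seg <- tr[tr$sample_id == s & tr$chrom == ch, ]
    if (nrow(seg) > 1) {
      seg <- seg[order(seg$start), ]
      expect_true(all(seg$start[-1] >= seg$end[-nrow(seg)]))
    }
  }
  expect_identical(tr, simulate_truth(g, 20, c(1e4, 2e5),
                                      state_weights = c("0" = 0.2, "1" = 0.3,
                                                        "3" = 0.3, "4" = 0.2),
                                      sample_ids = c("A", "B"), seed = 3))
})

test_that("state frequencies follow the requested weights (binomial 99% bounds)", {
  g <- genome_spec("1", 2e8)
  tr <- simulate_truth(g, 100, c(1e4, 5e4),
                       state_weights = c("1" = 0.5, "3" = 0.5), seed = 7)
  n1 <- sum(tr$copy_state == 1)
  bounds <- qbinom(c(0.005, 0.995), 100, 0.5)
  expect_true(n1 >= bounds[1] && n1 <= bounds[2])
})

test_that("zero-noise tracks reproduce expected log2 exactly", {
  g <- genome_spec("1", 2e6)
  pm <- simulate_probe_map(g, 2000, 60, seed = 1)
  tr <- data.frame(sample_id = "S1", chrom = "1", start = 5e5, end = 8e5,
                   copy_state = 4L, expected_log2 = 1)
  t0 <- simulate_ratio_track(pm, tr, noise_spec(probe_sd = 0, qc_fail_frac = 0),
                             "S1")
  mid <- (pm$start + pm$end) / 2
  inside <- mid >= 5e5 & mid < 8e5
  expect_identical(t0$log2_ratio[inside], rep(1, sum(inside)))
  expect_identical(t0$log2_ratio[!inside], rep(0, sum(!inside)))
})

test_that("pure-noise tracks have the requested spread, wave, and seeding", {
  g <- genome_spec("1", 27e6)
  pm <- simulate_probe_map(g, 2632, 60, seed = 2)
  expect_gt(nrow(pm), 9000)
  nt <- noise_spec(probe_sd = 0.15, qc_fail_frac = 0, seed = 9)
  t1 <- simulate_ratio_track(pm, NULL, nt, "S1")
  expect_true(abs(sd(t1$log2_ratio) - 0.15) < 0.015)
  expect_identical(t1$log2_ratio,
                   simulate_ratio_track(pm, NULL, nt, "S1")$log2_ratio)
  # sinusoidal wave recoverable by regression
  ntw <- noise_spec(probe_sd = 0.15, wave_amplitude = 0.2, wave_period = 1e7,
                    qc_fail_frac = 0, seed = 9)
  tw <- simulate_ratio_track(pm, NULL, ntw, "S1")
  ph <- 2 * pi * pm$start / 1e7
  fit <- lm(tw$log2_ratio ~ sin(ph) + cos(ph))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_true(abs(amp - 0.2) < 0.02)
})

test_that("sex-mismatched arrays put chrX at -1, chrY at a gain, autosomes at 0", {
  g <- genome_spec(c("1", "X", "Y"), c(2e6, 2e6, 1e6))
  pm <- simulate_probe_map(g, 2000, 60, seed = 4)
  t0 <- simulate_sex_mismatch(pm, noise_spec(probe_sd = 0, qc_fail_frac = 0))
  expect_true(all(t0$log2_ratio[pm$chrom == "X"] == -1))
  expect_true(all(t0$log2_ratio[pm$chrom == "1"] == 0))
  expect_true(all(t0$log2_ratio[pm$chrom == "Y"] > 0))  # chrY only as gains
  tn <- simulate_sex_mismatch(pm, noise_spec(probe_sd = 0.15, qc_fail_frac = 0,
                                             seed = 2))
  expect_lt(mean(tn$log2_ratio[pm$chrom == "X"] > 0), 0.005)
  pm_nox <- simulate_probe_map(genome_spec("1", 2e6), 2000, 60, seed = 4)
  expect_error(simulate_sex_mismatch(pm_nox, noise_spec()), "X")
})

test_that("simulated Ct tables encode copy number on the efficiency scale", {
  truth <- data.frame(sample_id = c("A", "A", "B"), chrom = "1",
                      start = c(100, 5000, 100), end = c(1000, 6000, 1000),
                      copy_state = c(4L, 1L, 1L),
                      expected_log2 = c(1, -1, -1))
  targets <- data.frame(target_id = c("T1", "T2"), chrom = "1",
                        start = c(100, 5000), end = c(1000, 6000))
  ct <- simulate_qpcr(truth, targets, c("A", "B"), reference_sample = "REF",
                      ct_sd = 0, seed = 1)
  expect_equal(ddct_copy_ratio(ct, "T1", "A"), 2)      # 4 copies vs 2
  expect_equal(ddct_copy_ratio(ct, "T2", "A"), 0.5)    # 1 copy vs 2
  expect_equal(ddct_copy_ratio(ct, "T1", "B"), 0.5)
  expect_equal(ddct_copy_ratio(ct, "T2", "B"), 2^(0))  # B baseline at T2? no:
  # B has no truth at T2 -> baseline -> ratio 1
  expect_equal(ddct_copy_ratio(ct, "T2", "REF"), 1)    # reference vs itself
  expect_equal(nrow(ct[ct$sample_id == "A" & ct$target_id == "T1", ]), 2)
  expect_error(simulate_qpcr(truth, targets, "A", efficiency = 1.5),
               "efficiency")
  # baseline regions: Ct difference to reference has near-zero mean
  ct2 <- simulate_qpcr(truth, targets, c("A", "B"), reference_sample = "REF",
                       ct_sd = 0.1, seed = 2)
  expect_identical(ct2$ct,
                   simulate_qpcr(truth, targets, c("A", "B"),
                                 reference_sample = "REF", ct_sd = 0.1,
                                 seed = 2)$ct)
})
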