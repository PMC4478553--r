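# Seeded generators for every input the workflow consumes: probe maps,
# ground-truth copy-number segments, noisy log2-ratio tracks, sex-mismatched
# hybridizations, and qPCR Ct tables. All coordinates are 0-based half-open;
# all randomness flows from an explicit integer seed per call.

#' Define a genome for simulation
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in base pairs.
#' @param ploidy baseline copy number (default 2).
#' @return a `genome_spec` data.frame with columns `chrom`, `length`.
#' @examples
#' genome_spec(c("1", "X"), c(5e6, 3e6))
#' @export
genome_spec <- function(chrom, length, ploidy = 2L) {
  chrom <- norm_chrom(chrom)
  if (anyDuplicated(chrom)) .stopf("chromosome names must be unique")
  if (any(length <= 0)) .stopf("chromosome lengths must be positive")
  g <- data.frame(chrom = chrom, length = as.numeric(length),
                  stringsAsFactors = FALSE)
  attr(g, "ploidy") <- as.integer(ploidy)
  class(g) <- c("genome_spec", "data.frame")
  g
}

#' Noise model for simulated ratio tracks
#'
#' @param probe_sd per-probe Gaussian noise SD in log2 units (>= 0; 0 is
#'   the exact zero-noise limit used to test signal reconstruction).
#' @param wave_amplitude amplitude (log2 units) of a sinusoidal genomic wave.
#' @param wave_period wave period in base pairs.
#' @param dye_bias_slope intensity-dependent dye-bias slope, log2 units per
#'   unit of centered mean log-intensity.
#' @param qc_fail_frac fraction of probes engineered to fail the QC filter.
#' @param seed integer seed.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(probe_sd = 0.15, wave_amplitude = 0,
                       wave_period = 1e7, dye_bias_slope = 0,
                       qc_fail_frac = 0.01, seed = 1L) {
  if (probe_sd < 0) .stopf("probe_sd must be >= 0")
  if (wave_amplitude < 0) .stopf("wave_amplitude must be >= 0")
  structure(list(probe_sd = probe_sd, wave_amplitude = wave_amplitude,
                 wave_period = wave_period, dye_bias_slope = dye_bias_slope,
                 qc_fail_frac = qc_fail_frac, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Simulate an array probe map
#'
#' Probe starts are laid down left to right with exponential inter-probe
#' gaps, giving the requested mean start-to-start spacing (the array design
#' emulated here has a ~2.6 kb average probe interval). One map is drawn per
#' design and shared by all samples.
#'
#' @param genome a [genome_spec()].
#' @param mean_spacing mean start-to-start probe spacing in bp.
#' @param probe_length oligo length in bp (default 60).
#' @param seed integer seed.
#' @return a `probe_map` data.frame: `probe_id`, `chrom`, `start`, `end`
#'   (0-based half-open), sorted by (chrom, start).
#' @export
simulate_probe_map <- function(genome, mean_spacing = 2632,
                               probe_length = 60, seed = 1L) {
  stopifnot(inherits(genome, "genome_spec"))
  if (!(mean_spacing > probe_length && probe_length > 0))
    .stopf("require mean_spacing > probe_length > 0")
  .with_seed(seed, {
    pieces <- lapply(seq_len(nrow(genome)), function(i) {
      len <- genome$length[i]
      n_max <- ceiling(len / mean_spacing * 3) + 10
      gaps <- stats::rexp(n_max, rate = 1 / (mean_spacing - probe_length))
      starts <- cumsum(gaps + probe_length) - probe_length
      starts <- floor(starts[starts + probe_length <= len])
      if (length(starts) == 0) {
        .warnf("no probes fit on chromosome %s (length %g < spacing %g)",
               genome$chrom[i], len, mean_spacing)
        return(NULL)
      }
      data.frame(chrom = genome$chrom[i], start = starts,
                 end = starts + probe_length, stringsAsFactors = FALSE)
    })
    pm <- do.call(rbind, pieces)
    if (is.null(pm)) pm <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric())
    pm <- pm[order(match(pm$chrom, genome$chrom), pm$start), , drop = FALSE]
    pm <- data.frame(probe_id = sprintf("P%06d", seq_len(nrow(pm))), pm,
                     stringsAsFactors = FALSE)
    rownames(pm) <- NULL
    attr(pm, "genome") <- genome
    class(pm) <- c("probe_map", "data.frame")
    pm
  })
}

#' Simulate ground-truth copy-number segments
#'
#' Places non-overlapping aberrant segments per sample, with sizes drawn
#' log-uniformly within `size_range` and integer copy states drawn from
#' `state_weights`. The baseline (copy-neutral) state is never emitted.
#' `expected_log2 = log2(copy_state / ploidy)`, floored at `log2_floor`
#' for homozygous deletions (log2 of zero copies saturates on real arrays).
#'
#' @param genome a [genome_spec()].
#' @param n_segments number of segments per sample.
#' @param size_range numeric length-2, segment size range in bp.
#' @param state_weights named numeric of placement probabilities per copy
#'   state (names are states, all different from the baseline); the default
#'   is loss-heavy, mirroring the loss/gain imbalance typical of aCGH calls.
#' @param sample_ids character vector of samples to simulate.
#' @param seed integer seed.
#' @param log2_floor expected log2 for copy 0 (default -4).
#' @param min_gap minimum separation in bp between segments of one
#'   sample (default 0 = non-overlapping only). Recovery benchmarks use
#'   a buffer of several probe intervals so that per-segment breakpoint
#'   attribution is well-defined (two same-direction segments a couple
#'   of probes apart are indistinguishable from one).
#' @param max_tries placement retries per segment before failing.
#' @return data.frame: `sample_id`, `chrom`, `start`, `end`, `copy_state`,
#'   `expected_log2`.
#' @export
simulate_truth <- function(genome, n_segments, size_range = c(7020, 2635290),
                           state_weights = c("1" = 0.66, "0" = 0.06,
                                             "3" = 0.22, "4" = 0.06),
                           sample_ids = "S1", seed = 1L, log2_floor = -4,
                           min_gap = 0, max_tries = 200L) {
  stopifnot(inherits(genome, "genome_spec"))
  ploidy <- attr(genome, "ploidy")
  states <- as.integer(names(state_weights))
  if (any(states == ploidy)) .stopf("state_weights must exclude the baseline state")
  if (abs(sum(state_weights) - 1) > 1e-8)
    .stopf("state_weights must sum to 1")
  .with_seed(seed, {
    out <- vector("list", length(sample_ids))
    for (s in seq_along(sample_ids)) {
      placed <- data.frame(chrom = character(), start = numeric(),
                           end = numeric())
      segs <- vector("list", n_segments)
      for (k in seq_len(n_segments)) {
        ok <- FALSE
        chrom <- NA_character_
        for (try in seq_len(max_tries)) {
          ci <- sample.int(nrow(genome), 1, prob = genome$length)
          chrom <- genome$chrom[ci]
          size <- round(exp(stats::runif(1, log(size_range[1]),
                                         log(min(size_range[2],
                                                 genome$length[ci])))))
          size <- min(size, genome$length[ci])
          start <- floor(stats::runif(1, 0, genome$length[ci] - size + 1))
          end <- start + size
          same <- placed[placed$chrom == chrom, , drop = FALSE]
          if (!any(start < same$end + min_gap &
                     same$start - min_gap < end)) { ok <- TRUE; break }
        }
        if (!ok)
          .stopf("could not place a non-overlapping segment (last tried chromosome %s)",
                 chrom)
        state <- sample(states, 1, prob = state_weights)
        el2 <- if (state == 0) log2_floor else log2(state / ploidy)
        placed <- rbind(placed, data.frame(chrom = chrom, start = start,
                                           end = end))
        segs[[k]] <- data.frame(sample_id = sample_ids[s], chrom = chrom,
                                start = start, end = end, copy_state = state,
                                expected_log2 = el2, stringsAsFactors = FALSE)
      }
      out[[s]] <- do.call(rbind, segs)
    }
    truth <- do.call(rbind, out)
    if (is.null(truth))
      truth <- data.frame(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          copy_state = integer(), expected_log2 = numeric())
    rownames(truth) <- NULL
    truth
  })
}

# expected log2 per probe given truth segments (probe midpoint containment)
.expected_log2 <- function(probe_map, truth) {
  e <- numeric(nrow(probe_map))
  if (is.null(truth) || nrow(truth) == 0) return(e)
  mid <- (probe_map$start + probe_map$end) / 2
  for (i in seq_len(nrow(truth))) {
    hit <- probe_map$chrom == truth$chrom[i] &
      mid >= truth$start[i] & mid < truth$end[i]
    e[hit] <- truth$expected_log2[i]
  }
  e
}

# shared track construction given per-probe expected log2
.make_track <- function(probe_map, expected, noise, sample_id) {
  n <- nrow(probe_map)
  .with_seed(noise$seed, {
    int_ref <- stats::rlnorm(n, meanlog = log(1000), sdlog = 0.4)
    snr_test <- stats::rlnorm(n, meanlog = log(120), sdlog = 0.3)
    snr_ref <- stats::rlnorm(n, meanlog = log(120), sdlog = 0.3)
    a_raw <- log2(int_ref) + expected / 2
    wave <- if (noise$wave_amplitude > 0)
      noise$wave_amplitude * sin(2 * pi * probe_map$start / noise$wave_period)
    else 0
    bias <- if (noise$dye_bias_slope != 0)
      noise$dye_bias_slope * (a_raw - mean(a_raw))
    else 0
    log2r <- expected + stats::rnorm(n, 0, noise$probe_sd) + wave + bias
    int_test <- int_ref * 2^log2r
    # engineer QC failures on a random subset
    n_fail <- round(noise$qc_fail_frac * n)
    if (n_fail > 0) {
      idx <- sample.int(n, n_fail)
      half <- idx[seq_len(floor(n_fail / 2))]
      int_test[half] <- stats::runif(length(half), 5, 45)
      snr_ref[setdiff(idx, half)] <- stats::runif(n_fail - length(half), 2, 20)
    }
    new_ratio_track(sample_id = sample_id, probe_map = probe_map,
                    log2_ratio = log2r, intensity_test = int_test,
                    intensity_ref = int_ref, snr_test = snr_test,
                    snr_ref = snr_ref)
  })
}

#' Simulate a noisy log2-ratio track
#'
#' Per-probe log2 ratio = expected log2 of the covering truth segment (zero
#' outside any segment) + Gaussian probe noise + optional sinusoidal wave +
#' optional intensity-dependent dye bias. Test/reference intensities and
#' signal-to-noise values are emitted so the QC filter path is exercisable.
#'
#' @param probe_map a [simulate_probe_map()] result.
#' @param truth data.frame from [simulate_truth()] (may be empty for a
#'   pure-noise track); rows for other samples are ignored.
#' @param noise a [noise_spec()].
#' @param sample_id sample label for the track.
#' @return a `ratio_track`.
#' @export
simulate_ratio_track <- function(probe_map, truth = NULL,
                                 noise = noise_spec(), sample_id = "S1") {
  stopifnot(inherits(probe_map, "probe_map"))
  if (!is.null(truth) && nrow(truth) > 0) {
    if ("sample_id" %in% names(truth))
      truth <- truth[truth$sample_id == sample_id | is.na(truth$sample_id), ,
                     drop = FALSE]
    g <- attr(probe_map, "genome")
    if (!is.null(g)) {
      len <- g$length[match(truth$chrom, g$chrom)]
      if (any(is.na(len)) || any(truth$end > len) || any(truth$start < 0))
        .stopf("truth segments fall outside the probe map's genome")
    }
  }
  .make_track(probe_map, .expected_log2(probe_map, truth), noise, sample_id)
}

#' Simulate a sex-mismatched hybridization
#'
#' Emulates a male test sample against a female reference: chrX probes are
#' centered at log2 = -1 (one copy vs two), chrY probes (if present on the
#' map) at a configurable gain level, autosomes at 0. Used as a built-in
#' false-positive control: every genuine chrX call should be a loss and
#' every chrY call a gain.
#'
#' @inheritParams simulate_ratio_track
#' @param x_chrom,y_chrom chromosome names treated as X and Y.
#' @param y_log2 expected log2 on chrY (default +1).
#' @return a `ratio_track`.
#' @export
simulate_sex_mismatch <- function(probe_map, noise = noise_spec(),
                                  sample_id = "male_vs_female",
                                  x_chrom = "X", y_chrom = "Y", y_log2 = 1) {
  stopifnot(inherits(probe_map, "probe_map"))
  if (!any(probe_map$chrom == x_chrom))
    .stopf("probe map has no chromosome designated X (%s)", x_chrom)
  expected <- numeric(nrow(probe_map))
  expected[probe_map$chrom == x_chrom] <- -1
  expected[probe_map$chrom == y_chrom] <- y_log2
  .make_track(probe_map, expected, noise, sample_id)
}

#' Simulate a qPCR Ct table
#'
#' Generates duplicate-well cycle-threshold values consistent with integer
#' copy states: `Ct = const - log_efficiency(copy) + noise`, with a
#' single-copy-per-haploid control amplicon at baseline copy in every
#' sample. A target overlapping no truth segment of a sample amplifies at
#' baseline copy. Copy 0 is floored at `ploidy * 2^-4` (residual
#' amplification), matching the log2 saturation used by the track simulator.
#'
#' @param truth truth segments ([simulate_truth()]).
#' @param targets data.frame `target_id`, `chrom`, `start`, `end`.
#' @param sample_ids test samples to assay.
#' @param reference_sample reference sample id (baseline copy everywhere).
#' @param efficiency amplification factor per cycle, in [1.9, 2.1].
#' @param ct_sd per-well Ct noise SD in cycles.
#' @param n_wells replicate wells per (sample, amplicon) (default 2).
#' @param ploidy baseline copy number.
#' @param seed integer seed.
#' @return a `ct_table` data.frame (`sample_id`, `target_id`, `well`, `ct`)
#'   with attributes `reference_sample` and `control_target`.
#' @export
simulate_qpcr <- function(truth, targets, sample_ids, reference_sample = "REF",
                          efficiency = 2, ct_sd = 0.1, n_wells = 2L,
                          ploidy = 2L, seed = 1L) {
  if (efficiency < 1.9 || efficiency > 2.1)
    .stopf("efficiency must lie in [1.9, 2.1]")
  control_id <- "GCG"
  all_samples <- unique(c(sample_ids, reference_sample))
  copy_at <- function(sample, tgt) {
    tr <- truth[truth$sample_id == sample & truth$chrom == tgt$chrom &
                  truth$start < tgt$end & tgt$start < truth$end, , drop = FALSE]
    if (sample == reference_sample || nrow(tr) == 0) return(ploidy)
    tr$copy_state[which.max(pmin(tr$end, tgt$end) - pmax(tr$start, tgt$start))]
  }
  .with_seed(seed, {
    rows <- list()
    for (s in all_samples) {
      for (ti in seq_len(nrow(targets))) {
        tgt <- targets[ti, ]
        cn <- max(copy_at(s, tgt), ploidy * 2^-4)
        ct0 <- 24 - log(cn) / log(efficiency)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, target_id = tgt$target_id,
          well = seq_len(n_wells),
          ct = ct0 + stats::rnorm(n_wells, 0, ct_sd),
          stringsAsFactors = FALSE)
      }
      ctc <- 20 - log(ploidy) / log(efficiency)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, target_id = control_id, well = seq_len(n_wells),
        ct = ctc + stats::rnorm(n_wells, 0, ct_sd), stringsAsFactors = FALSE)
    }
    ct <- do.call(rbind, rows)
    rownames(ct) <- NULL
    attr(ct, "reference_sample") <- reference_sample
    attr(ct, "control_target") <- control_id
    class(ct) <- c("ct_table", "data.frame")
    ct
  })
}
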