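# Probe-level preprocessing ahead of segmentation: QC filtering on
# intensity and signal-to-noise, LOWESS intensity normalization, robust
# noise estimation from the derivative log-ratio spread (DLRS), and mode
# centralization so the copy-neutral state sits at log2 = 0.

#' QC-filter a ratio track
#'
#' A probe passes iff both channels have intensity strictly above
#' `min_intensity` and signal-to-noise strictly above `min_snr`, and its
#' log2 ratio is present. Failing probes are excluded from all downstream
#' statistics but retained in the track (and its row count). Idempotent.
#'
#' @param track a `ratio_track`.
#' @param min_intensity minimum intensity, both channels (default 50).
#' @param min_snr minimum signal-to-noise ratio, both channels (default 25).
#' @return the track with `qc_pass` set.
#' @export
qc_filter <- function(track, min_intensity = 50, min_snr = 25) {
  stopifnot(inherits(track, "ratio_track"))
  pass <- track$intensity_test > min_intensity &
    track$intensity_ref > min_intensity &
    track$snr_test > min_snr & track$snr_ref > min_snr &
    is.finite(track$log2_ratio)
  pass[is.na(pass)] <- FALSE
  if (!any(pass))
    .stopf("all %d probes fail QC on sample %s: array not interpretable",
           length(pass), track$sample_id)
  track$qc_pass <- pass
  message(sprintf("QC %s: %d/%d probes retained", track$sample_id,
                  sum(pass), length(pass)))
  track
}

#' LOWESS intensity normalization
#'
#' Fits a locally weighted regression of log2 ratio on mean log2 intensity
#' (A = (log2 test + log2 reference)/2) over QC-passing probes and
#' subtracts the fitted trend, removing intensity-dependent dye bias.
#' Probe order and count are unchanged.
#'
#' @param track a QC-filtered `ratio_track`.
#' @param span LOWESS smoother span (default 0.3).
#' @return the normalized track.
#' @export
lowess_normalize <- function(track, span = 0.3) {
  stopifnot(inherits(track, "ratio_track"))
  ok <- track$qc_pass & is.finite(track$log2_ratio)
  if (sum(ok) < 50)
    .stopf("fewer than 50 QC-passing probes on %s: cannot normalize",
           track$sample_id)
  a <- (log2(track$intensity_test) + log2(track$intensity_ref)) / 2
  fit <- stats::lowess(a[ok], track$log2_ratio[ok], f = span)
  trend <- stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
  track$log2_ratio <- track$log2_ratio - trend
  track
}

#' Estimate probe noise by derivative log-ratio spread
#'
#' noise_sigma = median(|successive log2 differences within chromosomes|)
#' / (0.6745 * sqrt(2)); robust to aberrant segments since only their two
#' boundary differences are affected. Invariant to adding a constant.
#' A zero estimate (constant track) is replaced by a small floor.
#'
#' @param track a `ratio_track` (QC applied).
#' @param floor minimum allowed sigma (default 1e-3).
#' @return the track with `noise_sigma` filled in.
#' @export
estimate_noise <- function(track, floor = 1e-3) {
  stopifnot(inherits(track, "ratio_track"))
  ok <- track$qc_pass & is.finite(track$log2_ratio)
  diffs <- unlist(lapply(split(track$log2_ratio[ok], track$probe_map$chrom[ok]),
                         diff), use.names = FALSE)
  if (length(diffs) < 1)
    .stopf("need >= 2 passing probes on some chromosome to estimate noise")
  sigma <- stats::median(abs(diffs)) / (0.6745 * sqrt(2))
  if (sigma <= 0) {
    .warnf("zero derivative spread on %s; using noise floor %g",
           track$sample_id, floor)
    sigma <- floor
  }
  track$noise_sigma <- sigma
  track
}

# Locate the dominant (copy-neutral) state: the highest-density
# histogram bin picks the state, and the median of the probes within
# +-window of that bin refines the shift. The histogram alone cannot do
# better than ~2-3 bin widths on a flat Gaussian peak; the local median
# is symmetric around the neutral state, excludes aberrant states (the
# nearest, a single-copy gain, sits ~0.585 away), and converges at
# ~sigma/sqrt(n).
.histogram_mode <- function(x, bin_width, window = 0.25) {
  breaks <- seq(floor(min(x) / bin_width) * bin_width,
                max(x) + bin_width, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  counts <- h$counts
  top <- which(counts == max(counts))
  if (length(top) > 1) {
    .warnf("multimodal centering tie; choosing the smaller shift")
    top <- top[which.min(abs(h$mids[top]))]
  }
  mid <- h$mids[top]
  stats::median(x[abs(x - mid) <= window])
}

#' Centralize a ratio track on its copy-neutral mode
#'
#' Subtracts the location of the dominant copy-neutral state so it sits
#' at 0, iterating until the shift is below `tol`. The state is located
#' by the highest-density histogram bin and the shift refined as the
#' median of probes within a window (+-0.25 log2) of that bin — the
#' nearest aberrant state, a single-copy gain, is ~0.585 away. Before
#' the mode is computed, aberrant intervals with |interval score| at or
#' above `mask_threshold` are masked so strong aberrations cannot drag
#' the baseline. The cumulative shift is recorded in `centering_shift`.
#'
#' When more than half of the probes are masked as aberrant the mode may
#' track an aberrant state; a warning is emitted.
#'
#' @param track a track with noise estimated.
#' @param bin_width histogram bin width in log2 units (default 0.01).
#' @param max_iter maximum centering iterations.
#' @param tol convergence tolerance on the per-iteration shift.
#' @param mask_threshold |score| at which intervals are masked before the
#'   mode is computed (default 6, the aberration-detection threshold).
#' @return the centralized track.
#' @export
centralize <- function(track, bin_width = 0.01, max_iter = 10, tol = 1e-3,
                       mask_threshold = 6) {
  stopifnot(inherits(track, "ratio_track"))
  if (is.null(track$noise_sigma))
    .stopf("estimate_noise() must run before centralize()")
  total <- 0
  for (iter in seq_len(max_iter)) {
    mask <- rep(FALSE, length(track$log2_ratio))
    segs <- tryCatch(detect_aberrations(track, threshold = mask_threshold),
                     error = function(e) NULL)
    if (!is.null(segs) && nrow(segs) > 0) {
      for (i in seq_len(nrow(segs))) {
        mask <- mask | (track$probe_map$chrom == segs$chrom[i] &
                          track$probe_map$start >= segs$start[i] &
                          track$probe_map$end <= segs$end[i])
      }
    }
    ok <- track$qc_pass & is.finite(track$log2_ratio) & !mask
    if (mean(mask[track$qc_pass]) > 0.5) {
      .warnf("more than half of %s is called aberrant; centering may track an aberrant state",
             track$sample_id)
      ok <- track$qc_pass & is.finite(track$log2_ratio)
    }
    shift <- .histogram_mode(track$log2_ratio[ok], bin_width)
    track$log2_ratio <- track$log2_ratio - shift
    total <- total + shift
    if (abs(shift) < tol) break
  }
  track$centering_shift <- total
  track
}

#' Run the full preprocessing chain
#'
#' QC filter, LOWESS normalization, DLRS noise estimation, and mode
#' centralization, in that order.
#'
#' @inheritParams qc_filter
#' @inheritParams lowess_normalize
#' @param ... passed to [centralize()].
#' @return a preprocessed `ratio_track`.
#' @export
preprocess_track <- function(track, min_intensity = 50, min_snr = 25,
                             span = 0.3, ...) {
  track <- qc_filter(track, min_intensity, min_snr)
  track <- lowess_normalize(track, span)
  track <- estimate_noise(track)
  centralize(track, ...)
}
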