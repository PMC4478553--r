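# ratio_track: one sample's probe-level aCGH measurements aligned to a
# probe map, plus the preprocessing state (QC flags, noise estimate,
# cumulative centering shift).

new_ratio_track <- function(sample_id, probe_map, log2_ratio,
                            intensity_test, intensity_ref,
                            snr_test, snr_ref,
                            qc_pass = rep(TRUE, nrow(probe_map)),
                            noise_sigma = NULL, centering_shift = 0) {
  n <- nrow(probe_map)
  lens <- c(length(log2_ratio), length(intensity_test), length(intensity_ref),
            length(snr_test), length(snr_ref), length(qc_pass))
  if (any(lens != n))
    .stopf("track arrays must all have the probe map's length (%d)", n)
  structure(list(sample_id = sample_id, probe_map = probe_map,
                 log2_ratio = as.numeric(log2_ratio),
                 intensity_test = as.numeric(intensity_test),
                 intensity_ref = as.numeric(intensity_ref),
                 snr_test = as.numeric(snr_test),
                 snr_ref = as.numeric(snr_ref),
                 qc_pass = as.logical(qc_pass),
                 noise_sigma = noise_sigma,
                 centering_shift = centering_shift),
            class = "ratio_track")
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("ratio_track '%s': %d probes on %d chromosome(s)\n",
              x$sample_id, length(x$log2_ratio),
              length(unique(x$probe_map$chrom))))
  cat(sprintf("  QC pass: %d/%d; noise sigma: %s; centering shift: %.4g\n",
              sum(x$qc_pass, na.rm = TRUE), length(x$qc_pass),
              if (is.null(x$noise_sigma)) "not estimated"
              else sprintf("%.4f", x$noise_sigma),
              x$centering_shift))
  invisible(x)
}

#' @export
summary.ratio_track <- function(object, ...) {
  ok <- object$qc_pass & is.finite(object$log2_ratio)
  out <- list(sample_id = object$sample_id,
              n_probes = length(object$log2_ratio),
              n_pass = sum(ok),
              log2_summary = summary(object$log2_ratio[ok]),
              noise_sigma = object$noise_sigma,
              centering_shift = object$centering_shift)
  class(out) <- "summary.ratio_track"
  out
}

#' @export
print.summary.ratio_track <- function(x, ...) {
  cat(sprintf("ratio_track '%s': %d probes, %d passing QC\n",
              x$sample_id, x$n_probes, x$n_pass))
  print(x$log2_summary)
  invisible(x)
}

#' Plot a ratio track along the genome
#'
#' @param x a `ratio_track`.
#' @param chrom optional chromosome to restrict to.
#' @param calls optional CNV call data.frame to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ratio_track <- function(x, chrom = NULL, calls = NULL, ...) {
  keep <- if (is.null(chrom)) rep(TRUE, nrow(x$probe_map))
          else x$probe_map$chrom == chrom
  pos <- x$probe_map$start[keep]
  graphics::plot(pos, x$log2_ratio[keep], pch = ".", cex = 2,
                 xlab = "position (bp)", ylab = "log2 ratio",
                 main = x$sample_id, ...)
  graphics::abline(h = 0, col = "grey60")
  if (!is.null(calls) && nrow(calls) > 0) {
    cc <- if (is.null(chrom)) calls else calls[calls$chrom == chrom, ]
    graphics::segments(cc$start, cc$mean_log2, cc$end, cc$mean_log2,
                       col = ifelse(cc$direction == "gain", "red3", "blue3"),
                       lwd = 2)
  }
  invisible(x)
}
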