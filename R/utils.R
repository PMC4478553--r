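# Shared helpers: chromosome-name normalization, coordinate conventions,
# and interval <-> GRanges conversion. Internal coordinates are 0-based
# half-open everywhere; 1-based inclusive appears only at report boundaries.

#' Normalize chromosome names
#'
#' Strips a leading "chr"/"Chr." prefix so that mixed styles ("chr4",
#' "Chr.4", "4") compare equal internally. The prefix is re-added on BED
#' export.
#'
#' @param x character vector of chromosome names.
#' @return character vector of bare chromosome names.
#' @export
norm_chrom <- function(x) {
  sub("^[Cc]hr\\.?", "", as.character(x))
}

# internal: 0-based half-open data.frame -> GRanges (1-based closed)
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = norm_chrom(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Convert internal coordinates to 1-based inclusive for reporting
#'
#' @param df data.frame with `start`, `end` in 0-based half-open convention.
#' @return the same data.frame with `start` shifted to 1-based inclusive.
#' @export
to_one_based <- function(df) {
  df$start <- df$start + 1L
  df
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# seeded RNG scope: run expr with a local seed without disturbing global state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
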