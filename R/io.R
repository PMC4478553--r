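# Readers and writers for every on-disk format the workflow touches:
# tab-delimited probe ratio tables, BED intervals, GFF-like gene
# annotation, and CSV qPCR Ct tables. Internal coordinates are 0-based
# half-open; BED is written as-is, 1-based inclusive only in the optional
# report companion.

.ratio_cols <- c("probe_id", "chrom", "start", "end", "intensity_test",
                 "intensity_ref", "snr_test", "snr_ref", "log2_ratio")

#' Read a probe-level ratio table
#'
#' Tab-delimited with a header, `#` comment lines, and columns
#' `probe_id, chrom, start, end, intensity_test, intensity_ref, snr_test,
#' snr_ref, log2_ratio`. An empty `log2_ratio` cell marks a flagged probe
#' (kept in the row count, excluded from downstream statistics).
#'
#' @param path file path.
#' @param sample_id sample label for the returned track (default: file
#'   name without extension).
#' @return list with `probe_map` and `track` (a `ratio_track`).
#' @export
read_ratio_table <- function(path, sample_id = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  missing_cols <- setdiff(.ratio_cols, names(df))
  if (length(missing_cols))
    .stopf("ratio table %s is missing column(s): %s", path,
           paste(missing_cols, collapse = ", "))
  if (nrow(df) > 0) {
    bad <- which(!(df$start < df$end) | df$start < 0)
    if (length(bad))
      .stopf("ratio table %s: invalid coordinates (start >= end or negative) at data row(s) %s",
             path, paste(bad, collapse = ", "))
    df$chrom <- norm_chrom(df$chrom)
    ord <- order(df$chrom, df$start)
    if (!identical(ord, seq_len(nrow(df)))) {
      message("ratio table ", path, ": rows were not sorted; sorting by (chrom, start)")
      df <- df[ord, , drop = FALSE]
    }
  }
  pm <- df[, c("probe_id", "chrom", "start", "end")]
  rownames(pm) <- NULL
  class(pm) <- c("probe_map", "data.frame")
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  track <- new_ratio_track(sample_id = sample_id, probe_map = pm,
                           log2_ratio = df$log2_ratio,
                           intensity_test = df$intensity_test,
                           intensity_ref = df$intensity_ref,
                           snr_test = df$snr_test, snr_ref = df$snr_ref,
                           qc_pass = is.finite(df$log2_ratio))
  list(probe_map = pm, track = track)
}

#' Write a ratio track to the tab-delimited dialect
#'
#' @param track a `ratio_track`.
#' @param path output path.
#' @export
write_ratio_table <- function(track, path) {
  df <- data.frame(track$probe_map[, c("probe_id", "chrom", "start", "end")],
                   intensity_test = track$intensity_test,
                   intensity_ref = track$intensity_ref,
                   snr_test = track$snr_test, snr_ref = track$snr_ref,
                   log2_ratio = track$log2_ratio)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# aCGH ratio table, sample %s", track$sample_id), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write intervals as BED
#'
#' Internal coordinates are already BED-native (0-based half-open). A
#' leading "chr" is re-added to chromosome names on export. Optionally a
#' companion tab-delimited report with 1-based inclusive coordinates (the
#' convention of printed tables) is written next to the BED.
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optional
#'   `name`/`id` and `score` columns.
#' @param path output BED path.
#' @param one_based_report if TRUE, also write `<path>.1based.tsv` with
#'   1-based inclusive coordinates.
#' @export
write_bed <- function(regions, path, one_based_report = FALSE) {
  if (nrow(regions) > 0 && any(regions$start < 0 | regions$end < 0))
    .stopf("negative coordinates cannot be written as BED")
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  if (nrow(regions) == 0) {
    writeLines("# BED 0-based half-open", path)
    if (one_based_report)
      utils::write.table(to_one_based(regions), paste0(path, ".1based.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  name <- if ("name" %in% names(regions)) regions$name
          else if ("id" %in% names(regions)) regions$id
          else sprintf("region_%d", seq_len(nrow(regions)))
  score <- if ("score" %in% names(regions)) regions$score
           else rep(0, nrow(regions))
  bed <- data.frame(chrom = paste0("chr", norm_chrom(regions$chrom)),
                    start = format(regions$start, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE),
                    name = name, score = score)
  con <- file(path, "w")
  writeLines("# BED 0-based half-open", con)
  if (nrow(bed) > 0)
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  close(con)
  if (one_based_report) {
    rep_path <- paste0(path, ".1based.tsv")
    rep <- to_one_based(regions)
    utils::write.table(rep, rep_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a BED file into internal interval convention
#'
#' @param path BED path (3-6 columns, `#` comments allowed).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open) plus
#'   `name`/`score` when present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  parts <- strsplit(lines, "\t")
  ncol <- min(lengths(parts))
  df <- data.frame(chrom = norm_chrom(vapply(parts, `[`, "", 1)),
                   start = as.numeric(vapply(parts, `[`, "", 2)),
                   end = as.numeric(vapply(parts, `[`, "", 3)))
  if (ncol >= 4) df$name <- vapply(parts, `[`, "", 4)
  if (ncol >= 5) df$score <- as.numeric(vapply(parts, `[`, "", 5))
  df[order(df$chrom, df$start), , drop = FALSE]
}

.biotype_map <- function(x) {
  x <- tolower(x)
  out <- rep("other", length(x))
  out[grepl("pseudo", x)] <- "pseudo"
  out[x %in% c("protein_coding", "protein-coding")] <- "protein_coding"
  out[grepl("miscrna", x)] <- "miscRNA"
  out[is.na(x) | !nzchar(x)] <- "other"
  out
}

#' Read gene annotation
#'
#' Supports a BED dialect (columns chrom, start, end, gene_id, optional
#' biotype in column 5) and a GFF-like dialect (9 columns, attributes
#' carrying `gene_id` and `gene_biotype`). Biotypes are mapped onto
#' \{protein_coding, pseudo, miscRNA, other\} and default to "other" when
#' absent. Overlapping genes are allowed.
#'
#' @param path annotation path.
#' @param format "bed" or "gff_like".
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `biotype`
#'   (0-based half-open).
#' @export
read_gene_annotation <- function(path, format = c("bed", "gff_like")) {
  format <- match.arg(format)
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    parts <- strsplit(lines, "\t")
    if (length(parts) == 0)
      return(data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        biotype = character()))
    nc <- min(lengths(parts))
    genes <- data.frame(
      gene_id = if (nc >= 4) vapply(parts, `[`, "", 4)
                else sprintf("gene_%d", seq_along(parts)),
      chrom = norm_chrom(vapply(parts, `[`, "", 1)),
      start = as.numeric(vapply(parts, `[`, "", 2)),
      end = as.numeric(vapply(parts, `[`, "", 3)),
      # column 5 carries the biotype in this dialect
      biotype = if (nc >= 5) .biotype_map(vapply(parts, `[`, "", 5))
                else "other",
      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    parts <- strsplit(lines, "\t")
    if (length(parts) && any(lengths(parts) < 9))
      .stopf("gff_like annotation %s: expected 9 tab-separated columns", path)
    attr_field <- vapply(parts, `[`, "", 9)
    get_attr <- function(key) {
      m <- regmatches(attr_field,
                      regexpr(paste0(key, "=[^;]+"), attr_field))
      out <- rep(NA_character_, length(attr_field))
      hit <- grepl(paste0(key, "="), attr_field)
      out[hit] <- sub(paste0(key, "="), "",
                      regmatches(attr_field,
                                 regexpr(paste0(key, "=[^;]+"), attr_field)))
      out
    }
    ids <- get_attr("gene_id")
    ids[is.na(ids)] <- sprintf("gene_%d", which(is.na(ids)))
    genes <- data.frame(gene_id = ids,
                        chrom = norm_chrom(vapply(parts, `[`, "", 1)),
                        start = as.numeric(vapply(parts, `[`, "", 4)) - 1,
                        end = as.numeric(vapply(parts, `[`, "", 5)),
                        biotype = .biotype_map(get_attr("gene_biotype")))
  }
  if (any(genes$start >= genes$end))
    .stopf("gene annotation %s: start >= end", path)
  rownames(genes) <- NULL
  genes[order(genes$chrom, genes$start), , drop = FALSE]
}

#' Read a qPCR Ct table
#'
#' CSV with columns `sample_id`, `target_id`, `well`, `ct`. "Undetermined"
#' wells are parsed as missing and flagged with a warning; negative Ct
#' values are rejected.
#'
#' @param path CSV path.
#' @param reference_sample reference sample id stored on the table.
#' @param control_target control amplicon id stored on the table.
#' @return a `ct_table` data.frame.
#' @export
read_ct_table <- function(path, reference_sample = NULL,
                          control_target = "GCG") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target_id", "well", "ct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    .stopf("Ct table %s is missing column(s): %s", path,
           paste(missing_cols, collapse = ", "))
  undet <- toupper(trimws(as.character(df$ct))) %in%
    c("UNDETERMINED", "UNDET", "NA", "")
  df$ct <- suppressWarnings(as.numeric(df$ct))
  df$ct[undet] <- NA_real_
  if (any(undet))
    .warnf("%d well(s) with undetermined Ct flagged as missing", sum(undet))
  if (any(df$ct < 0, na.rm = TRUE)) .stopf("negative Ct values in %s", path)
  pairs <- unique(df[, c("sample_id", "target_id")])
  wells <- table(paste(df$sample_id, df$target_id))
  if (any(wells < 1)) .stopf("every (sample, target) pair needs >= 1 well")
  attr(df, "reference_sample") <- reference_sample
  attr(df, "control_target") <- control_target
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Write a qPCR Ct table as CSV
#'
#' @param ct a `ct_table`.
#' @param path output path.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.csv(as.data.frame(ct)[, c("sample_id", "target_id", "well", "ct")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
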