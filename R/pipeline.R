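# End-to-end orchestration: simulate -> preprocess -> call -> merge ->
# validate -> cluster -> report, from a single seeded configuration. The
# pipeline is exactly the composition of the module functions; every
# stage is independently invokable.

#' Default pipeline configuration
#'
#' All module parameters with their standard defaults (detection
#' threshold 6, post-filter 5 probes / 0.5 log ratio, QC intensity > 50
#' and SNR > 25), a two-chromosome desk-scale genome, and 12 simulated
#' test samples.
#'
#' @param ... overrides for any top-level field.
#' @return a named config list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    genome = list(chrom = c("1", "X"), length = c(20e6, 10e6)),
    ploidy = 2L,
    n_samples = 12L,
    mean_spacing = 2632, probe_length = 60,
    n_segments = 8L, size_range = c(2e4, 1e6),
    probe_sd = 0.15, wave_amplitude = 0, dye_bias_slope = 0,
    qc_fail_frac = 0.01,
    min_intensity = 50, min_snr = 25, lowess_span = 0.3,
    threshold = 6, fuzzy_zero_frac = 0.2, mode = "exact", bin = 10,
    min_probes = 5, min_abs_log2 = 0.5,
    n_sex_mismatch = 2L,
    qpcr_targets = 8L, ct_sd = 0.1, efficiency = 2,
    gain_cutoff = 1.4, loss_cutoff = 0.7,
    metric = "jaccard", n_boot = 200L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return a config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  base[names(user)] <- user
  base
}

.validate_config <- function(cfg) {
  if (cfg$threshold <= 0) .stopf("config: threshold must be positive")
  if (cfg$min_probes < 1) .stopf("config: min_probes must be >= 1")
  if (cfg$n_samples < 1) .stopf("config: n_samples must be >= 1")
  if (cfg$probe_sd <= 0) .stopf("config: probe_sd must be positive")
  invisible(cfg)
}

#' Run the full aCGH CNV workflow on simulated data
#'
#' Simulates a shared probe map and per-sample truth tracks, preprocesses
#' and segments every sample, merges calls into a CNVR catalog,
#' summarizes it, measures the sex-mismatch false-positive rate on
#' simulated male-vs-female arrays, runs a qPCR confirmation round at a
#' set of assayed truth regions, clusters samples on CNVR carrier
#' status, and (when `out_dir` is set) writes per-sample call BEDs, the
#' catalog, the dendrogram (Newick), the resolved configuration, and a
#' machine-readable JSON summary. Identical config + seed gives
#' identical outputs.
#'
#' @param config a config list ([default_config()] / [read_config()]).
#' @return a `cnv_pipeline_run` list with all stage outputs and the
#'   headline `summary` list.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- .validate_config(config)
  genome <- genome_spec(cfg$genome$chrom, cfg$genome$length, cfg$ploidy)
  pm <- simulate_probe_map(genome, cfg$mean_spacing, cfg$probe_length,
                           seed = cfg$seed)
  sample_ids <- sprintf("S%02d", seq_len(cfg$n_samples))
  truth <- simulate_truth(genome, cfg$n_segments, cfg$size_range,
                          sample_ids = sample_ids, seed = cfg$seed + 1)
  calls_by_sample <- vector("list", cfg$n_samples)
  tracks <- vector("list", cfg$n_samples)
  for (s in seq_len(cfg$n_samples)) {
    noise <- noise_spec(probe_sd = cfg$probe_sd,
                        wave_amplitude = cfg$wave_amplitude,
                        dye_bias_slope = cfg$dye_bias_slope,
                        qc_fail_frac = cfg$qc_fail_frac,
                        seed = cfg$seed + 100 + s)
    tr <- simulate_ratio_track(pm, truth, noise, sample_id = sample_ids[s])
    tr <- suppressMessages(preprocess_track(tr, cfg$min_intensity,
                                            cfg$min_snr, cfg$lowess_span))
    tracks[[s]] <- tr
    calls_by_sample[[s]] <- call_cnvs(tr, threshold = cfg$threshold,
                                      min_probes = cfg$min_probes,
                                      min_abs_mean = cfg$min_abs_log2,
                                      fuzzy_zero_frac = cfg$fuzzy_zero_frac,
                                      mode = cfg$mode, bin = cfg$bin)
  }
  calls <- do.call(rbind, calls_by_sample)
  catalog <- merge_cnvrs(calls, n_test_samples = cfg$n_samples)
  catalog_summary <- summarize_catalog(catalog, genome)

  # sex-mismatch false-positive control arrays
  fpr_calls <- list()
  for (a in seq_len(cfg$n_sex_mismatch)) {
    noise <- noise_spec(probe_sd = cfg$probe_sd,
                        qc_fail_frac = cfg$qc_fail_frac,
                        seed = cfg$seed + 900 + a)
    sm <- simulate_sex_mismatch(pm, noise, sample_id = sprintf("XY%d", a))
    sm <- suppressMessages(preprocess_track(sm, cfg$min_intensity,
                                            cfg$min_snr, cfg$lowess_span))
    fpr_calls[[a]] <- call_cnvs(sm, threshold = cfg$threshold,
                                min_probes = cfg$min_probes,
                                min_abs_mean = cfg$min_abs_log2,
                                fuzzy_zero_frac = cfg$fuzzy_zero_frac)
  }
  chrx_len <- genome$length[genome$chrom == "X"]
  fpr <- sex_mismatch_fpr(do.call(rbind, fpr_calls), chrx_length = chrx_len,
                          n_arrays = cfg$n_sex_mismatch)

  # qPCR confirmation at a sample of assayed truth regions
  assayed <- unique(truth[, c("chrom", "start", "end")])
  assayed <- assayed[.with_seed(cfg$seed + 7,
    sample.int(nrow(assayed), min(cfg$qpcr_targets, nrow(assayed)))), ,
    drop = FALSE]
  assayed$target_id <- sprintf("T%02d", seq_len(nrow(assayed)))
  ct <- simulate_qpcr(truth, assayed, sample_ids, reference_sample = "REF",
                      efficiency = cfg$efficiency, ct_sd = cfg$ct_sd,
                      ploidy = cfg$ploidy, seed = cfg$seed + 8)
  qpcr <- do.call(rbind, lapply(seq_len(nrow(assayed)), function(ti) {
    data.frame(target_id = assayed$target_id[ti], sample_id = sample_ids,
               cn_ratio = vapply(sample_ids, function(s)
                 ddct_copy_ratio(ct, assayed$target_id[ti], s), 0),
               stringsAsFactors = FALSE)
  }))
  qpcr$call <- classify_qpcr(qpcr$cn_ratio, cfg$gain_cutoff, cfg$loss_cutoff)

  # CNVR-based clustering
  cluster <- NULL
  if (nrow(catalog) >= 2 && cfg$n_samples >= 2) {
    pmx <- suppressWarnings(presence_matrix(catalog, sample_ids))
    if (length(unique(as.vector(pmx))) > 1)
      cluster <- bootstrap_support(pmx, metric = cfg$metric,
                                   n_boot = cfg$n_boot, seed = cfg$seed + 9)
  }

  summary <- list(
    n_samples = cfg$n_samples,
    n_calls = nrow(calls),
    mean_calls_per_sample = nrow(calls) / cfg$n_samples,
    n_cnvrs = nrow(catalog),
    total_cnvr_mb = catalog_summary$total_length_bp / 1e6,
    mean_cnvr_kb = catalog_summary$mean_length_kb,
    type_pct = as.list(catalog_summary$type_pct),
    sex_mismatch_fpr_pct = fpr$fpr_percent,
    seed = cfg$seed)

  run <- list(config = cfg, genome = genome, probe_map = pm, truth = truth,
              tracks = tracks, calls = calls, catalog = catalog,
              catalog_summary = catalog_summary, fpr = fpr, ct = ct,
              qpcr = qpcr, cluster = cluster, summary = summary)
  class(run) <- "cnv_pipeline_run"
  if (!is.null(cfg$out_dir)) .write_run(run, cfg$out_dir)
  run
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in unique(run$calls$sample_id))
    write_bed(run$calls[run$calls$sample_id == s, ],
              file.path(out_dir, paste0("calls_", s, ".bed")))
  write_bed(as.data.frame(run$catalog),
            file.path(out_dir, "cnvr_catalog.bed"), one_based_report = TRUE)
  utils::write.table(as.data.frame(run$catalog),
                     file.path(out_dir, "cnvr_catalog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(run$cluster))
    export_newick(run$cluster, file.path(out_dir, "dendrogram.nwk"))
  yaml::write_yaml(run$config[!vapply(run$config, is.null, TRUE)],
                   file.path(out_dir, "config_resolved.yaml"))
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.cnv_pipeline_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("aCGH CNV pipeline run (seed %d)\n", s$seed))
  cat(sprintf("  %d samples, %d CNV calls (%.2f per sample)\n",
              s$n_samples, s$n_calls, s$mean_calls_per_sample))
  cat(sprintf("  %d CNVRs covering %.2f Mb (mean %.2f kb)\n",
              s$n_cnvrs, s$total_cnvr_mb, s$mean_cnvr_kb))
  cat(sprintf("  sex-mismatch FPR: %.3f%%\n", s$sex_mismatch_fpr_pct))
  invisible(x)
}
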