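# End-to-end orchestration over the synthetic pipeline: simulate -> offsets
# -> coverage -> pauses -> diff -> enrichment / proteomics, with a manifest
# recording the seed, thresholds and output checksums, and stage-level
# caching keyed on those checksums.

#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline with the standard
#' defaults (trim 0.05, pause threshold 1e-7, FDR 0.05, coherence delta 0.8,
#' peak filter 8-fold / 1e-5, window 30 aa, coverage minimum 1), the
#' simulation configuration, and the global seed. Stage child seeds are
#' derived from the global seed by fixed increments so each stage is locally
#' reproducible.
#'
#' @param sim A \code{\link{sim_config}} describing the synthetic inputs.
#' @param stages Character vector of stages to run, in dependency order.
#' @param trim_frac,pause_threshold,fdr,coherence_delta,peak_fold,peak_p,window,coverage_min
#'   Analysis thresholds; see the stage functions for their meaning.
#' @param n_perm Permutations for the enrichment stage.
#' @param seed Global integer seed.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(sim = sim_config(),
                       stages = c("simulate", "offsets", "coverage",
                                  "pauses", "diff", "enrichment",
                                  "proteomics"),
                       trim_frac = 0.05, pause_threshold = 1e-7,
                       fdr = 0.05, coherence_delta = 0.8,
                       peak_fold = 8, peak_p = 1e-5, window = 30,
                       coverage_min = 1, n_perm = 200, seed = 1L) {
  stopifnot(trim_frac >= 0, trim_frac < 0.5,
            pause_threshold > 0, pause_threshold < 1,
            fdr > 0, fdr < 1, coherence_delta >= 0,
            peak_fold >= 0, peak_p > 0, peak_p <= 1,
            window >= 1, coverage_min >= 0, n_perm >= 1)
  structure(list(sim = sim, stages = stages, trim_frac = trim_frac,
                 pause_threshold = pause_threshold, fdr = fdr,
                 coherence_delta = coherence_delta, peak_fold = peak_fold,
                 peak_p = peak_p, window = window,
                 coverage_min = coverage_min, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_checksum <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [ribopause] ", ...)
}

#' Run the pipeline end to end
#'
#' Executes the configured stages in dependency order, writing each stage's
#' outputs under \code{out_dir} and a \code{manifest.json} recording the
#' package version, seed, effective configuration checksum and per-file md5
#' checksums. Stage inputs are regenerated deterministically from the seed,
#' so a partial run (a subset of \code{stages}) writes outputs identical to
#' the corresponding files of a full run and leaves upstream outputs
#' untouched; reruns with an unchanged configuration reproduce every
#' checksum in the manifest.
#'
#' @param config A \code{\link{run_config}}.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_sum <- config_checksum(config)
  manifest_path <- file.path(out_dir, "manifest.json")

  files <- list()
  results <- list()
  record <- function(stage, outputs) {
    sums <- tools::md5sum(outputs)
    names(sums) <- basename(outputs)
    files[[stage]] <<- as.list(sums)
  }
  fail <- function(stage, err) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }

  sim <- config$sim
  cov_ctl <- cov_kd <- NULL

  # -- simulate ------------------------------------------------------------
  fa <- file.path(out_dir, "transcripts.fa")
  ann <- file.path(out_dir, "transcripts.tsv")
  peaks_path <- file.path(out_dir, "peaks.tsv")
  spectra_path <- file.path(out_dir, "spectra.tsv")
  tryCatch({
    gen <- gen_transcripts(sim)
    results$transcripts <- gen$transcripts
    results$truth <- gen$truth
    if ("simulate" %in% config$stages) {
      write_transcripts(gen$transcripts, fa, ann)
      pk <- gen_peaks(gen$transcripts, gen$truth, sim)
      results$peaks <- pk$peaks
      results$peak_truth <- pk$truth
      write_peaks(pk$peaks, peaks_path)
      sp <- gen_spectra(seed = sim$seed + 5000L)
      results$spectra <- sp
      write_spectra(sp$table, spectra_path)
      jsonlite::write_json(list(seed = sim$seed),
                           file.path(out_dir, "seed.json"),
                           auto_unbox = TRUE)
      record("simulate", c(fa, ann, peaks_path, spectra_path))
      pipeline_log("simulate: ", nrow(gen$transcripts), " transcripts, ",
                   nrow(pk$peaks), " peaks")
    }
    cov_ctl <- gen_coverage(gen$transcripts, gen$truth, sim, "control")
    cov_kd <- gen_coverage(gen$transcripts, gen$truth, sim, "knockdown")
  }, error = function(e) fail("simulate", e))

  # -- offsets -------------------------------------------------------------
  if ("offsets" %in% config$stages) {
    tryCatch({
      fps <- gen_footprints(cov_ctl, results$transcripts, sim)
      off <- estimate_offsets(fps, results$transcripts,
                              length_range = sim$read_len_range)
      results$offsets <- off
      off_path <- file.path(out_dir, "offsets.tsv")
      utils::write.table(data.frame(read_length = names(off$offsets),
                                    offset = unname(off$offsets)),
                         off_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("offsets", off_path)
      pipeline_log("offsets: calibrated ", length(off$offsets), " lengths")
    }, error = function(e) fail("offsets", e))
  }

  # -- coverage ------------------------------------------------------------
  keep <- NULL
  if ("coverage" %in% config$stages) {
    tryCatch({
      keep <- filter_genes(list(cov_ctl, cov_kd),
                           min_coverage = config$coverage_min)
      if (!length(keep)) stop("no gene passes the coverage filter")
      cov_ctl <- subset_coverage(cov_ctl, keep)
      cov_kd <- subset_coverage(cov_kd, keep)
      cov_path <- file.path(out_dir, "coverage_control.tsv")
      write_coverage(cov_ctl, cov_path)
      record("coverage", cov_path)
      results$kept_genes <- keep
      pipeline_log("coverage: ", length(keep), " genes pass filter")
    }, error = function(e) fail("coverage", e))
  }
  results$coverage_control <- cov_ctl
  results$coverage_knockdown <- cov_kd

  # -- pauses --------------------------------------------------------------
  pauses <- NULL
  if ("pauses" %in% config$stages) {
    tryCatch({
      pauses <- call_pauses(cov_ctl, threshold = config$pause_threshold,
                            trim_frac = config$trim_frac)
      results$pauses <- pauses
      pp <- file.path(out_dir, "pauses.tsv")
      write_pauses(pauses, pp)
      record("pauses", pp)
      pipeline_log("pauses: ", sum(pauses$called), " called sites")
    }, error = function(e) fail("pauses", e))
  }

  # -- diff ----------------------------------------------------------------
  if ("diff" %in% config$stages) {
    tryCatch({
      called <- pauses[pauses$called, , drop = FALSE]
      if (nrow(called)) {
        diff <- diff_pause_analysis(called, cov_ctl, cov_kd,
                                    fdr = config$fdr,
                                    coherence_delta = config$coherence_delta)
        results$diff <- diff
        dp <- file.path(out_dir, "diff_pauses.tsv")
        utils::write.table(diff, dp, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        record("diff", dp)
        pipeline_log("diff: ", sum(diff$disposition == "retained"),
                     " retained sites")
      } else {
        pipeline_log("diff: skipped, no called pauses")
      }
    }, error = function(e) fail("diff", e))
  }

  # -- enrichment ----------------------------------------------------------
  if ("enrichment" %in% config$stages) {
    tryCatch({
      sig <- filter_peaks(results$peaks, min_fold = config$peak_fold,
                          max_p = config$peak_p)
      anchors <- peaks_to_anchors(sig, results$transcripts)
      if (!nrow(anchors)) stop("no anchors after peak filtering")
      prof <- positional_enrichment(anchors, results$transcripts,
                                    window = config$window,
                                    n_perm = config$n_perm,
                                    seed = config$seed + 6000L)
      results$enrichment <- prof
      ep <- file.path(out_dir, "enrichment.tsv")
      write_enrichment(prof, ep)
      record("enrichment", ep)
      pipeline_log("enrichment: ", nrow(anchors), " anchors")
    }, error = function(e) fail("enrichment", e))
  }

  # -- proteomics ----------------------------------------------------------
  if ("proteomics" %in% config$stages) {
    tryCatch({
      calls <- call_interactors(results$spectra$table)
      results$interactors <- calls
      ip <- file.path(out_dir, "interactors.tsv")
      utils::write.table(calls, ip, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("proteomics", ip)
      pipeline_log("proteomics: ", sum(calls$high_confidence),
                   " high-confidence interactors")
    }, error = function(e) fail("proteomics", e))
  }

  manifest <- list(package = "ribopause",
                   version = as.character(utils::packageVersion("ribopause")),
                   seed = config$seed,
                   config_checksum = cfg_sum,
                   stages = config$stages,
                   thresholds = list(trim_frac = config$trim_frac,
                                     pause_threshold = config$pause_threshold,
                                     fdr = config$fdr,
                                     coherence_delta = config$coherence_delta,
                                     peak_fold = config$peak_fold,
                                     peak_p = config$peak_p,
                                     window = config$window,
                                     coverage_min = config$coverage_min),
                   files = files)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
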