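# Synthetic-data generator: transcripts with planted charged tracts, NB
# footprint coverage with multiplicative pause sites, a knockdown condition
# that attenuates pauses, crosslink peaks downstream of tract ends, and
# spectral-count tables. Every generator records its ground truth.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# sample() treats a length-1 numeric x as 1:x; this never does
resample <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

# codons (standard code) for each amino acid, stops excluded
codons_for <- function(residue) {
  code <- Biostrings::GENETIC_CODE
  out <- names(code)[code == residue]
  if (!length(out)) stop("no codons for residue '", residue, "'")
  out
}

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

#' Simulation configuration
#'
#' Parameters of the synthetic ribosome-profiling experiment. Coverage at
#' non-pause positions is negative binomial with a gene-level mean drawn
#' log-normally and size \code{nb_size} (variance = mu + mu^2 / nb_size).
#' Pause sites multiply the mean by \code{pause_factor} in the control
#' condition and by \code{1 + (pause_factor - 1) * knockdown_attenuation} in
#' the knockdown condition.
#'
#' @param n_genes Number of transcripts.
#' @param cds_len_range Length-2 integer vector, CDS length range in nt
#'   (stop codon included); rounded to codon multiples.
#' @param tract_rate Expected number of charged tracts per gene (Poisson).
#' @param tract_len_range Length-2 vector, tract length range in amino acids.
#' @param tract_residues Amino acids making up tracts (default E and K).
#' @param expr_log_mean,expr_log_sd Log-scale mean and sd of the per-gene
#'   mean coverage (reads per CDS nucleotide).
#' @param nb_size NB size parameter k > 0.
#' @param pause_rate Expected pauses per gene; pauses sit downstream of
#'   tract ends, at most one per tract.
#' @param pause_factor Multiplicative coverage elevation at pause positions
#'   (> 1).
#' @param pause_offset_range Length-2 vector, codons downstream of a tract
#'   end where pauses/peaks are placed.
#' @param knockdown_attenuation Fraction of the pause elevation retained in
#'   the knockdown condition, in [0, 1].
#' @param init_factor Multiplicative coverage elevation at the start codon
#'   (first CDS nucleotide), emulating the initiation peak that start-codon
#'   metagene plots rely on for offset calibration; default 2.
#' @param n_replicates Replicates per condition.
#' @param read_len_range Length-2 vector, footprint length range in nt.
#' @param true_offsets Named integer vector mapping read length to P-site
#'   offset (5' end to P-site, nt). Must cover \code{read_len_range}.
#' @param utr_len_range Length-2 vector, UTR length range in nt (both UTRs).
#' @param seed Integer seed; every generator call is deterministic given the
#'   configuration.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 50,
                       cds_len_range = c(600, 3000),
                       tract_rate = 2,
                       tract_len_range = c(5, 12),
                       tract_residues = c("E", "K"),
                       expr_log_mean = log(5),
                       expr_log_sd = 1,
                       nb_size = 5,
                       pause_rate = 2,
                       pause_factor = 10,
                       pause_offset_range = c(1, 3),
                       knockdown_attenuation = 0.2,
                       init_factor = 2,
                       n_replicates = 3,
                       read_len_range = c(26, 34),
                       true_offsets = NULL,
                       utr_len_range = c(30, 60),
                       seed = 1L) {
  if (is.null(true_offsets)) {
    lens <- seq(read_len_range[1], read_len_range[2])
    # canonical ~12 nt 5'-to-P-site distance, growing slowly with length
    true_offsets <- stats::setNames(pmin(14L, pmax(11L, 11L + (lens - 26L) %/% 3L)),
                                    lens)
  }
  cfg <- list(n_genes = as.integer(n_genes),
              cds_len_range = as.integer(cds_len_range),
              tract_rate = tract_rate,
              tract_len_range = as.integer(tract_len_range),
              tract_residues = tract_residues,
              expr_log_mean = expr_log_mean, expr_log_sd = expr_log_sd,
              nb_size = nb_size,
              pause_rate = pause_rate, pause_factor = pause_factor,
              pause_offset_range = as.integer(pause_offset_range),
              knockdown_attenuation = knockdown_attenuation,
              init_factor = init_factor,
              n_replicates = as.integer(n_replicates),
              read_len_range = as.integer(read_len_range),
              true_offsets = true_offsets,
              utr_len_range = as.integer(utr_len_range),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1,
            length(cfg$cds_len_range) == 2,
            cfg$cds_len_range[1] <= cfg$cds_len_range[2],
            cfg$tract_rate >= 0,
            cfg$tract_len_range[1] <= cfg$tract_len_range[2],
            all(cfg$tract_residues %in% AA20),
            cfg$nb_size > 0,
            cfg$pause_rate >= 0,
            cfg$pause_factor >= 1,
            cfg$pause_offset_range[1] <= cfg$pause_offset_range[2],
            cfg$knockdown_attenuation >= 0, cfg$knockdown_attenuation <= 1,
            cfg$init_factor >= 1,
            cfg$n_replicates >= 1,
            cfg$read_len_range[1] <= cfg$read_len_range[2],
            cfg$utr_len_range[1] <= cfg$utr_len_range[2])
  if (cfg$pause_factor <= 1 && cfg$pause_rate > 0 && cfg$pause_factor != 1) {
    stop("pause_factor must be > 1 (or exactly 1 for a null simulation)")
  }
  lens <- as.character(seq(cfg$read_len_range[1], cfg$read_len_range[2]))
  if (!all(lens %in% names(cfg$true_offsets))) {
    stop("true_offsets must define an offset for every read length in ",
         "read_len_range")
  }
  invisible(cfg)
}

# place n_tract non-overlapping codon intervals in [1, plen); up to 100
# resampling attempts per tract, then a configuration error
place_tracts <- function(plen, n_tract, len_range) {
  placed <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n_tract)) {
    ok <- FALSE
    for (attempt in 1:100) {
      tl <- resample(seq(len_range[1], len_range[2]), 1L)
      if (plen - 1L - tl < 1L) next
      s <- resample(seq(1L, plen - tl), 1L)  # codon 0 is the start codon
      e <- s + tl                          # half-open [s, e)
      if (!nrow(placed) || all(e <= placed[, 1] | s >= placed[, 2])) {
        placed <- rbind(placed, c(s, e))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place ", n_tract, " non-overlapping tracts in a ",
           plen, "-codon protein; cds_len_range too small for tract_rate")
    }
  }
  placed[order(placed[, 1]), , drop = FALSE]
}

#' Generate synthetic transcripts with planted charged tracts
#'
#' Builds random transcripts (UTR5 + CDS + UTR3), overwrites planted tract
#' intervals with codons for \code{tract_residues}, and selects pause
#' positions downstream of tract ends. Pauses are single-nucleotide
#' multiplicative elevations at the first nucleotide of the selected codon.
#'
#' @param cfg A \code{sim_config}.
#' @return List with \code{transcripts} (a \code{transcript_set}) and
#'   \code{truth}, itself a list with \code{genes} (id, cds_len, mean
#'   coverage), \code{tracts} (transcript, aa_start, aa_end; 0-based
#'   half-open codon interval), and \code{pauses} (transcript, codon,
#'   position in CDS nt frame, factor_control, factor_knockdown).
#' @export
gen_transcripts <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  sense <- sense_codons()
  res_codons <- lapply(stats::setNames(nm = cfg$tract_residues), codons_for)

  ids <- sprintf("tx%04d", seq_len(cfg$n_genes))
  seqs <- character(cfg$n_genes)
  cds_start <- integer(cfg$n_genes)
  cds_end <- integer(cfg$n_genes)
  tract_rows <- list()
  pause_rows <- list()

  n_codon_range <- pmax(3L, cfg$cds_len_range %/% 3L)
  gene_mean <- stats::rlnorm(cfg$n_genes, cfg$expr_log_mean, cfg$expr_log_sd)

  for (g in seq_len(cfg$n_genes)) {
    n_codons <- resample(seq(n_codon_range[1], n_codon_range[2]), 1L)
    plen <- n_codons - 1L  # protein length (stop excluded, start included)
    body <- sample(sense, plen - 1L, replace = TRUE)
    codons <- c("ATG", body, sample(STOP_CODONS, 1L))

    n_tract <- if (cfg$tract_rate > 0) stats::rpois(1L, cfg$tract_rate) else 0L
    tracts <- place_tracts(plen, n_tract, cfg$tract_len_range)
    if (nrow(tracts)) {
      for (t in seq_len(nrow(tracts))) {
        idx <- seq(tracts[t, 1], tracts[t, 2] - 1L)
        residues <- resample(cfg$tract_residues, length(idx), replace = TRUE)
        codons[idx + 1L] <- vapply(residues, function(r) {
          resample(res_codons[[r]], 1L)
        }, character(1L))
      }
      tract_rows[[g]] <- data.frame(transcript = ids[g],
                                    aa_start = tracts[, 1],
                                    aa_end = tracts[, 2])
    }

    # pauses: at most one per tract, downstream of the tract end
    n_pause <- if (cfg$pause_rate > 0 && nrow(tracts)) {
      min(stats::rpois(1L, cfg$pause_rate), nrow(tracts))
    } else 0L
    if (n_pause > 0L) {
      chosen <- sort(resample(seq_len(nrow(tracts)), n_pause))
      codon_idx <- vapply(chosen, function(t) {
        off <- resample(seq(cfg$pause_offset_range[1],
                            cfg$pause_offset_range[2]), 1L)
        min(plen - 1L, tracts[t, 2] - 1L + off)
      }, integer(1L))
      codon_idx <- unique(codon_idx)
      pause_rows[[g]] <- data.frame(
        transcript = ids[g], codon = codon_idx,
        position = 3L * codon_idx,
        factor_control = cfg$pause_factor,
        factor_knockdown = 1 + (cfg$pause_factor - 1) * cfg$knockdown_attenuation)
    }

    utr5 <- resample(seq(cfg$utr_len_range[1], cfg$utr_len_range[2]), 1L)
    utr3 <- resample(seq(cfg$utr_len_range[1], cfg$utr_len_range[2]), 1L)
    seqs[g] <- paste0(
      paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE), collapse = ""),
      paste(codons, collapse = ""),
      paste(sample(c("A", "C", "G", "T"), utr3, replace = TRUE), collapse = ""))
    cds_start[g] <- utr5
    cds_end[g] <- utr5 + 3L * n_codons
  }

  transcripts <- transcript_set(ids, seqs, cds_start, cds_end)
  truth <- list(
    genes = data.frame(transcript = ids,
                       cds_len = cds_end - cds_start,
                       mean_coverage = gene_mean),
    tracts = if (length(tract_rows)) do.call(rbind, tract_rows) else
      data.frame(transcript = character(0), aa_start = integer(0),
                 aa_end = integer(0)),
    pauses = if (length(pause_rows)) do.call(rbind, pause_rows) else
      data.frame(transcript = character(0), codon = integer(0),
                 position = integer(0), factor_control = numeric(0),
                 factor_knockdown = numeric(0)))
  rownames(truth$tracts) <- rownames(truth$pauses) <- NULL
  list(transcripts = transcripts, truth = truth)
}

#' Generate NB P-site coverage for one condition
#'
#' Draws independent NB counts per CDS nucleotide, replicate and gene. Counts
#' share the per-gene mean; pause positions have the mean multiplied by the
#' condition's true pause factor.
#'
#' @param transcripts A \code{transcript_set} from \code{gen_transcripts}.
#' @param truth Matching truth list.
#' @param cfg The \code{sim_config}.
#' @param condition \code{"control"} or \code{"knockdown"}.
#' @param mean_scale Multiplier applied to gene means in this condition
#'   (models gene-level occupancy shifts with pause factors untouched):
#'   either a scalar for every gene or a named vector keyed by transcript
#'   id (unnamed genes keep 1); default 1.
#' @param seed Seed for this draw; defaults to a condition-specific child of
#'   \code{cfg$seed} so the two conditions are independent.
#' @return A \code{coverage_set} (see \code{\link{coverage_set}}).
#' @export
gen_coverage <- function(transcripts, truth, cfg,
                         condition = c("control", "knockdown"),
                         mean_scale = 1, seed = NULL) {
  condition <- match.arg(condition)
  if (is.null(seed)) {
    seed <- cfg$seed + ifelse(condition == "control", 1000L, 2000L)
  }
  set.seed(seed)
  fac_col <- paste0("factor_", condition)
  lens <- cds_length(transcripts)
  scale_of <- function(tx) {
    if (is.null(names(mean_scale))) mean_scale[1L]
    else if (tx %in% names(mean_scale)) mean_scale[[tx]] else 1
  }
  counts <- lapply(transcripts$id, function(tx) {
    L <- lens[[tx]]
    mu <- rep(truth$genes$mean_coverage[truth$genes$transcript == tx] *
                scale_of(tx), L)
    mu[1L] <- mu[1L] * cfg$init_factor  # start-codon initiation peak
    p <- truth$pauses[truth$pauses$transcript == tx, , drop = FALSE]
    if (nrow(p)) mu[p$position + 1L] <- mu[p$position + 1L] * p[[fac_col]]
    m <- matrix(as.integer(stats::rnbinom(L * cfg$n_replicates,
                                          mu = rep(mu, cfg$n_replicates),
                                          size = cfg$nb_size)),
                nrow = L, ncol = cfg$n_replicates)
    colnames(m) <- paste0(condition, "_rep", seq_len(cfg$n_replicates))
    m
  })
  names(counts) <- transcripts$id
  coverage_set(counts, condition = condition)
}

#' Emit BED6 footprints from coverage
#'
#' Each P-site count at CDS position p emits one read per count, of random
#' length L, with 5' end at transcript position
#' \code{cds_start + p - true_offsets[L]}. Reads that would extend past the
#' transcript bounds are dropped and counted in the \code{clipped} attribute.
#'
#' @param coverage A \code{coverage_set} (one condition).
#' @param transcripts The matching \code{transcript_set}.
#' @param cfg The \code{sim_config} (read lengths and true offsets).
#' @param seed Seed for read-length assignment; defaults to a child of
#'   \code{cfg$seed}.
#' @return Named list of BED6 data frames, one per library (replicate), each
#'   with attribute \code{clipped} (number of dropped reads).
#' @export
gen_footprints <- function(coverage, transcripts, cfg, seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed + 3000L
  set.seed(seed)
  lens <- seq(cfg$read_len_range[1], cfg$read_len_range[2])
  offs <- cfg$true_offsets[as.character(lens)]
  cds_start <- stats::setNames(transcripts$cds_start, transcripts$id)
  tx_len <- stats::setNames(nchar(transcripts$sequence), transcripts$id)

  libs <- colnames(coverage$counts[[1L]])
  out <- lapply(stats::setNames(nm = libs), function(lib) {
    rows <- lapply(names(coverage$counts), function(tx) {
      cnt <- coverage$counts[[tx]][, lib]
      pos <- rep.int(seq_along(cnt) - 1L, cnt)
      if (!length(pos)) return(NULL)
      L <- resample(lens, length(pos), replace = TRUE)
      start <- cds_start[[tx]] + pos - offs[as.character(L)]
      data.frame(chrom = tx, start = unname(start),
                 end = unname(start) + L, score = L,
                 stringsAsFactors = FALSE)
    })
    bed <- do.call(rbind, rows)
    keep <- bed$start >= 0L & bed$end <= tx_len[bed$chrom]
    clipped <- sum(!keep)
    bed <- bed[keep, , drop = FALSE]
    bed <- data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
                      name = sprintf("%s_read%07d", lib, seq_len(nrow(bed))),
                      score = bed$score, strand = "+",
                      stringsAsFactors = FALSE)
    rownames(bed) <- NULL
    attr(bed, "clipped") <- clipped
    bed
  })
  out
}

#' Generate crosslink peaks downstream of tract ends
#'
#' One peak per planted tract, centered a random number of codons
#' (\code{cfg$pause_offset_range}) downstream of the tract end, converted to
#' the middle nucleotide of that codon. Fold-enrichment and p-value columns
#' are drawn so that a configurable fraction fails the standard
#' ">8-fold, p < 1e-5" significance filter.
#'
#' @param transcripts,truth Output of \code{gen_transcripts}.
#' @param cfg The \code{sim_config}.
#' @param fraction_failing Fraction of peaks drawn to fail the filter.
#' @param half_width Peak half-width in nt.
#' @param seed Seed; defaults to a child of \code{cfg$seed}.
#' @return List with \code{peaks} (a \code{peak_table}) and
#'   \code{truth} data frame (transcript, codon, center_nt, passes_filter).
#' @export
gen_peaks <- function(transcripts, truth, cfg, fraction_failing = 0.2,
                      half_width = 20L, seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed + 4000L
  set.seed(seed)
  tr <- truth$tracts
  if (!nrow(tr)) {
    empty <- data.frame(transcript = character(0), start = integer(0),
                        end = integer(0), fold_enrichment = numeric(0),
                        p_value = numeric(0), center = integer(0))
    class(empty) <- c("peak_table", "data.frame")
    return(list(peaks = empty,
                truth = data.frame(transcript = character(0), codon = integer(0),
                                   center_nt = integer(0),
                                   passes_filter = logical(0))))
  }
  cds_start <- stats::setNames(transcripts$cds_start, transcripts$id)
  plen <- stats::setNames(nchar(transcripts$protein), transcripts$id)
  tx_len <- stats::setNames(nchar(transcripts$sequence), transcripts$id)

  off <- resample(seq(cfg$pause_offset_range[1], cfg$pause_offset_range[2]),
                  nrow(tr), replace = TRUE)
  codon <- pmin(plen[tr$transcript] - 1L, tr$aa_end - 1L + off)
  center <- cds_start[tr$transcript] + 3L * codon + 1L
  start <- pmax(0L, center - half_width)
  end <- pmin(tx_len[tr$transcript], center + half_width + 1L)
  # keep the derived midpoint equal to the intended center
  shift <- center - (start + end) %/% 2L
  start <- start + shift; end <- end + shift

  n <- nrow(tr)
  fails <- stats::runif(n) < fraction_failing
  fold <- ifelse(fails & stats::runif(n) < 0.5,
                 stats::runif(n, 0, 8), stats::runif(n, 10, 50))
  pval <- 10^ifelse(fails, ifelse(fold <= 8, stats::runif(n, -12, -6),
                                  stats::runif(n, -4, 0)),
                    stats::runif(n, -12, -6))
  peaks <- peak_table(tr$transcript, start, end, fold, pval)
  list(peaks = peaks,
       truth = data.frame(transcript = tr$transcript, codon = unname(codon),
                          center_nt = unname(center),
                          passes_filter = fold > 8 & pval < 1e-5))
}

#' Generate a spectral-count fractionation table
#'
#' Emulates the statistical structure of a cytosol/ER fractionation
#' experiment: per-protein Poisson peptide counts in compartment
#' (\code{ER}, \code{cyto}) by pool (\code{rna_dep}, \code{ribosome},
#' \code{mrnp}, \code{mock}) by replicate cells. Each protein has a true ER
#' fraction \code{0.5 + compartment_bias * (u - 0.5)}, u uniform, and a true
#' interactor status; non-interactors have strongly reduced means in the
#' polysome pools while the mock pool is common background.
#'
#' @param n_proteins Number of proteins.
#' @param compartment_bias Spread of true ER fractions around 0.5, in [0, 1]
#'   (0: every protein is 50 percent ER).
#' @param mock_background Mock-bead background level as a fraction of the
#'   mrnp pool mean, in [0, 1].
#' @param n_replicates Replicates per pool.
#' @param mean_abundance Mean peptide count for an interactor in a polysome
#'   pool (split between compartments by the ER fraction).
#' @param interactor_fraction Fraction of proteins that are true interactors.
#' @param seed Integer seed.
#' @return List with \code{table} (long data frame: protein, compartment,
#'   pool, replicate, count) and \code{truth} (protein, er_frac,
#'   is_interactor).
#' @export
gen_spectra <- function(n_proteins = 100, compartment_bias = 0.8,
                        mock_background = 0.1, n_replicates = 3,
                        mean_abundance = 30, interactor_fraction = 0.5,
                        seed = 1L) {
  stopifnot(compartment_bias >= 0, compartment_bias <= 1,
            mock_background >= 0, mock_background <= 1)
  set.seed(as.integer(seed))
  ids <- sprintf("prot%04d", seq_len(n_proteins))
  er_frac <- 0.5 + compartment_bias * (stats::runif(n_proteins) - 0.5)
  is_int <- stats::runif(n_proteins) < interactor_fraction

  pools <- c("rna_dep", "ribosome", "mrnp", "mock")
  grid <- expand.grid(protein = ids, compartment = c("ER", "cyto"),
                      pool = pools, replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pi_er <- er_frac[match(grid$protein, ids)]
  interactor <- is_int[match(grid$protein, ids)]
  comp_w <- ifelse(grid$compartment == "ER", pi_er, 1 - pi_er)
  pool_w <- ifelse(grid$pool == "mock", mock_background,
                   ifelse(interactor, 1, 0.02))
  mu <- mean_abundance * comp_w * pool_w
  # mock background does not depend on interactor status
  mu[grid$pool == "mock"] <- mean_abundance * mock_background *
    comp_w[grid$pool == "mock"]
  grid$count <- stats::rpois(nrow(grid), mu)
  list(table = grid,
       truth = data.frame(protein = ids, er_frac = er_frac,
                          is_interactor = is_int))
}
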