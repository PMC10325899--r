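# Spectral-count fractionation scoring: replicate presence calls, mock-bead
# enrichment for the oligo-dT (mRNP) pool, the high-confidence interactor
# intersection rule, and the percent-ER distribution statistic.

#' Replicate presence call
#'
#' A protein is present in a pool iff its peptide count is nonzero in at
#' least \code{min_replicates} replicates.
#'
#' @param counts Numeric vector of per-replicate peptide counts.
#' @param min_replicates Minimum detected replicates; default 2.
#' @return Logical scalar.
#' @export
presence_call <- function(counts, min_replicates = 2) {
  sum(counts > 0) >= min_replicates
}

#' Mock-bead enrichment call for the oligo-dT pool
#'
#' Passes iff the presence rule holds and the summed peptide count is at
#' least \code{fold}-fold over the matched mock pulldown in every experiment
#' in which the protein was detected. A zero mock total is replaced by a 0.5
#' pseudo-count.
#'
#' @param counts Per-experiment oligo-dT peptide totals.
#' @param mock_counts Matched per-experiment mock-bead totals.
#' @param fold Minimum enrichment (inclusive); default 2.
#' @param min_replicates Presence rule threshold; default 2.
#' @return Logical scalar; attribute \code{ratios} carries the per-experiment
#'   enrichment ratios.
#' @export
oligodt_call <- function(counts, mock_counts, fold = 2, min_replicates = 2) {
  stopifnot(length(counts) == length(mock_counts))
  present <- presence_call(counts, min_replicates)
  ratios <- counts / pmax(mock_counts, 0.5)
  detected <- counts > 0
  enriched <- length(counts) > 0 && any(detected) &&
    all(ratios[detected] >= fold)
  out <- present && enriched
  attr(out, "ratios") <- ratios
  out
}

#' Percent-ER of a protein in one pool
#'
#' Per experiment: 100 * ER / (ER + cytosol); experiments with zero total
#' are excluded; the result is the arithmetic mean across the included
#' experiments. All-zero input is undefined and returns NA with a flag.
#'
#' @param er_peptides,cyto_peptides Per-experiment peptide counts in the ER
#'   and cytosolic fractions of the same pool.
#' @return Numeric percentage in [0, 100], or NA (attribute
#'   \code{undefined = TRUE}) when every experiment has zero total.
#' @export
percent_er <- function(er_peptides, cyto_peptides) {
  stopifnot(length(er_peptides) == length(cyto_peptides))
  total <- er_peptides + cyto_peptides
  keep <- total > 0
  if (!any(keep)) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  mean(100 * er_peptides[keep] / total[keep])
}

#' Score a spectral-count table into interactor calls
#'
#' Applies the presence rule per pool (summing ER and cytosol compartments
#' per replicate), the mock-enrichment rule to the mRNP (oligo-dT) pool, the
#' high-confidence intersection rule (mRNP-bound AND (ribosome-bound OR
#' RNA-dependent)), removes proteins on a curated exclusion list, and
#' computes percent-ER per pool and averaged over pools.
#'
#' @param table Long data frame with columns \code{protein},
#'   \code{compartment} (\code{ER} / \code{cyto}), \code{pool}
#'   (\code{rna_dep}, \code{ribosome}, \code{mrnp}, \code{mock}),
#'   \code{replicate}, \code{count}.
#' @param exclude Character vector of curated contaminant ids to drop.
#' @param min_replicates Presence rule threshold; default 2.
#' @param fold Mock enrichment threshold; default 2.
#' @return Data frame of class \code{interactor_calls}: per protein, the
#'   three presence calls, \code{high_confidence}, percent-ER per pool and
#'   \code{percent_er_mean}. Attribute \code{n_excluded} counts removed ids.
#' @export
call_interactors <- function(table, exclude = character(0),
                             min_replicates = 2, fold = 2) {
  needed <- c("protein", "compartment", "pool", "replicate", "count")
  stopifnot(all(needed %in% names(table)))
  n_before <- length(unique(table$protein))
  table <- table[!(table$protein %in% exclude), , drop = FALSE]
  n_excluded <- n_before - length(unique(table$protein))

  pool_counts <- function(d, pool) {
    sel <- d[d$pool == pool, , drop = FALSE]
    reps <- sort(unique(table$replicate))
    vapply(reps, function(r) sum(sel$count[sel$replicate == r]), numeric(1L))
  }
  compartment_counts <- function(d, pool, compartment) {
    sel <- d[d$pool == pool & d$compartment == compartment, , drop = FALSE]
    reps <- sort(unique(table$replicate))
    vapply(reps, function(r) sum(sel$count[sel$replicate == r]), numeric(1L))
  }

  res <- lapply(split(table, table$protein), function(d) {
    ribo <- pool_counts(d, "ribosome")
    rnad <- pool_counts(d, "rna_dep")
    mrnp <- pool_counts(d, "mrnp")
    mock <- pool_counts(d, "mock")
    present_ribosome <- presence_call(ribo, min_replicates)
    present_rna_dep <- presence_call(rnad, min_replicates)
    present_oligo_dt <- isTRUE(oligodt_call(mrnp, mock, fold = fold,
                                            min_replicates = min_replicates))
    pe <- vapply(c(rna_dep = "rna_dep", ribosome = "ribosome",
                   mrnp = "mrnp"), function(pool) {
      percent_er(compartment_counts(d, pool, "ER"),
                 compartment_counts(d, pool, "cyto"))
    }, numeric(1L))
    data.frame(protein = d$protein[1L],
               present_ribosome = present_ribosome,
               present_rna_dep = present_rna_dep,
               present_oligo_dt = present_oligo_dt,
               high_confidence = present_oligo_dt &&
                 (present_ribosome || present_rna_dep),
               percent_er_rna_dep = pe[["rna_dep"]],
               percent_er_ribosome = pe[["ribosome"]],
               percent_er_mrnp = pe[["mrnp"]],
               percent_er_mean = mean(pe, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("interactor_calls", "data.frame")
  out
}

#' Read / write spectral-count tables as TSV
#' @param path File path.
#' @return \code{read_spectra}: long data frame (protein, compartment, pool,
#'   replicate, count).
#' @export
read_spectra <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_spectra
#' @param table Long spectral-count data frame.
#' @export
write_spectra <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}
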