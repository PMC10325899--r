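# Codon-space anchors (crosslink peak centers or pause sites), positional
# amino-acid and charge-class enrichment in +/- windows around them with a
# permutation null, mRNA-region distributions, and set-overlap enrichment.

#' Map peak centers to codon-space anchors
#'
#' Peaks whose center lies inside the CDS map to codon
#' floor((center - cds_start) / 3); centers in the UTRs are excluded and
#' tallied in the \code{excluded} attribute.
#'
#' @param peaks A \code{peak_table} (typically after
#'   \code{\link{filter_peaks}}).
#' @param transcripts A \code{transcript_set}.
#' @return Data frame of class \code{anchor_set} (\code{transcript},
#'   \code{codon}) with attributes \code{source = "clip_peak"} and
#'   \code{excluded} (named count of UTR peaks).
#' @export
peaks_to_anchors <- function(peaks, transcripts) {
  idx <- match(peaks$transcript, transcripts$id)
  if (anyNA(idx)) stop("peaks reference unknown transcripts")
  cds_start <- transcripts$cds_start[idx]
  cds_end <- transcripts$cds_end[idx]
  plen <- nchar(transcripts$protein)[idx]
  inside <- peaks$center >= cds_start & peaks$center < cds_end
  codon <- (peaks$center - cds_start) %/% 3L
  inside <- inside & codon < plen  # stop codon carries no residue
  out <- data.frame(transcript = peaks$transcript[inside],
                    codon = codon[inside], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "source") <- "clip_peak"
  attr(out, "excluded") <- sum(!inside)
  class(out) <- c("anchor_set", "data.frame")
  out
}

#' Map pause sites to codon-space anchors
#'
#' Uses the P-site codon (position %/% 3) of each pause.
#'
#' @param pauses Data frame with \code{transcript} and \code{position}
#'   (CDS-frame nt), e.g. called rows of \code{\link{call_pauses}}.
#' @param transcripts A \code{transcript_set}.
#' @return An \code{anchor_set} with \code{source = "pause_site"}.
#' @export
pauses_to_anchors <- function(pauses, transcripts) {
  idx <- match(pauses$transcript, transcripts$id)
  if (anyNA(idx)) stop("pauses reference unknown transcripts")
  plen <- nchar(transcripts$protein)[idx]
  codon <- pauses$position %/% 3L
  keep <- codon >= 0L & codon < plen
  out <- data.frame(transcript = pauses$transcript[keep],
                    codon = codon[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "source") <- "pause_site"
  attr(out, "excluded") <- sum(!keep)
  class(out) <- c("anchor_set", "data.frame")
  out
}

# integer residue codes (1..20) per transcript protein; X/N -> NA
protein_codes <- function(proteins) {
  lapply(proteins, function(p) {
    match(strsplit(p, "")[[1L]], AA20)
  })
}

aa_offset_counts <- function(codes_flat, base, plen, tx_idx, codon, offsets) {
  W <- length(offsets)
  pos <- outer(codon, offsets, "+")                  # anchors x offsets
  valid <- pos >= 0L & pos < plen[tx_idx]
  idx <- base[tx_idx] + pos + 1L
  code <- matrix(NA_integer_, nrow = nrow(pos), ncol = W)
  code[valid] <- codes_flat[idx[valid]]
  off_idx <- matrix(rep(seq_len(W), each = nrow(pos)), ncol = W)
  ok <- !is.na(code)
  counts <- tabulate(code[ok] + 20L * (off_idx[ok] - 1L), nbins = 20L * W)
  matrix(counts, nrow = 20L, ncol = W, dimnames = list(AA20, offsets))
}

#' Positional amino-acid enrichment around anchors
#'
#' For each offset d in -window..window, counts the residue at codon + d over
#' all anchors where in range, converts to per-offset frequencies f(a, d),
#' and reports log2((f + eps) / (g + eps)) against the background g(a): the
#' residue frequencies over the full CDSs of anchor-bearing transcripts (or
#' a user-supplied proteome-wide background). Significance comes from a
#' permutation null that re-draws each anchor uniformly within its own
#' transcript's codon range, preserving per-transcript anchor counts:
#' per-cell two-sided empirical p-values with a +1 correction, and the 95
#' percent envelope of the per-permutation maximum |log2 enrichment|
#' (a family-wise reference level).
#'
#' @param anchors An \code{anchor_set}.
#' @param transcripts A \code{transcript_set}.
#' @param window Window half-width in amino acids; default 30.
#' @param background \code{"targets"} (default: anchor-bearing transcripts'
#'   own CDSs) or a named numeric vector of residue frequencies over
#'   \code{AA20} (e.g. proteome-wide rates).
#' @param n_perm Number of permutations; default 1000.
#' @param seed Optional seed for the permutation draw.
#' @param pseudo Pseudo-frequency epsilon; default 1e-4.
#' @return List of class \code{enrichment_profile}: \code{offsets},
#'   \code{freq} (20 x offsets), \code{background}, \code{log2_enrichment},
#'   \code{perm_p}, \code{n_contributing} (per offset), \code{max_envelope}
#'   (95 percent quantile of the permutation max |log2 enrichment|),
#'   \code{n_anchors}, \code{n_perm}.
#' @export
positional_enrichment <- function(anchors, transcripts, window = 30,
                                  background = "targets", n_perm = 1000,
                                  seed = NULL, pseudo = 1e-4) {
  if (!nrow(anchors)) stop("no anchors supplied")
  if (!is.null(seed)) set.seed(seed)
  txs <- unique(anchors$transcript)
  tset <- transcripts[match(txs, transcripts$id), , drop = FALSE]
  plen <- nchar(tset$protein)
  if (max(plen) <= window) {
    stop("window (", window, " aa) exceeds every anchor-bearing protein")
  }
  codes <- protein_codes(tset$protein)
  codes_flat <- unlist(codes, use.names = FALSE)
  base <- c(0L, cumsum(plen))[seq_along(plen)]
  tx_idx <- match(anchors$transcript, txs)
  offsets <- seq(-window, window)

  obs_counts <- aa_offset_counts(codes_flat, base, plen, tx_idx,
                                 anchors$codon, offsets)
  n_contrib <- colSums(obs_counts)
  freq <- sweep(obs_counts, 2L, pmax(n_contrib, 1L), "/")
  freq[, n_contrib == 0L] <- NA_real_

  if (identical(background, "targets")) {
    bg_counts <- tabulate(codes_flat[!is.na(codes_flat)], nbins = 20L)
    g <- stats::setNames(bg_counts / sum(bg_counts), AA20)
  } else {
    stopifnot(is.numeric(background), all(AA20 %in% names(background)))
    g <- background[AA20] / sum(background[AA20])
  }
  enr <- log2((freq + pseudo) / (g + pseudo))

  ge <- matrix(0L, nrow = 20L, ncol = length(offsets))
  perm_max <- numeric(n_perm)
  abs_obs <- abs(enr)
  abs_obs[is.na(abs_obs)] <- Inf   # empty cells never count as exceeded
  for (b in seq_len(n_perm)) {
    codon_b <- as.integer(floor(stats::runif(nrow(anchors)) * plen[tx_idx]))
    cb <- aa_offset_counts(codes_flat, base, plen, tx_idx, codon_b, offsets)
    nc <- colSums(cb)
    fb <- sweep(cb, 2L, pmax(nc, 1L), "/")
    fb[, nc == 0L] <- NA_real_
    eb <- log2((fb + pseudo) / (g + pseudo))
    abs_eb <- abs(eb)
    perm_max[b] <- max(abs_eb, na.rm = TRUE)
    ge <- ge + (!is.na(abs_eb) & abs_eb >= abs_obs)
  }
  perm_p <- (1 + ge) / (n_perm + 1)
  perm_p[is.na(freq)] <- NA_real_

  structure(list(offsets = offsets, freq = freq, background = g,
                 log2_enrichment = enr, perm_p = perm_p,
                 n_contributing = n_contrib,
                 max_envelope = unname(stats::quantile(perm_max, 0.95)),
                 n_anchors = nrow(anchors), n_perm = n_perm,
                 pseudo = pseudo),
            class = "enrichment_profile")
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat("enrichment_profile:", x$n_anchors, "anchors, offsets",
      min(x$offsets), "..", max(x$offsets), ",", x$n_perm, "permutations\n")
  cat("  95% max-|log2 enrichment| envelope:", signif(x$max_envelope, 3), "\n")
  invisible(x)
}

#' Charge-class frequencies per offset
#'
#' Sums per-residue frequencies into positive, negative and neutral classes.
#' Histidine is treated as neutral (mostly uncharged at cytosolic pH).
#'
#' @param profile An \code{enrichment_profile}.
#' @param positive,negative Character vectors of class members; they must
#'   not overlap.
#' @return Data frame: \code{offset}, \code{positive}, \code{negative},
#'   \code{neutral}.
#' @export
charge_profile <- function(profile, positive = c("K", "R"),
                           negative = c("D", "E")) {
  if (length(intersect(positive, negative))) {
    stop("positive and negative classes overlap")
  }
  pos <- colSums(profile$freq[positive, , drop = FALSE])
  neg <- colSums(profile$freq[negative, , drop = FALSE])
  data.frame(offset = profile$offsets, positive = pos, negative = neg,
             neutral = 1 - pos - neg, row.names = NULL)
}

#' Region distribution and normalized-length metagene of peaks
#'
#' Classifies peak centers into 5'UTR / CDS / 3'UTR and histograms the
#' relative position center / transcript_length over equal bins.
#'
#' @param peaks A \code{peak_table}.
#' @param transcripts A \code{transcript_set}.
#' @param n_bins Number of metagene bins; default 100.
#' @return List: \code{fractions} (named, sums to 1), \code{counts} (named
#'   tallies), \code{metagene} (integer vector of length \code{n_bins}).
#' @export
region_distribution <- function(peaks, transcripts, n_bins = 100) {
  idx <- match(peaks$transcript, transcripts$id)
  if (anyNA(idx)) stop("peaks reference unknown transcripts")
  cds_start <- transcripts$cds_start[idx]
  cds_end <- transcripts$cds_end[idx]
  tx_len <- nchar(transcripts$sequence)[idx]
  region <- ifelse(peaks$center < cds_start, "utr5",
                   ifelse(peaks$center < cds_end, "cds", "utr3"))
  counts <- vapply(c(utr5 = "utr5", cds = "cds", utr3 = "utr3"),
                   function(r) sum(region == r), integer(1L))
  rel <- peaks$center / tx_len
  bin <- pmin(n_bins - 1L, as.integer(floor(rel * n_bins)))
  metagene <- tabulate(bin + 1L, nbins = n_bins)
  list(fractions = counts / sum(counts), counts = counts,
       metagene = metagene)
}

#' Hypergeometric set-overlap enrichment
#'
#' Upper-tail P(X >= overlap) for the observed overlap of two sets drawn
#' from a common universe, plus the fold over expectation
#' |A| * |B| / |U|.
#'
#' @param set_a,set_b Character vectors (subsets of \code{universe}).
#' @param universe Character vector of all eligible elements.
#' @return List: \code{overlap}, \code{expected}, \code{fold}, \code{p}.
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("sets must be subsets of the universe")
  }
  ov <- length(intersect(set_a, set_b))
  nA <- length(set_a); nB <- length(set_b); nU <- length(universe)
  expected <- nA * nB / nU
  p <- stats::phyper(ov - 1L, nA, nU - nA, nB, lower.tail = FALSE)
  list(overlap = ov, expected = expected,
       fold = if (expected > 0) ov / expected else NA_real_, p = p)
}

#' Write an enrichment profile as TSV
#'
#' Rows are offsets; columns are the 20 residue log2 enrichments followed by
#' the three charge-class frequencies.
#'
#' @param profile An \code{enrichment_profile}.
#' @param path Output path.
#' @return Invisibly, the written data frame.
#' @export
write_enrichment <- function(profile, path) {
  cc <- charge_profile(profile)
  df <- data.frame(offset = profile$offsets, t(profile$log2_enrichment),
                   positive = cc$positive, negative = cc$negative,
                   neutral = cc$neutral, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
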