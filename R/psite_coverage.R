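# P-site offset calibration from start-codon metagenes, nucleotide-resolution
# CDS coverage construction, and the expression filter.

#' Per-condition coverage container
#'
#' Holds nucleotide-resolution P-site counts over the CDS of each transcript
#' for all replicate libraries of one condition.
#'
#' @param counts Named list (by transcript) of integer matrices, CDS length
#'   by replicate; all matrices must share column names (library ids).
#' @param condition Condition label.
#' @return List of class \code{coverage_set} with elements \code{counts},
#'   \code{condition}, \code{libraries} and \code{lib_sizes} (total counts
#'   per library).
#' @export
coverage_set <- function(counts, condition = "control") {
  stopifnot(is.list(counts), length(counts) >= 1,
            !is.null(names(counts)))
  libs <- colnames(counts[[1L]])
  for (tx in names(counts)) {
    m <- counts[[tx]]
    if (!is.matrix(m) || !identical(colnames(m), libs)) {
      stop("coverage matrices must share identical library columns")
    }
    if (any(m < 0)) stop("negative counts in transcript '", tx, "'")
  }
  lib_sizes <- Reduce(`+`, lapply(counts, colSums))
  structure(list(counts = counts, condition = condition,
                 libraries = libs, lib_sizes = lib_sizes),
            class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat("coverage_set:", length(x$counts), "transcripts,",
      length(x$libraries), "libraries, condition:", x$condition, "\n")
  invisible(x)
}

#' Calibrate P-site offsets per read length
#'
#' For each read length, the offset is the arg-max over the search window of
#' the histogram of \code{cds_start - five_prime_end} (the distance from each
#' read's 5' end to the annotated start codon, restricted to reads whose 5'
#' end lies within the window upstream of the start). Ties break toward the
#' smaller offset. Lengths with fewer than \code{min_reads} reads are left
#' uncalibrated and excluded downstream.
#'
#' @param footprints A BED6 data frame or a list of them (libraries are
#'   pooled for calibration).
#' @param transcripts A \code{transcript_set}.
#' @param search_window Length-2 integer vector of candidate offsets (nt).
#' @param length_range Length-2 integer vector of read lengths to calibrate.
#' @param min_reads Minimum reads (within the window) for a length to be
#'   calibrated.
#' @return List of class \code{offset_table}: \code{offsets} (named integer
#'   vector) and \code{histograms} (per length, counts over the window).
#' @export
estimate_offsets <- function(footprints, transcripts,
                             search_window = c(8, 16),
                             length_range = c(26, 34),
                             min_reads = 100) {
  if (is.data.frame(footprints)) footprints <- list(footprints)
  bed <- do.call(rbind, lapply(footprints, function(b) {
    b[, c("chrom", "start", "score")]
  }))
  cds_start <- stats::setNames(transcripts$cds_start, transcripts$id)
  bed <- bed[bed$chrom %in% names(cds_start), , drop = FALSE]
  d <- cds_start[bed$chrom] - bed$start
  window <- seq(search_window[1], search_window[2])
  lens <- seq(length_range[1], length_range[2])

  offsets <- integer(0)
  histograms <- list()
  for (L in lens) {
    sel <- bed$score == L
    if (sum(sel) < min_reads) next
    dL <- d[sel]
    h <- vapply(window, function(w) sum(dL == w), integer(1L))
    names(h) <- window
    histograms[[as.character(L)]] <- h
    offsets[as.character(L)] <- window[which.max(h)]  # ties -> smaller offset
  }
  if (!length(offsets)) {
    stop("no read length could be calibrated (need >= ", min_reads,
         " reads per length)")
  }
  structure(list(offsets = offsets, histograms = histograms,
                 search_window = search_window, min_reads = min_reads),
            class = "offset_table")
}

#' @export
print.offset_table <- function(x, ...) {
  cat("offset_table:\n")
  print(x$offsets)
  invisible(x)
}

#' Build nucleotide-resolution CDS coverage from footprints
#'
#' Each read of a calibrated length increments CDS position
#' \code{five_prime_end + offset - cds_start} when that P-site lies inside
#' the CDS. Reads of uncalibrated lengths and reads whose P-site falls
#' outside the CDS are counted in the \code{exclusions} attribute, not
#' silently dropped.
#'
#' @param footprints Named list of BED6 data frames, one per library.
#' @param offsets An \code{offset_table}.
#' @param transcripts A \code{transcript_set}.
#' @param condition Condition label for the resulting \code{coverage_set}.
#' @return A \code{coverage_set} with attribute \code{exclusions}: data
#'   frame (library, uncalibrated, out_of_cds).
#' @export
build_coverage <- function(footprints, offsets, transcripts,
                           condition = "control") {
  stopifnot(is.list(footprints), !is.null(names(footprints)))
  cds_start <- stats::setNames(transcripts$cds_start, transcripts$id)
  lens <- cds_length(transcripts)
  off <- offsets$offsets

  per_lib <- lapply(names(footprints), function(lib) {
    bed <- footprints[[lib]]
    calibrated <- as.character(bed$score) %in% names(off)
    n_uncal <- sum(!calibrated)
    bed <- bed[calibrated, , drop = FALSE]
    psite <- bed$start + off[as.character(bed$score)] - cds_start[bed$chrom]
    inside <- psite >= 0L & psite < lens[bed$chrom]
    n_out <- sum(!inside)
    bed <- bed[inside, , drop = FALSE]
    psite <- psite[inside]
    counts <- lapply(stats::setNames(nm = transcripts$id), function(tx) {
      v <- integer(lens[[tx]])
      sel <- bed$chrom == tx
      if (any(sel)) {
        tb <- tabulate(psite[sel] + 1L, nbins = lens[[tx]])
        v <- as.integer(tb)
      }
      v
    })
    list(counts = counts, uncalibrated = n_uncal, out_of_cds = n_out)
  })
  names(per_lib) <- names(footprints)

  counts <- lapply(stats::setNames(nm = transcripts$id), function(tx) {
    m <- vapply(per_lib, function(pl) pl$counts[[tx]],
                integer(lens[[tx]]))
    m <- matrix(m, nrow = lens[[tx]], ncol = length(per_lib),
                dimnames = list(NULL, names(footprints)))
    m
  })
  cs <- coverage_set(counts, condition = condition)
  attr(cs, "exclusions") <- data.frame(
    library = names(footprints),
    uncalibrated = vapply(per_lib, `[[`, integer(1L), "uncalibrated"),
    out_of_cds = vapply(per_lib, `[[`, integer(1L), "out_of_cds"),
    row.names = NULL)
  cs
}

#' Expression filter on CDS coverage
#'
#' Keeps a gene iff its normalized CDS coverage (mean P-site count per CDS
#' nucleotide, or RPKM with \code{method = "rpkm"}) is at least
#' \code{min_coverage} in every library of every supplied condition.
#'
#' @param coverages A \code{coverage_set} or list of them (e.g. both
#'   conditions).
#' @param min_coverage Inclusive threshold; default 1.
#' @param method \code{"mean"} (default: mean counts per CDS nt) or
#'   \code{"rpkm"} (reads per kb of CDS per million P-sites in the library).
#' @return Character vector of retained transcript ids.
#' @export
filter_genes <- function(coverages, min_coverage = 1,
                         method = c("mean", "rpkm")) {
  method <- match.arg(method)
  if (inherits(coverages, "coverage_set")) coverages <- list(coverages)
  if (!length(coverages) || !length(coverages[[1L]]$counts)) return(character(0))
  ids <- names(coverages[[1L]]$counts)
  keep <- rep(TRUE, length(ids))
  for (cs in coverages) {
    stopifnot(identical(names(cs$counts), ids))
    for (i in seq_along(ids)) {
      m <- cs$counts[[i]]
      stat <- if (method == "mean") {
        colMeans(m)
      } else {
        colSums(m) * 1e9 / (nrow(m) * cs$lib_sizes)
      }
      if (any(stat < min_coverage)) keep[i] <- FALSE
    }
  }
  ids[keep]
}

#' Subset a coverage set to selected transcripts
#' @param coverage A \code{coverage_set}.
#' @param ids Transcript ids to keep.
#' @return A \code{coverage_set}.
#' @export
subset_coverage <- function(coverage, ids) {
  coverage_set(coverage$counts[ids], condition = coverage$condition)
}

#' Write coverage as a combined TSV
#'
#' Long-to-wide table: transcript, position (0-based, CDS frame), one column
#' per library.
#'
#' @param coverage A \code{coverage_set}.
#' @param path Output path.
#' @return Invisibly, the written data frame.
#' @export
write_coverage <- function(coverage, path) {
  rows <- lapply(names(coverage$counts), function(tx) {
    m <- coverage$counts[[tx]]
    data.frame(transcript = tx, position = seq_len(nrow(m)) - 1L, m,
               check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read coverage written by \code{write_coverage}
#' @param path TSV path.
#' @param condition Condition label to attach.
#' @return A \code{coverage_set}.
#' @export
read_coverage <- function(path, condition = "control") {
  df <- utils::read.delim(path, check.names = FALSE)
  libs <- setdiff(names(df), c("transcript", "position"))
  counts <- lapply(split(df, df$transcript), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    m <- as.matrix(d[, libs, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- NULL
    m
  })
  coverage_set(counts[unique(df$transcript)], condition = condition)
}
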