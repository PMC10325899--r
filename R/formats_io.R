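# Readers/writers and the single coordinate convention shared by all modules.
# All coordinates are 0-based half-open in transcript space; `to_display_coords`
# is the only place 1-based coordinates are produced.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Translate a CDS nucleotide sequence
#'
#' Translates with the standard genetic code. The CDS must be in frame and end
#' in a stop codon, which is dropped from the returned protein. Codons
#' containing N translate to \code{"X"}; internal stop codons are an error.
#'
#' @param seq Character scalar, CDS nucleotide sequence (alphabet A/C/G/T/N).
#' @param id Transcript identifier used in error messages.
#' @return Character scalar amino-acid sequence (terminal stop excluded).
#' @export
translate_cds <- function(seq, id = "<cds>") {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("CDS of '", id, "' has length ", n, ", not divisible by 3")
  }
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # fuzzy codons (N bases)
  n_cod <- length(aa)
  if (aa[n_cod] != "*") {
    stop("CDS of '", id, "' does not end in a stop codon")
  }
  aa <- aa[-n_cod]
  if (any(aa == "*")) {
    stop("CDS of '", id, "' contains an internal stop codon at codon ",
         which(aa == "*")[1L] - 1L, " (0-based)")
  }
  paste(aa, collapse = "")
}

#' Build a transcript set from sequences and CDS boundaries
#'
#' @param id Character vector of transcript identifiers.
#' @param sequence Character vector of transcript nucleotide sequences.
#' @param cds_start,cds_end Integer vectors, 0-based half-open CDS bounds in
#'   transcript coordinates; the terminal stop codon is part of the CDS.
#' @return A data frame of class \code{transcript_set} with columns
#'   \code{id}, \code{sequence}, \code{cds_start}, \code{cds_end} and the
#'   derived \code{protein} (terminal stop excluded).
#' @export
transcript_set <- function(id, sequence, cds_start, cds_end) {
  stopifnot(length(id) == length(sequence),
            length(id) == length(cds_start),
            length(id) == length(cds_end))
  if (anyDuplicated(id)) stop("duplicated transcript ids")
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  bad <- cds_start < 0L | cds_end > nchar(sequence) | cds_start >= cds_end
  if (any(bad)) {
    stop("CDS outside sequence bounds for transcript '", id[which(bad)[1L]], "'")
  }
  protein <- vapply(seq_along(id), function(i) {
    translate_cds(substr(sequence[i], cds_start[i] + 1L, cds_end[i]), id[i])
  }, character(1L))
  out <- data.frame(id = as.character(id), sequence = as.character(sequence),
                    cds_start = cds_start, cds_end = cds_end,
                    protein = protein, stringsAsFactors = FALSE)
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set with", nrow(x), "transcripts\n")
  cat("  CDS lengths:", paste(range(x$cds_end - x$cds_start), collapse = "-"),
      "nt\n")
  invisible(x)
}

#' CDS length (nt) per transcript
#' @param transcripts A \code{transcript_set}.
#' @return Named integer vector.
#' @export
cds_length <- function(transcripts) {
  stats::setNames(transcripts$cds_end - transcripts$cds_start, transcripts$id)
}

#' Read transcripts from FASTA plus annotation TSV
#'
#' The annotation TSV must have a header with columns \code{transcript_id},
#' \code{cds_start}, \code{cds_end} (0-based half-open, transcript
#' coordinates). Every annotation row must name a FASTA record.
#'
#' @param fasta_path Path to a (optionally gzipped) FASTA file.
#' @param annotation_path Path to the annotation TSV.
#' @return A \code{transcript_set}.
#' @export
read_transcripts <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  required <- c("transcript_id", "cds_start", "cds_end")
  if (!all(required %in% names(ann))) {
    stop("annotation must contain columns: ", paste(required, collapse = ", "))
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(ann$transcript_id, names(seqs))
  if (length(missing)) {
    stop("annotation names transcripts absent from FASTA: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  transcript_set(id = ann$transcript_id,
                 sequence = as.character(seqs[ann$transcript_id]),
                 cds_start = ann$cds_start, cds_end = ann$cds_end)
}

#' Write transcripts to FASTA plus annotation TSV
#' @param transcripts A \code{transcript_set}.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the transcript set.
#' @export
write_transcripts <- function(transcripts, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(stats::setNames(transcripts$sequence,
                                                   transcripts$id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- data.frame(transcript_id = transcripts$id,
                    cds_start = transcripts$cds_start,
                    cds_end = transcripts$cds_end)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(transcripts)
}

#' Construct an eCLIP-style peak table
#'
#' @param transcript Character vector of transcript ids.
#' @param start,end Integer vectors, 0-based half-open peak bounds.
#' @param fold_enrichment Non-negative enrichment over the size-matched input.
#' @param p_value Peak significance p-value in [0, 1].
#' @return Data frame of class \code{peak_table} with derived \code{center}
#'   (= floor((start + end) / 2)).
#' @export
peak_table <- function(transcript, start, end, fold_enrichment, p_value) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("peak start must be < end")
  if (any(fold_enrichment < 0)) stop("fold_enrichment must be >= 0")
  if (any(p_value < 0 | p_value > 1)) stop("p_value must be in [0, 1]")
  out <- data.frame(transcript = as.character(transcript), start = start,
                    end = end, fold_enrichment = fold_enrichment,
                    p_value = p_value,
                    center = (start + end) %/% 2L,
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Filter peaks on enrichment and significance
#'
#' Retains peaks with \code{fold_enrichment > min_fold} and
#' \code{p_value < max_p}; both inequalities are strict.
#'
#' @param peaks A \code{peak_table}.
#' @param min_fold Minimum fold enrichment (exclusive); default 8.
#' @param max_p Maximum p-value (exclusive); default 1e-5.
#' @return The retained subset, same class.
#' @export
filter_peaks <- function(peaks, min_fold = 8, max_p = 1e-5) {
  keep <- peaks$fold_enrichment > min_fold & peaks$p_value < max_p
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write peak tables as TSV
#' @param path File path (gzip-transparent on read).
#' @return \code{read_peaks}: a \code{peak_table}.
#' @export
read_peaks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  peak_table(df$transcript, df$start, df$end, df$fold_enrichment, df$p_value)
}

#' @rdname read_peaks
#' @param peaks A \code{peak_table}.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(peaks[, c("transcript", "start", "end",
                               "fold_enrichment", "p_value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(peaks)
}

#' Read / write BED6 footprint tables
#'
#' BED6 columns: chrom (transcript id), start, end (0-based half-open), name,
#' score (read length), strand. No header row.
#'
#' @param path File path.
#' @return \code{read_bed6}: data frame with BED6 columns.
#' @export
read_bed6 <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$score <- as.integer(df$score)
  df
}

#' @rdname read_bed6
#' @param bed Data frame with columns chrom, start, end, name, score, strand.
#' @export
write_bed6 <- function(bed, path) {
  utils::write.table(bed[, c("chrom", "start", "end", "name", "score",
                             "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(bed)
}

#' Convert internal 0-based half-open coordinates to 1-based display form
#' @param start,end 0-based half-open interval.
#' @return Data frame with 1-based inclusive \code{start}, \code{end}.
#' @export
to_display_coords <- function(start, end) {
  data.frame(start = as.integer(start) + 1L, end = as.integer(end))
}
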