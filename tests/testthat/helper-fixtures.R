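# Fixtures are built in code; nothing is read from disk.

# one codon per residue (first in the standard-code table), for building
# transcripts whose protein is chosen exactly
CODON_OF <- local({
  code <- Biostrings::GENETIC_CODE
  vapply(ribopause:::AA20, function(a) names(code)[code == a][1L],
         character(1L))
})

# transcript whose CDS encodes `protein` exactly (plus ATG start handling:
# the first residue of `protein` is the initiator M unless supplied)
tx_from_protein <- function(protein, id = "tx1", utr5 = 12L, utr3 = 12L) {
  aa <- strsplit(protein, "")[[1L]]
  codons <- CODON_OF[aa]
  seq <- paste0(strrep("A", utr5), paste(codons, collapse = ""), "TAA",
                strrep("T", utr3))
  transcript_set(id = id, sequence = seq, cds_start = utr5,
                 cds_end = utr5 + 3L * (length(aa) + 1L))
}

tx_set_from_proteins <- function(proteins, utr5 = 12L, utr3 = 12L) {
  sets <- lapply(seq_along(proteins), function(i) {
    tx_from_protein(proteins[i], id = sprintf("tx%03d", i), utr5, utr3)
  })
  out <- do.call(rbind, sets)
  class(out) <- c("transcript_set", "data.frame")
  out
}

# coverage_set with constant per-library counts for one gene
constant_coverage <- function(per_lib_value, L = 30L, tx = "tx1",
                              condition = "control") {
  m <- vapply(per_lib_value, function(v) rep(v, L), numeric(L))
  m <- matrix(m, nrow = L,
              dimnames = list(NULL, paste0("lib", seq_along(per_lib_value))))
  coverage_set(stats::setNames(list(m), tx), condition = condition)
}

# brute-force inclusive NB upper tail by direct summation, stopping when the
# remaining mass is below 1e-12 (independent of pnbinom's tail path)
nb_tail_bruteforce <- function(x, mu, size) {
  vapply(x, function(xi) {
    if (xi <= 0) return(1)
    j <- xi
    total <- 0
    repeat {
      d <- stats::dnbinom(j, size = size, mu = mu)
      total <- total + d
      j <- j + 1L
      if (d < 1e-16 && j > mu + 20 * sqrt(mu + mu^2 / size)) break
    }
    total
  }, numeric(1L))
}

# chi-square upper tail with 2R df via the finite Poisson-mixture series,
# an independent closed form for Fisher's statistic
fisher_tail_series <- function(stat, R) {
  h <- stat / 2
  exp(-h) * sum(h^(0:(R - 1L)) / factorial(0:(R - 1L)))
}
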