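test_that("generators are deterministic given the configuration", {
  cfg <- sim_config(n_genes = 8, cds_len_range = c(300, 600), seed = 3)
  a <- gen_transcripts(cfg)
  b <- gen_transcripts(cfg)
  expect_identical(a, b)
  expect_identical(gen_coverage(a$transcripts, a$truth, cfg, "control"),
                   gen_coverage(b$transcripts, b$truth, cfg, "control"))
  cov <- gen_coverage(a$transcripts, a$truth, cfg, "control")
  expect_identical(gen_footprints(cov, a$transcripts, cfg),
                   gen_footprints(cov, a$transcripts, cfg))
  expect_identical(gen_peaks(a$transcripts, a$truth, cfg),
                   gen_peaks(a$transcripts, a$truth, cfg))
  expect_identical(gen_spectra(n_proteins = 20, seed = 4),
                   gen_spectra(n_proteins = 20, seed = 4))
})

test_that("tract-free configuration yields no tracts, pauses or peaks", {
  cfg <- sim_config(n_genes = 5, cds_len_range = c(300, 600),
                    tract_rate = 0, seed = 2)
  gen <- gen_transcripts(cfg)
  expect_equal(nrow(gen$truth$tracts), 0L)
  expect_equal(nrow(gen$truth$pauses), 0L)
  expect_equal(nrow(gen_peaks(gen$transcripts, gen$truth, cfg)$peaks), 0L)
})

test_that("planted tracts are in-frame runs of the tract residues", {
  cfg <- sim_config(n_genes = 50, cds_len_range = c(600, 1500),
                    tract_rate = 2, seed = 5)
  gen <- gen_transcripts(cfg)
  tx <- gen$transcripts
  expect_true(all((tx$cds_end - tx$cds_start) %% 3L == 0L))
  expect_equal(nchar(tx$protein), (tx$cds_end - tx$cds_start) / 3L - 1L)
  tr <- gen$truth$tracts
  for (i in seq_len(nrow(tr))) {
    prot <- tx$protein[tx$id == tr$transcript[i]]
    residues <- strsplit(substr(prot, tr$aa_start[i] + 1L, tr$aa_end[i]),
                         "")[[1L]]
    expect_true(all(residues %in% cfg$tract_residues))
  }
  # no overlapping tracts within a transcript
  by_tx <- split(tr, tr$transcript)
  for (d in by_tx) {
    d <- d[order(d$aa_start), ]
    if (nrow(d) > 1L) expect_true(all(d$aa_start[-1L] >= d$aa_end[-nrow(d)]))
  }
  # Poisson sampling of tract counts: mean within 2 SE of the rate
  n_per_gene <- table(factor(tr$transcript, levels = tx$id))
  se <- sqrt(2 / 50)
  expect_lt(abs(mean(n_per_gene) - 2), 2 * se + 1e-9)
})

test_that("every pause lies inside its CDS at the first nt of a codon", {
  cfg <- sim_config(n_genes = 30, seed = 8)
  gen <- gen_transcripts(cfg)
  p <- gen$truth$pauses
  lens <- cds_length(gen$transcripts)
  expect_true(all(p$position %% 3L == 0L))
  expect_true(all(p$position >= 0 & p$position < lens[p$transcript]))
  expect_equal(p$factor_control, rep(10, nrow(p)))
  expect_equal(p$factor_knockdown, rep(1 + 9 * 0.2, nrow(p)))
})

test_that("coverage matches NB moment identities at non-pause positions", {
  cfg <- sim_config(n_genes = 1, cds_len_range = c(100002, 100002),
                    tract_rate = 0, pause_rate = 0,
                    expr_log_mean = log(10), expr_log_sd = 0,
                    nb_size = 5, n_replicates = 1, seed = 9)
  gen <- gen_transcripts(cfg)
  cov <- gen_coverage(gen$transcripts, gen$truth, cfg, "control")
  x <- cov$counts[[1L]][-1L, 1L]  # position 0 carries the initiation peak
  expect_lt(abs(mean(x) - 10) / 10, 0.01)
  expect_lt(abs(stats::var(x) - 30) / 30, 0.05)
})

test_that("pause_factor 1 leaves pause positions indistinguishable", {
  cfg <- sim_config(n_genes = 40, cds_len_range = c(1500, 3000),
                    pause_factor = 1, expr_log_sd = 0,
                    expr_log_mean = log(10), seed = 10)
  gen <- gen_transcripts(cfg)
  cov <- gen_coverage(gen$transcripts, gen$truth, cfg, "control")
  p <- gen$truth$pauses
  at_pause <- unlist(lapply(seq_len(nrow(p)), function(i) {
    cov$counts[[p$transcript[i]]][p$position[i] + 1L, ]
  }))
  elsewhere <- unlist(lapply(cov$counts, function(m) as.vector(m[-1L, ])))
  expect_gt(stats::wilcox.test(at_pause, elsewhere)$p.value, 0.01)
})

test_that("zero attenuation collapses the knockdown pause mean to the gene mean", {
  cfg <- sim_config(n_genes = 80, cds_len_range = c(900, 1500),
                    knockdown_attenuation = 0, expr_log_sd = 0,
                    expr_log_mean = log(10), seed = 11)
  gen <- gen_transcripts(cfg)
  expect_true(all(gen$truth$pauses$factor_knockdown == 1))
  cov <- gen_coverage(gen$transcripts, gen$truth, cfg, "knockdown")
  p <- gen$truth$pauses
  at_pause <- unlist(lapply(seq_len(nrow(p)), function(i) {
    cov$counts[[p$transcript[i]]][p$position[i] + 1L, ]
  }))
  se <- sqrt(30 / length(at_pause))  # NB(10, 5) variance over n draws
  expect_lt(abs(mean(at_pause) - 10), 3 * se)
})

test_that("unknown condition labels are rejected", {
  cfg <- sim_config(n_genes = 2, cds_len_range = c(300, 450), seed = 1)
  gen <- gen_transcripts(cfg)
  expect_error(gen_coverage(gen$transcripts, gen$truth, cfg, "treated"))
})

test_that("fixed-length footprints sit exactly offset nt upstream of P-sites", {
  cfg <- sim_config(n_genes = 4, cds_len_range = c(300, 450),
                    read_len_range = c(30, 30),
                    true_offsets = c("30" = 12L), seed = 12)
  gen <- gen_transcripts(cfg)
  cov <- gen_coverage(gen$transcripts, gen$truth, cfg, "control")
  fps <- gen_footprints(cov, gen$transcripts, cfg)
  cds_start <- stats::setNames(gen$transcripts$cds_start, gen$transcripts$id)
  for (bed in fps) {
    expect_true(all(bed$score == 30L))
    psite <- bed$start + 12L - cds_start[bed$chrom]
    expect_true(all(psite >= 0))
    # rebuilding coverage from reads with the true offset is exact
  }
  off <- structure(list(offsets = c("30" = 12L)), class = "offset_table")
  rebuilt <- build_coverage(fps, off, gen$transcripts)
  expect_identical(rebuilt$counts, cov$counts)
})

test_that("footprint totals are conserved up to logged clipping", {
  cfg <- sim_config(n_genes = 6, cds_len_range = c(300, 600),
                    utr_len_range = c(5, 8), seed = 13)
  gen <- gen_transcripts(cfg)
  cov <- gen_coverage(gen$transcripts, gen$truth, cfg, "control")
  fps <- gen_footprints(cov, gen$transcripts, cfg)
  total_cov <- sum(vapply(cov$counts, sum, numeric(1L)))
  for (lib in names(fps)) {
    in_lib <- sum(vapply(cov$counts, function(m) sum(m[, lib]), numeric(1L)))
    expect_equal(nrow(fps[[lib]]) + attr(fps[[lib]], "clipped"), in_lib)
  }
  # short UTRs force some clipping, so the log is exercised
  expect_gt(sum(vapply(fps, attr, integer(1L), "clipped")), 0L)
})

test_that("peaks are placed the configured codons downstream of tract ends", {
  cfg <- sim_config(n_genes = 40, cds_len_range = c(600, 1200),
                    pause_offset_range = c(2, 2), seed = 14)
  gen <- gen_transcripts(cfg)
  pk <- gen_peaks(gen$transcripts, gen$truth, cfg)
  tr <- gen$truth$tracts
  plen <- stats::setNames(nchar(gen$transcripts$protein),
                          gen$transcripts$id)
  expect_equal(pk$truth$codon,
               unname(pmin(plen[tr$transcript] - 1L, tr$aa_end - 1L + 2L)))
  # derived midpoint equals the intended center
  expect_equal(pk$peaks$center, pk$truth$center_nt)
  # and the center maps inside the CDS
  idx <- match(pk$peaks$transcript, gen$transcripts$id)
  expect_true(all(pk$peaks$center >= gen$transcripts$cds_start[idx] &
                    pk$peaks$center < gen$transcripts$cds_end[idx]))
})

test_that("the configured fraction of peaks fails the significance filter", {
  cfg <- sim_config(n_genes = 120, cds_len_range = c(900, 1500),
                    tract_rate = 2, seed = 15)
  gen <- gen_transcripts(cfg)
  pk <- gen_peaks(gen$transcripts, gen$truth, cfg, fraction_failing = 0.5)
  n <- nrow(pk$peaks)
  surv <- nrow(filter_peaks(pk$peaks))
  expect_equal(surv, sum(pk$truth$passes_filter))
  expect_lt(abs(surv - 0.5 * n), 2 * sqrt(n * 0.25) + 1e-9)
})

test_that("spectral counts are Poisson-like with the configured ER split", {
  sp <- gen_spectra(n_proteins = 60, compartment_bias = 0,
                    n_replicates = 100, seed = 16)
  expect_true(all(sp$truth$er_frac == 0.5))
  # zero-bias interactor: expected percent ER is 50
  tab <- sp$table
  ints <- sp$truth$protein[sp$truth$is_interactor]
  er <- tab[tab$pool == "mrnp" & tab$compartment == "ER" &
              tab$protein %in% ints, ]
  cy <- tab[tab$pool == "mrnp" & tab$compartment == "cyto" &
              tab$protein %in% ints, ]
  expect_lt(abs(sum(er$count) / (sum(er$count) + sum(cy$count)) - 0.5), 0.02)
  # dispersion index near 1 for a Poisson pool
  one <- er[er$protein == ints[1L], "count"]
  expect_lt(abs(stats::var(one) / mean(one) - 1), 0.5)
})
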