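test_that("peak centers map to codons by floor division from cds_start", {
  ts <- tx_set_from_proteins(strrep("MKEDR", 20), utr5 = 12L)  # CDS at 12
  peaks <- peak_table(rep("tx001", 3),
                      start = c(12L, 17L, 400L), end = c(13L, 18L, 401L),
                      fold_enrichment = rep(20, 3), p_value = rep(1e-9, 3))
  anchors <- peaks_to_anchors(peaks, ts)
  expect_equal(anchors$codon, c(0L, 1L))  # centers 12, 17 -> codons 0, 1
  expect_equal(attr(anchors, "excluded"), 1L)  # 3'UTR center tallied
  expect_equal(attr(anchors, "source"), "clip_peak")
})

test_that("pause anchors use the P-site codon", {
  ts <- tx_set_from_proteins(strrep("MKEDR", 20))
  pauses <- data.frame(transcript = "tx001", position = c(0L, 7L, 33L))
  a <- pauses_to_anchors(pauses, ts)
  expect_equal(a$codon, c(0L, 2L, 11L))
  expect_equal(attr(a, "source"), "pause_site")
})

test_that("a single anchor gives a point-mass frequency at offset zero", {
  ts <- tx_set_from_proteins(paste0("MAAAA", "K", "AAAAA"))
  anchors <- data.frame(transcript = "tx001", codon = 5L)
  prof <- positional_enrichment(anchors, ts, window = 3, n_perm = 10,
                                seed = 1)
  expect_equal(unname(prof$freq["K", "0"]), 1)
  expect_equal(sum(prof$freq[, "0"]), 1)
})

test_that("per-offset frequencies sum to one wherever residues contribute", {
  cfg <- sim_config(n_genes = 20, cds_len_range = c(600, 900), seed = 42)
  gen <- gen_transcripts(cfg)
  pk <- gen_peaks(gen$transcripts, gen$truth, cfg, fraction_failing = 0)
  anchors <- peaks_to_anchors(pk$peaks, gen$transcripts)
  prof <- positional_enrichment(anchors, gen$transcripts, n_perm = 20,
                                seed = 2)
  sums <- colSums(prof$freq)
  expect_equal(unname(sums[prof$n_contributing > 0]),
               rep(1, sum(prof$n_contributing > 0)))
})

test_that("enrichment is invariant to duplicating every transcript", {
  cfg <- sim_config(n_genes = 12, cds_len_range = c(600, 900), seed = 43)
  gen <- gen_transcripts(cfg)
  pk <- gen_peaks(gen$transcripts, gen$truth, cfg, fraction_failing = 0)
  anchors <- peaks_to_anchors(pk$peaks, gen$transcripts)
  prof1 <- positional_enrichment(anchors, gen$transcripts, n_perm = 5,
                                 seed = 3)
  dup <- gen$transcripts
  dup$id <- paste0(dup$id, "_copy")
  both <- rbind(gen$transcripts, dup)
  class(both) <- c("transcript_set", "data.frame")
  anchors2 <- rbind(anchors,
                    transform(anchors, transcript = paste0(transcript,
                                                           "_copy")))
  prof2 <- positional_enrichment(anchors2, both, n_perm = 5, seed = 3)
  expect_equal(prof2$freq, prof1$freq)
  expect_equal(prof2$log2_enrichment, prof1$log2_enrichment)
})

test_that("poly-K tract signal is upstream-confined against a flat background", {
  # proteins drawn uniformly over the 20 residues, one 10-aa poly-K tract
  # each, anchor 2 codons after the tract end; supplied flat background
  set.seed(44)
  prots <- vapply(1:1000, function(i) {
    aa <- sample(ribopause:::AA20, 200, replace = TRUE)
    aa[1] <- "M"
    aa[120:129] <- "K"
    paste(aa, collapse = "")
  }, character(1L))
  ts <- tx_set_from_proteins(prots)
  anchors <- data.frame(transcript = ts$id, codon = 130L)
  flat <- stats::setNames(rep(1 / 20, 20), ribopause:::AA20)
  prof <- positional_enrichment(anchors, ts, background = flat,
                                n_perm = 20, seed = 4)
  up <- as.character(-11:-2)
  expect_true(all(prof$log2_enrichment["K", up] > 1))
  # downstream of the anchor the K signal is flat at background level
  down <- as.character(5:30)
  expect_lt(stats::median(abs(prof$log2_enrichment["K", down])), 0.2)
  expect_lt(max(abs(prof$log2_enrichment["K", down])), 1)
})

test_that("permutation p-values are calibrated for uniform anchors", {
  cfg <- sim_config(n_genes = 60, cds_len_range = c(600, 900),
                    tract_rate = 0, seed = 45)
  gen <- gen_transcripts(cfg)
  set.seed(46)
  idx <- sample(nrow(gen$transcripts), 400, replace = TRUE)
  plen <- nchar(gen$transcripts$protein)[idx]
  anchors <- data.frame(transcript = gen$transcripts$id[idx],
                        codon = floor(stats::runif(400) * plen))
  prof <- positional_enrichment(anchors, gen$transcripts, n_perm = 100,
                                seed = 5)
  expect_lt(mean(prof$perm_p < 0.05, na.rm = TRUE), 0.10)
  expect_lte(max(abs(prof$log2_enrichment), na.rm = TRUE),
             prof$max_envelope * 1.25)
})

test_that("a window wider than every protein errors", {
  ts <- tx_set_from_proteins("MKEDR")
  anchors <- data.frame(transcript = "tx001", codon = 2L)
  expect_error(positional_enrichment(anchors, ts, window = 30, n_perm = 5),
               "window")
  expect_error(positional_enrichment(anchors[0, ], ts), "no anchors")
})

test_that("charge classes add frequencies and reject overlap", {
  ts <- tx_set_from_proteins(paste0("M", strrep("G", 40)))
  anchors <- data.frame(transcript = "tx001", codon = 20L)
  prof <- positional_enrichment(anchors, ts, window = 5, n_perm = 5,
                                seed = 6)
  cc <- charge_profile(prof)
  expect_equal(cc$positive, rep(0, 11))
  expect_equal(cc$negative, rep(0, 11))
  expect_equal(cc$neutral, rep(1, 11))
  expect_error(charge_profile(prof, positive = c("K", "R"),
                              negative = c("R", "D")), "overlap")
  # additivity on a mixed window
  ts2 <- tx_set_from_proteins(paste0("M", strrep("KKKRDDDEGG", 5)))
  prof2 <- positional_enrichment(data.frame(transcript = "tx001",
                                            codon = 25L),
                                 ts2, window = 4, n_perm = 5, seed = 7)
  cc2 <- charge_profile(prof2)
  expect_equal(cc2$positive + cc2$negative + cc2$neutral, rep(1, 9))
  expect_equal(cc2$positive,
               colSums(prof2$freq[c("K", "R"), , drop = FALSE]),
               ignore_attr = TRUE)
})

test_that("region distribution classifies centers and bins the metagene", {
  ts <- tx_set_from_proteins(strrep("MKEDR", 20), utr5 = 50L, utr3 = 50L)
  # transcript length = 50 + 303 + 50 = 403; CDS = [50, 353)
  peaks <- peak_table(rep("tx001", 4),
                      start = c(0L, 10L, 100L, 380L),
                      end = c(1L, 11L, 101L, 381L),
                      fold_enrichment = rep(10, 4), p_value = rep(1e-9, 4))
  rd <- region_distribution(peaks, ts, n_bins = 10)
  expect_equal(unname(rd$counts), c(2L, 1L, 1L))
  expect_equal(sum(rd$fractions), 1)
  expect_equal(rd$metagene[1L], 2L)  # centers 0 and 10 in the first bin
  expect_equal(sum(rd$metagene), 4L)
})

test_that("uniform peak centers pass a chi-square uniformity check", {
  set.seed(47)
  ts <- tx_set_from_proteins(strrep("MKEDRAAAAA", 60), utr5 = 0L, utr3 = 0L)
  L <- nchar(ts$sequence)
  centers <- floor(stats::runif(2000) * L)
  peaks <- peak_table(rep("tx001", 2000), centers, centers + 1L,
                      rep(10, 2000), rep(1e-9, 2000))
  rd <- region_distribution(peaks, ts, n_bins = 20)
  expect_gt(stats::chisq.test(rd$metagene)$p.value, 0.01)
})

test_that("set overlap matches exact hypergeometric enumeration", {
  u <- paste0("g", 1:10)
  res <- overlap_enrichment(u[1:5], u[1:4], u)
  # oracle: enumerate all C(10, 4) draws of B and count overlaps >= 4
  combos <- utils::combn(10, 4)
  exceed <- mean(colSums(combos <= 5) >= 4)
  expect_equal(res$p, exceed)
  expect_equal(res$p, 5 / 210)
  expect_equal(res$overlap, 4L)
  # independence: overlap equal to expectation gives fold 1
  res2 <- overlap_enrichment(u[1:5], u[c(1, 2, 6, 7)], u)
  expect_equal(res2$fold, 1)  # expected = 5 * 4 / 10 = 2 = observed
  # A inside B = U gives p = 1
  res3 <- overlap_enrichment(u[1:3], u, u)
  expect_equal(res3$p, 1)
  expect_error(overlap_enrichment(u[1:2], u[1:2], character(0)), "universe")
  expect_error(overlap_enrichment(c(u[1], "zz"), u[1:2], u), "subsets")
})
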