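# Differential pause-site analysis: median-of-ratios size factors, a
# negative binomial likelihood-ratio test at a common dispersion shared
# across sites, BH correction, and the gene-coherence fold-change filter.

#' Median-of-ratios size factors
#'
#' Size factors against the geometric-mean pseudo-reference, rescaled to
#' geometric mean 1. When fewer than 10 genes are nonzero in every library
#' the estimator falls back to total-count ratios.
#'
#' @param counts Gene-by-library count matrix (>= 2 libraries).
#' @return Named positive numeric vector, one factor per library.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2)
  if (all(counts == 0)) stop("all-zero count matrix")
  nz <- rowSums(counts > 0) == ncol(counts)
  if (sum(nz) >= 10) {
    logc <- log(counts[nz, , drop = FALSE])
    ref <- rowMeans(logc)
    sf <- apply(logc, 2L, function(col) exp(stats::median(col - ref)))
  } else {
    sf <- colSums(counts)
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

# NB log-likelihood at known size k for counts y with means mu * s
nb_loglik <- function(y, s, mu, k) {
  if (mu == 0) return(if (all(y == 0)) 0 else -Inf)
  sum(stats::dnbinom(y, size = k, mu = mu * s, log = TRUE))
}

# MLE of the common mean mu for y_i ~ NB(mu * s_i, k); score is decreasing
nb_fit_mu <- function(y, s, k) {
  if (all(y == 0)) return(0)
  score <- function(mu) sum(y / mu - (y + k) * s / (mu * s + k))
  hi <- max(y / s) + 1
  while (score(hi) > 0) hi <- hi * 2
  stats::uniroot(score, c(1e-12, hi), tol = 1e-10)$root
}

#' Common NB dispersion across sites by method of moments
#'
#' For each site the pooled within-group variance of size-factor-normalized
#' counts is computed; the common dispersion is the moment regression of
#' (variance - technical mean term) on squared means across sites, floored
#' at \code{floor}.
#'
#' @param counts Site-by-library count matrix.
#' @param size_factors Per-library size factors.
#' @param groups Factor of condition labels, one per library.
#' @param floor Dispersion floor; default 1e-8.
#' @return Scalar dispersion phi (variance = mu + phi * mu^2).
#' @export
common_dispersion <- function(counts, size_factors, groups, floor = 1e-8) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  n <- sweep(counts, 2L, size_factors, "/")
  cinv <- mean(1 / size_factors)
  # per site and group: within-group variance s2_g estimates
  # c * mu_g + phi * mu_g^2; regress (s2_g - c * m_g) on an (approximately
  # unbiased) estimate of mu_g^2, pooled over sites and groups, weighted by
  # within-group degrees of freedom
  num <- 0; den <- 0
  for (g in levels(groups)) {
    ng <- n[, groups == g, drop = FALSE]
    R <- ncol(ng)
    if (R < 2) next
    mg <- rowMeans(ng)
    s2g <- rowSums((ng - mg)^2) / (R - 1)
    mu2g <- pmax(mg^2 - s2g / R, 0)  # E[m^2] = mu^2 + Var(m)
    w <- R - 1
    num <- num + w * sum((s2g - cinv * mg) * mu2g)
    den <- den + w * sum(mu2g^2)
  }
  phi <- if (den > 0) num / den else floor
  max(phi, floor)
}

#' NB likelihood-ratio test at one site
#'
#' Compares a per-group-mean model against a shared-mean model at a common
#' dispersion; p from the chi-square upper tail with (groups - 1) degrees of
#' freedom. The log2 fold change uses a 0.5 pseudo-count on normalized group
#' means and is oriented as second group level over first (perturbed over
#' control when levels are in that order).
#'
#' @param counts Integer vector of counts across libraries at one site.
#' @param size_factors Per-library size factors.
#' @param groups Factor of condition labels (2 levels; >= 2 replicates each
#'   recommended).
#' @param dispersion Common dispersion phi; see
#'   \code{\link{common_dispersion}}.
#' @return List: \code{log2fc}, \code{p_value}, \code{stat}.
#' @export
site_test <- function(counts, size_factors, groups, dispersion) {
  groups <- as.factor(groups)
  stopifnot(length(counts) == length(size_factors),
            length(counts) == length(groups),
            nlevels(groups) >= 2)
  k <- 1 / max(dispersion, 1e-8)
  mu0 <- nb_fit_mu(counts, size_factors, k)
  ll0 <- nb_loglik(counts, size_factors, mu0, k)
  ll1 <- 0
  gmeans <- numeric(nlevels(groups))
  for (i in seq_len(nlevels(groups))) {
    sel <- groups == levels(groups)[i]
    mug <- nb_fit_mu(counts[sel], size_factors[sel], k)
    gmeans[i] <- mean(counts[sel] / size_factors[sel])
    ll1 <- ll1 + nb_loglik(counts[sel], size_factors[sel], mug, k)
  }
  stat <- max(0, 2 * (ll1 - ll0))
  p <- stats::pchisq(stat, df = nlevels(groups) - 1L, lower.tail = FALSE)
  log2fc <- log2((gmeans[2L] + 0.5) / (gmeans[1L] + 0.5))
  list(log2fc = log2fc, p_value = p, stat = stat)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")} kept as the
#' module's single FDR entry point.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted values (step-up), same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Gene-level differential ribosome occupancy
#'
#' Applies the same NB LRT to summed CDS counts per gene, BH-adjusts across
#' genes, and flags genes with FDR <= \code{fdr_threshold}.
#'
#' @param gene_counts Gene-by-library matrix of summed CDS counts.
#' @param size_factors Per-library size factors.
#' @param groups Condition factor.
#' @param fdr_threshold Differential-gene FDR cutoff; default 0.05.
#' @return Data frame: \code{transcript}, \code{log2fc_gene}, \code{p_value},
#'   \code{fdr}, \code{gene_is_differential}.
#' @export
gene_occupancy_fc <- function(gene_counts, size_factors, groups,
                              fdr_threshold = 0.05) {
  gene_counts <- as.matrix(gene_counts)
  if (!nrow(gene_counts)) stop("empty gene count matrix")
  phi <- common_dispersion(gene_counts, size_factors, groups)
  res <- t(vapply(seq_len(nrow(gene_counts)), function(i) {
    st <- site_test(gene_counts[i, ], size_factors, groups, phi)
    c(st$log2fc, st$p_value)
  }, numeric(2L)))
  fdr <- bh_adjust(res[, 2L])
  data.frame(transcript = rownames(gene_counts),
             log2fc_gene = res[, 1L], p_value = res[, 2L], fdr = fdr,
             gene_is_differential = fdr <= fdr_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene-coherence filter on differential pause sites
#'
#' Sites with FDR above \code{fdr_threshold} are \code{not_significant}.
#' Significant sites in genes without differential occupancy are
#' \code{retained}. Significant sites in differential genes are
#' \code{removed_coherence} iff |log2fc_site - log2fc_gene| < \code{delta}
#' (their fold change merely tracks the gene), else \code{retained}.
#'
#' @param records Data frame with columns \code{fdr}, \code{log2fc_site},
#'   \code{log2fc_gene}, \code{gene_is_differential}.
#' @param delta Coherence threshold on |delta log2FC|; default 0.8.
#' @param fdr_threshold Site significance cutoff; default 0.05.
#' @return \code{records} with a \code{disposition} factor column added.
#' @export
coherence_filter <- function(records, delta = 0.8, fdr_threshold = 0.05) {
  disposition <- rep("retained", nrow(records))
  disposition[records$fdr > fdr_threshold] <- "not_significant"
  sig <- records$fdr <= fdr_threshold
  tracks <- abs(records$log2fc_site - records$log2fc_gene) < delta
  disposition[sig & records$gene_is_differential & tracks] <- "removed_coherence"
  records$disposition <- factor(disposition,
                                levels = c("retained", "removed_coherence",
                                           "not_significant"))
  records
}

#' Differential pause-site analysis between two conditions
#'
#' Extracts counts at pause-site positions and gene-level CDS totals from
#' two coverage sets, estimates size factors from the gene totals, tests
#' each site and each gene with the NB LRT at a common dispersion, BH-adjusts
#' site p-values, and applies the gene-coherence filter.
#'
#' @param sites Data frame with columns \code{transcript}, \code{position}
#'   (e.g. called pauses from \code{\link{call_pauses}}).
#' @param cov_control,cov_perturbed \code{coverage_set}s for the two
#'   conditions, over the same transcripts.
#' @param fdr Site significance threshold; default 0.05.
#' @param coherence_delta Coherence threshold; default 0.8.
#' @param gene_fdr Gene differential-occupancy threshold; default 0.05.
#' @return Data frame of class \code{diff_pause_records}: site reference,
#'   per-library counts, \code{log2fc_site}, \code{log2fc_gene},
#'   \code{p_value}, \code{fdr}, \code{gene_is_differential},
#'   \code{disposition}.
#' @export
diff_pause_analysis <- function(sites, cov_control, cov_perturbed,
                                fdr = 0.05, coherence_delta = 0.8,
                                gene_fdr = 0.05) {
  stopifnot(identical(names(cov_control$counts), names(cov_perturbed$counts)))
  if (!nrow(sites)) stop("no pause sites supplied")
  libs_c <- cov_control$libraries
  libs_p <- cov_perturbed$libraries
  groups <- factor(rep(c("control", "perturbed"),
                       c(length(libs_c), length(libs_p))),
                   levels = c("control", "perturbed"))

  site_counts <- t(vapply(seq_len(nrow(sites)), function(i) {
    tx <- sites$transcript[i]; pos <- sites$position[i]
    c(cov_control$counts[[tx]][pos + 1L, ],
      cov_perturbed$counts[[tx]][pos + 1L, ])
  }, numeric(length(groups))))
  colnames(site_counts) <- c(libs_c, libs_p)

  txs <- names(cov_control$counts)
  gene_counts <- t(vapply(txs, function(tx) {
    c(colSums(cov_control$counts[[tx]]), colSums(cov_perturbed$counts[[tx]]))
  }, numeric(length(groups))))
  colnames(gene_counts) <- c(libs_c, libs_p)

  sf <- estimate_size_factors(gene_counts)
  phi <- common_dispersion(site_counts, sf, groups)
  st <- t(vapply(seq_len(nrow(site_counts)), function(i) {
    r <- site_test(site_counts[i, ], sf, groups, phi)
    c(r$log2fc, r$p_value)
  }, numeric(2L)))

  gene_res <- gene_occupancy_fc(gene_counts, sf, groups,
                                fdr_threshold = gene_fdr)
  gi <- match(sites$transcript, gene_res$transcript)

  records <- data.frame(transcript = sites$transcript,
                        position = sites$position,
                        site_counts, check.names = FALSE)
  records$log2fc_site <- st[, 1L]
  records$p_value <- st[, 2L]
  records$fdr <- bh_adjust(st[, 2L])
  records$log2fc_gene <- gene_res$log2fc_gene[gi]
  records$gene_is_differential <- gene_res$gene_is_differential[gi]
  records <- coherence_filter(records, delta = coherence_delta,
                              fdr_threshold = fdr)
  attr(records, "size_factors") <- sf
  attr(records, "dispersion") <- phi
  attr(records, "gene_results") <- gene_res
  class(records) <- c("diff_pause_records", "data.frame")
  records
}
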