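# Nucleotide-resolution pause-site calling: trimmed negative-binomial fit per
# gene and replicate, inclusive upper-tail p-values per position, Fisher
# combination across replicates, and a strict combined-p threshold.

#' Trim extreme counts before fitting
#'
#' Removes the m = floor(frac * L) largest and m smallest values. Ties break
#' by position order: among equal values the leftmost is removed first. For
#' L < 1/frac, m = 0 and the vector is returned unchanged.
#'
#' @param counts Numeric vector of per-position counts.
#' @param frac Fraction trimmed from each tail; default 0.05.
#' @return Numeric vector of retained counts, with attribute
#'   \code{removed_idx} (indices removed, 1-based).
#' @export
trim_outliers <- function(counts, frac = 0.05) {
  L <- length(counts)
  m <- floor(frac * L)
  if (m == 0L) {
    out <- counts
    attr(out, "removed_idx") <- integer(0)
    return(out)
  }
  asc <- order(counts)                      # stable: leftmost first among ties
  bottom <- asc[seq_len(m)]
  desc <- order(-counts)                    # stable: leftmost first among ties
  top <- setdiff(desc, bottom)[seq_len(m)]  # disjoint even when ties span
  removed <- c(bottom, top)
  out <- counts[-removed]
  attr(out, "removed_idx") <- sort(removed)
  out
}

#' Fit a negative binomial by method of moments
#'
#' mu is the sample mean; size = mu^2 / (s^2 - mu) with the unbiased sample
#' variance s^2. When s^2 <= mu the NB is not identifiable from moments and
#' the fit falls back to a Poisson with the same mean; an all-zero vector is
#' flagged degenerate (downstream p-values are all 1). An MLE estimator is
#' available behind \code{estimator = "mle"}.
#'
#' @param counts Numeric vector of retained counts (length >= 2).
#' @param estimator \code{"mom"} (default) or \code{"mle"}.
#' @return List of class \code{nb_params}: \code{mu}, \code{size},
#'   \code{fit_kind} (\code{negative_binomial}, \code{poisson_fallback} or
#'   \code{degenerate}), \code{n_used}.
#' @export
fit_nb <- function(counts, estimator = c("mom", "mle")) {
  estimator <- match.arg(estimator)
  stopifnot(length(counts) >= 2)
  m <- mean(counts)
  if (m == 0) {
    return(structure(list(mu = 0, size = NA_real_, fit_kind = "degenerate",
                          n_used = length(counts)), class = "nb_params"))
  }
  s2 <- stats::var(counts)
  if (s2 <= m) {
    return(structure(list(mu = m, size = NA_real_,
                          fit_kind = "poisson_fallback",
                          n_used = length(counts)), class = "nb_params"))
  }
  if (estimator == "mom") {
    size <- m^2 / (s2 - m)
  } else {
    # profile likelihood in log-size; mu MLE is the sample mean
    nll <- function(ls) -sum(stats::dnbinom(counts, size = exp(ls), mu = m,
                                            log = TRUE))
    size <- exp(stats::optimize(nll, c(-7, 14))$minimum)
  }
  structure(list(mu = m, size = size, fit_kind = "negative_binomial",
                 n_used = length(counts)), class = "nb_params")
}

# expected mean and variance of the retained part of an NB (or Poisson)
# after removing fraction f of probability mass from each tail; boundary
# atoms are partially removed, matching rank-based trimming of a sample
trimmed_count_moments <- function(mu, k, f, poisson = FALSE) {
  qmax <- if (poisson) {
    stats::qpois(1 - 1e-12, mu)
  } else {
    stats::qnbinom(1 - 1e-12, size = k, mu = mu)
  }
  x <- 0:max(qmax, 1L)
  Fx <- if (poisson) stats::ppois(x, mu) else stats::pnbinom(x, size = k, mu = mu)
  Fprev <- c(0, Fx[-length(Fx)])
  w <- pmin(Fx, 1 - f) - pmax(Fprev, f)
  w[w < 0] <- 0
  w <- w / sum(w)
  m1 <- sum(w * x)
  c(mean = m1, var = sum(w * x^2) - m1^2)
}

#' Fit a negative binomial to a trimmed sample by trimmed-moment matching
#'
#' Given counts retained after removing the fraction \code{frac} of values
#' from each tail, finds the NB (or, when the trimmed variance does not
#' exceed the trimmed Poisson variance, the Poisson) whose expected trimmed
#' moments match the observed trimmed mean and variance. This inverts the
#' downward bias that rank trimming induces in plain moment estimates, so
#' the fitted distribution estimates the full per-position count law, not
#' the trimmed one.
#'
#' @param retained Numeric vector of retained counts (output of
#'   \code{\link{trim_outliers}}).
#' @param frac Effective trim fraction actually removed from each tail
#'   (use \code{m / L}); 0 reduces to \code{\link{fit_nb}}.
#' @return An \code{nb_params} (fit kinds as in \code{\link{fit_nb}}).
#' @export
fit_nb_trimmed <- function(retained, frac) {
  if (frac <= 0) return(fit_nb(retained))
  stopifnot(frac < 0.5, length(retained) >= 2)
  m <- mean(retained)
  if (m == 0) {
    return(structure(list(mu = 0, size = NA_real_, fit_kind = "degenerate",
                          n_used = length(retained)), class = "nb_params"))
  }
  v <- stats::var(retained)
  # Poisson with matched trimmed mean, as the equidispersed reference
  pois_mu <- tryCatch(
    stats::uniroot(function(mm) trimmed_count_moments(mm, NA, frac,
                                                      poisson = TRUE)[1L] - m,
                   c(max(m / 4, 1e-6), 4 * m + 10), tol = 1e-8)$root,
    error = function(e) m)
  pois_var <- trimmed_count_moments(pois_mu, NA, frac, poisson = TRUE)[2L]
  if (v <= pois_var || v <= 0) {
    return(structure(list(mu = pois_mu, size = NA_real_,
                          fit_kind = "poisson_fallback",
                          n_used = length(retained)), class = "nb_params"))
  }
  start <- fit_nb(retained)
  k0 <- if (start$fit_kind == "negative_binomial") start$size else 10
  obj <- function(par) {
    mm <- trimmed_count_moments(exp(par[1L]), exp(par[2L]), frac)
    (mm[1L] / m - 1)^2 + (mm[2L] / v - 1)^2
  }
  opt <- stats::optim(c(log(max(m, 1e-3)), log(k0)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  structure(list(mu = exp(opt$par[1L]), size = exp(opt$par[2L]),
                 fit_kind = "negative_binomial",
                 n_used = length(retained)), class = "nb_params")
}

#' @export
print.nb_params <- function(x, ...) {
  cat("nb_params:", x$fit_kind, " mu =", signif(x$mu, 4),
      if (x$fit_kind == "negative_binomial") paste("size =", signif(x$size, 4)),
      " n =", x$n_used, "\n")
  invisible(x)
}

#' Inclusive upper-tail p-value for observed counts
#'
#' p = P(X >= x) under the fitted distribution; p(0) = 1 by construction.
#' Degenerate fits return 1 for every position.
#'
#' @param x Non-negative integer vector of observed counts.
#' @param params An \code{nb_params}.
#' @return Numeric vector of p-values.
#' @export
position_pvalue <- function(x, params) {
  stopifnot(all(x >= 0))
  switch(params$fit_kind,
    degenerate = rep(1, length(x)),
    poisson_fallback = stats::ppois(x - 1, lambda = params$mu,
                                    lower.tail = FALSE),
    negative_binomial = stats::pnbinom(x - 1, size = params$size,
                                       mu = params$mu, lower.tail = FALSE))
}

#' Combine replicate p-values with Fisher's method
#'
#' stat = -2 * sum(log p); the combined p is the upper tail of a chi-square
#' with 2R degrees of freedom. Zero p-values are floored at \code{eps} (and
#' the flooring count reported) so the statistic stays finite.
#'
#' @param p Numeric vector of per-replicate p-values in (0, 1], or a matrix
#'   with one row per position and one column per replicate.
#' @param eps Floor applied to zero p-values; default 1e-300.
#' @return For a vector: list(\code{fisher_stat}, \code{combined_p},
#'   \code{n_floored}). For a matrix: data frame with those columns, one row
#'   per position.
#' @export
fisher_combine <- function(p, eps = 1e-300) {
  if (is.null(p) || !length(p)) stop("fisher_combine: empty p-value input")
  mat <- is.matrix(p)
  if (!mat) p <- matrix(p, nrow = 1L)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  n_floored <- rowSums(p < eps)
  p <- pmax(p, eps)
  stat <- -2 * rowSums(log(p))
  df <- 2L * ncol(p)
  combined <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  if (!mat) {
    list(fisher_stat = stat[1L], combined_p = combined[1L],
         n_floored = n_floored[1L])
  } else {
    data.frame(fisher_stat = stat, combined_p = combined,
               n_floored = n_floored)
  }
}

#' Call pause sites from replicate coverage
#'
#' For every CDS position of every gene: a per-replicate p-value from that
#' replicate's own trimmed fit (the fit excludes trimmed positions, but every
#' position is still assigned a p-value — a pause is by definition a top
#' outlier and must remain testable), Fisher combination across replicates,
#' and a call iff the combined p is strictly below \code{threshold}.
#'
#' Positions within \code{mask_start} codons of the start codon keep their
#' p-values but are never called: the start-codon initiation peak reflects
#' ribosome initiation, not an elongation pause.
#'
#' @param coverage A \code{coverage_set} (one condition, >= 1 replicate),
#'   already restricted to genes passing \code{\link{filter_genes}}.
#' @param threshold Strict combined-p calling threshold; default 1e-7.
#' @param trim_frac Fraction trimmed from each tail before fitting.
#' @param fit_method \code{"trimmed_mom"} (default: trimmed-moment matching,
#'   see \code{\link{fit_nb_trimmed}}), or plain \code{"mom"} / \code{"mle"}
#'   on the retained counts via \code{\link{fit_nb}}.
#' @param mask_start Codons at the CDS start excluded from calling;
#'   default 5.
#' @return Data frame sorted by transcript then position: \code{transcript},
#'   \code{position} (0-based, CDS frame), \code{codon}, one \code{p_<lib>}
#'   column per replicate, \code{fisher_stat}, \code{combined_p},
#'   \code{called}.
#' @export
call_pauses <- function(coverage, threshold = 1e-7, trim_frac = 0.05,
                        fit_method = c("trimmed_mom", "mom", "mle"),
                        mask_start = 5L) {
  fit_method <- match.arg(fit_method)
  stopifnot(inherits(coverage, "coverage_set"))
  libs <- coverage$libraries
  txs <- sort(names(coverage$counts))
  out <- lapply(txs, function(tx) {
    m <- coverage$counts[[tx]]
    L <- nrow(m)
    pmat <- vapply(libs, function(lib) {
      retained <- trim_outliers(m[, lib], trim_frac)
      n_rm <- length(attr(retained, "removed_idx")) / 2L
      fit <- if (fit_method == "trimmed_mom") {
        fit_nb_trimmed(retained, frac = n_rm / L)
      } else {
        fit_nb(retained, estimator = fit_method)
      }
      position_pvalue(m[, lib], fit)
    }, numeric(L))
    pmat <- matrix(pmat, nrow = L, dimnames = list(NULL, paste0("p_", libs)))
    fc <- fisher_combine(pmat)
    df <- data.frame(transcript = tx, position = seq_len(L) - 1L,
                     codon = (seq_len(L) - 1L) %/% 3L,
                     pmat, check.names = FALSE)
    df$fisher_stat <- fc$fisher_stat
    df$combined_p <- fc$combined_p
    df$called <- df$combined_p < threshold & df$codon >= mask_start
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  res
}

#' Write pause calls as TSV
#' @param pauses Output of \code{\link{call_pauses}}.
#' @param path Output path.
#' @param called_only Write only called sites; default TRUE.
#' @return Invisibly, the written data frame.
#' @export
write_pauses <- function(pauses, path, called_only = TRUE) {
  df <- if (called_only) pauses[pauses$called, , drop = FALSE] else pauses
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
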