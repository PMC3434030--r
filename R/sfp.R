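# Single-feature-polymorphism (SFP) screening.
#
# An SFP is a probe whose hybridization differs among genotypes because of
# sequence variation under the probe, not because of expression. The screen
# subtracts the probe-set expression estimate from each probe's normalized
# log2 value and tests the residuals for a strain effect with a multiclass
# SAM-type statistic whose significance is calibrated by permutation.

#' Probe-level residuals around the probe-set expression estimate
#'
#' \eqn{r_{ji} = } background-corrected, quantile-normalized log2 value of
#' probe \eqn{j} in sample \eqn{i} minus the probe-set expression estimate for
#' sample \eqn{i}. A constant probe affinity survives in the residual row but
#' cancels in any between-strain comparison; a genotype-dependent affinity
#' shift (an SFP) does not.
#'
#' @param probes_log2 probe x sample normalized log2 matrix (from
#'   [rma_preprocess()]).
#' @param expr probe-set x sample expression matrix from median polish on the
#'   same normalized data.
#' @param probe_map probe-to-probe-set mapping.
#' @return residual matrix, same shape as \code{probes_log2}.
#' @export
compute_probe_residuals <- function(probes_log2, expr, probe_map) {
  ps <- probe_map$probeset_id[match(rownames(probes_log2), probe_map$probe_id)]
  if (anyNA(ps)) sa_error("format", "probe rows missing from the probe map")
  missing <- setdiff(unique(ps), rownames(expr))
  if (length(missing) > 0L)
    sa_error("format", paste("probe set(s) missing from the expression matrix:",
                             paste(utils::head(missing, 5L), collapse = ", ")))
  if (!identical(colnames(probes_log2), colnames(expr)))
    sa_error("format", "probe matrix and expression matrix sample order differ")
  probes_log2 - expr[ps, , drop = FALSE]
}

sam_d_statistic <- function(x, cls, s0) {
  # x: probes x samples; cls: integer class labels 1..K
  K <- max(cls)
  n_k <- tabulate(cls, K)
  G <- matrix(0, length(cls), K)
  G[cbind(seq_along(cls), cls)] <- 1
  Gm <- sweep(G, 2L, n_k, `/`)
  M <- x %*% Gm                               # class means (P x K)
  xbar <- rowMeans(x)
  between <- sqrt(pmax(rowSums(sweep((M - xbar)^2, 2L, n_k, `*`)), 0))
  ssw <- pmax(rowSums(x^2) - as.vector(M^2 %*% n_k), 0)
  s <- sqrt(ssw / (length(cls) - K) * sum(1 / n_k))
  list(d = between / (s + s0), s = s)
}

#' Multiclass SAM statistic with permutation q-values
#'
#' Per probe, the F-like score
#' \deqn{d_j = \sqrt{\sum_k n_k (\bar x_{jk} - \bar x_j)^2} \; / \; (s_j + s_0)}
#' where \eqn{s_j} is the pooled within-strain standard error and \eqn{s_0} a
#' fudge constant guarding small denominators. Significance comes from random
#' permutations of the strain labels: the q-value of probe \eqn{j} is the
#' median over permutations of the count of permuted scores at or above
#' \eqn{d_j}, divided by the count of observed scores at or above \eqn{d_j},
#' clipped to [0, 1] and made monotone nonincreasing in \eqn{d}. Because the
#' calibration is permutation-based, any strictly monotone rescaling of the
#' score yields identical q-value rankings.
#'
#' @param residuals probe x sample residual matrix.
#' @param strain_labels per-sample class labels (>= 2 classes, >= 2 samples
#'   per class).
#' @param n_permutations number of label permutations (warned below 100).
#' @param seed integer seed for the permutations.
#' @param s0 \code{"auto"} (the 5th percentile of the \eqn{s_j} distribution),
#'   \code{"grid"} (coefficient-of-variation-minimizing grid search over
#'   percentiles of \eqn{s_j}), or a non-negative number.
#' @return data.frame with \code{probe_id}, \code{d}, \code{q}.
#' @export
sam_multiclass <- function(residuals, strain_labels, n_permutations = 1000L,
                           seed = 1L, s0 = "auto") {
  residuals <- as.matrix(residuals)
  cls <- as.integer(factor(strain_labels))
  if (max(cls) < 2L) sa_error("design", "need >= 2 strains")
  if (any(tabulate(cls) < 2L))
    sa_error("design", "need >= 2 samples per strain (design not invertible)")
  if (n_permutations < 100L)
    warning("fewer than 100 permutations: q-values will be coarse")
  # fudge constant from the unmoderated spread statistics
  raw <- sam_d_statistic(residuals, cls, 0)
  s0_val <- if (identical(s0, "auto")) {
    stats::quantile(raw$s, 0.05, names = FALSE)
  } else if (identical(s0, "grid")) {
    sam_s0_grid(raw, residuals, cls)
  } else {
    if (!is.numeric(s0) || s0 < 0) sa_error("config", "s0 must be >= 0")
    s0
  }
  d <- sam_d_statistic(residuals, cls, s0_val)$d
  P <- length(d)
  ord <- order(d, decreasing = TRUE)
  d_sorted <- d[ord]
  denom <- P - findInterval(d_sorted, sort(d), left.open = TRUE)  # #{d >= d_j}
  counts <- matrix(0L, P, n_permutations)
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perm <- sample(cls)
      db <- sort(sam_d_statistic(residuals, perm, s0_val)$d)
      counts[, b] <- P - findInterval(d_sorted, db, left.open = TRUE)
    }
  })
  med <- apply(counts, 1L, stats::median)
  q_sorted <- pmin(pmax(med / denom, 0), 1)
  # monotone nonincreasing in d: q at a larger d never exceeds q at a smaller d
  for (i in (P - 1L):1L) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1L])
  q <- numeric(P)
  q[ord] <- q_sorted
  data.frame(probe_id = rownames(residuals), d = d, q = q,
             stringsAsFactors = FALSE)
}

# Tusher-style grid search: pick the percentile of s that minimizes the
# coefficient of variation of mad(d) across windows of s.
sam_s0_grid <- function(raw, residuals, cls) {
  cand <- stats::quantile(raw$s, seq(0, 1, by = 0.05), names = FALSE)
  br <- stats::quantile(raw$s, seq(0, 1, by = 0.01), names = FALSE)
  bins <- cut(raw$s, unique(br), include.lowest = TRUE)
  cv <- vapply(cand, function(s0v) {
    d <- sam_d_statistic(residuals, cls, s0v)$d
    mads <- tapply(d, bins, stats::mad)
    mads <- mads[is.finite(mads) & mads > 0]
    if (length(mads) < 2L) return(Inf)
    stats::sd(mads) / mean(mads)
  }, 1.0)
  cand[which.min(cv)]
}

#' Flag probe sets containing significant SFP probes
#'
#' A probe set is flagged when at least \code{min_probes} (default 1) of its
#' member probes have permutation q-value below \code{alpha}; flagged probe
#' sets are removed from downstream differential expression.
#'
#' @param report per-probe data.frame from [sam_multiclass()].
#' @param probe_map probe-to-probe-set mapping.
#' @param alpha q-value threshold (default 0.01).
#' @param min_probes minimum number of significant probes to flag a probe set.
#' @return object of class \code{SFPReport}: list with \code{probes} (the
#'   per-probe report), \code{probesets} (data.frame: probeset_id, n_probes,
#'   n_significant, flagged) and \code{alpha}.
#' @export
flag_sfp_probesets <- function(report, probe_map, alpha = 0.01, min_probes = 1L) {
  ps <- probe_map$probeset_id[match(report$probe_id, probe_map$probe_id)]
  if (anyNA(ps)) sa_error("format", "report probes missing from the probe map")
  sig <- report$q < alpha
  tab <- data.frame(
    probeset_id = names(tapply(sig, ps, sum)),
    n_probes = as.integer(tapply(sig, ps, length)),
    n_significant = as.integer(tapply(sig, ps, sum)),
    stringsAsFactors = FALSE)
  tab$flagged <- tab$n_significant >= min_probes
  structure(list(probes = report, probesets = tab, alpha = alpha),
            class = "SFPReport")
}
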