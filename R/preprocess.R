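# RMA-style preprocessing: convolution background correction, quantile
# normalization, median-polish summarization; plus detection calls and the
# expression / interquartile-range filters.

max_density_point <- function(x, n_pts = 2^14) {
  d <- stats::density(x, kernel = "epanechnikov", n = n_pts, na.rm = TRUE)
  d$x[which.max(d$y)]
}

estimate_background_model <- function(x) {
  if (length(unique(x)) < 10L)
    sa_error("estimation", "degenerate sample: (near-)constant intensities")
  mode1 <- max_density_point(x)
  below <- x[x < mode1]
  if (length(below) < 10L)
    sa_error("estimation", "degenerate sample: no mass below the intensity mode")
  mu <- max_density_point(below)
  resid <- x[x < mu] - mu
  if (length(resid) < 2L)
    sa_error("estimation", "degenerate sample: no sub-mode spread to estimate sigma")
  # sub-mode residuals are the lower half of the background normal
  sigma <- sqrt(sum(resid^2) / (length(resid) - 1)) * sqrt(2)
  signal <- x[x > mu] - mu
  alpha <- 1 / max_density_point(signal)
  if (!is.finite(alpha) || alpha <= 0) alpha <- 1 / mean(signal)
  list(mu = mu, sigma = sigma, alpha = alpha)
}

#' Posterior mean signal under the exponential-normal convolution
#'
#' Closed form of \eqn{E[S \mid O = o]} when the observed intensity is
#' \eqn{O = S + B} with signal \eqn{S \sim Exp(\alpha)} and background
#' \eqn{B \sim N(\mu, \sigma^2)}:
#' \deqn{E[S|o] = a + b\,\frac{\phi(a/b) - \phi((o-a)/b)}{\Phi(a/b) + \Phi((o-a)/b) - 1}}
#' with \eqn{a = o - \mu - \sigma^2\alpha} and \eqn{b = \sigma}. The signal is
#' supported on \eqn{(0, o)}, i.e. the background draw is taken non-negative.
#'
#' @param o observed intensities (vector).
#' @param mu,sigma,alpha background mean/SD and exponential signal rate.
#' @return vector of posterior mean signals (strictly positive).
#' @export
bg_posterior_mean <- function(o, mu, sigma, alpha) {
  a <- o - mu - sigma^2 * alpha
  b <- sigma
  num <- stats::dnorm(a / b) - stats::dnorm((o - a) / b)
  den <- stats::pnorm(a / b) + stats::pnorm((o - a) / b) - 1
  out <- a + b * num / den
  # guard against denominator underflow far in the tails
  bad <- !is.finite(out) | den <= 0
  out[bad] <- pmax(a[bad], .Machine$double.eps)
  pmax(out, .Machine$double.xmin)
}

#' Background-correct a probe intensity matrix
#'
#' Per sample, estimates the exponential-signal / normal-background
#' convolution parameters from the intensity density (background mean at the
#' density mode, SD from the sub-mode spread, exponential rate from the
#' supra-mode mass) and replaces each intensity by the posterior mean signal
#' [bg_posterior_mean()]. The transform is strictly positive and monotone
#' increasing in the raw intensity within each sample.
#'
#' @param pm probe x sample matrix of strictly positive intensities.
#' @return list with \code{corrected} (same shape) and \code{models}
#'   (per-sample list of \code{mu}, \code{sigma}, \code{alpha}).
#' @export
background_correct <- function(pm) {
  pm <- as.matrix(pm)
  if (any(pm <= 0)) sa_error("value", "intensities must be strictly positive")
  models <- vector("list", ncol(pm))
  names(models) <- colnames(pm)
  corrected <- pm
  for (i in seq_len(ncol(pm))) {
    models[[i]] <- estimate_background_model(pm[, i])
    corrected[, i] <- bg_posterior_mean(pm[, i], models[[i]]$mu,
                                        models[[i]]$sigma, models[[i]]$alpha)
  }
  list(corrected = corrected, models = models)
}

#' Quantile normalization
#'
#' Forces every column onto the common distribution whose r-th order statistic
#' is the mean across columns of each column's r-th order statistic. Ties
#' within a column receive the mean of the reference values at their would-be
#' ranks (average-rank convention).
#'
#' @param x numeric matrix (probes x samples), no missing values.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) sa_error("value", "missing values are not allowed")
  if (ncol(x) == 1L) return(x)
  ref <- rowMeans(apply(x, 2L, sort, method = "radix"))
  out <- x
  for (i in seq_len(ncol(x))) {
    r <- rank(x[, i], ties.method = "average")
    out[, i] <- (ref[floor(r)] + ref[ceiling(r)]) / 2
  }
  out
}

median_polish_fit <- function(z, tol = 0.01, maxiter = 10L) {
  overall <- 0
  row_eff <- numeric(nrow(z))
  col_eff <- numeric(ncol(z))
  resid <- z
  oldsum <- Inf
  for (iter in seq_len(maxiter)) {
    rdelta <- apply(resid, 1L, stats::median)       # probe (row) sweep first
    resid <- resid - rdelta
    row_eff <- row_eff + rdelta
    delta <- stats::median(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta
    cdelta <- apply(resid, 2L, stats::median)
    resid <- sweep(resid, 2L, cdelta)
    col_eff <- col_eff + cdelta
    delta <- stats::median(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta
    newsum <- sum(abs(resid))
    if (newsum == 0 || abs(oldsum - newsum) < tol) break
    oldsum <- newsum
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = resid)
}

#' Median-polish summarization of log2 probe intensities
#'
#' Per probe set, fits the additive model
#' \code{log2 intensity = overall + probe effect + sample effect} by
#' alternating median sweeps (probe sweep before sample sweep; convergence when
#' the total absolute residual changes by less than \code{tol}, at most
#' \code{maxiter} iterations). The probe-set expression of a sample is
#' \code{overall + sample effect}.
#'
#' @param log2_probes probe x sample matrix on the log2 scale, finite, with
#'   probe row names of the form \code{probeset:index}.
#' @param probe_map data.frame mapping \code{probe_id} to \code{probeset_id}
#'   (as in a \code{ProbeLevelDataset}).
#' @param tol,maxiter median-polish convergence controls.
#' @return probe-set x sample matrix of log2 expression (an ExpressionMatrix).
#' @export
median_polish_summarize <- function(log2_probes, probe_map, tol = 0.01,
                                    maxiter = 10L) {
  log2_probes <- as.matrix(log2_probes)
  if (any(!is.finite(log2_probes)))
    sa_error("value", "log2 probe matrix must be finite")
  idx <- match(rownames(log2_probes), probe_map$probe_id)
  if (anyNA(idx))
    sa_error("format", "probe rows missing from the probe map")
  groups <- split(seq_len(nrow(log2_probes)), probe_map$probeset_id[idx])
  expr <- matrix(NA_real_, length(groups), ncol(log2_probes),
                 dimnames = list(names(groups), colnames(log2_probes)))
  for (g in seq_along(groups)) {
    fit <- median_polish_fit(log2_probes[groups[[g]], , drop = FALSE],
                             tol = tol, maxiter = maxiter)
    expr[g, ] <- fit$overall + fit$col
  }
  expr
}

# Exact/approximate one-sided signed-rank p-value for H0: median(x) = tau
# against median(x) > tau. Exact null for n <= exact_max (enumeration when the
# absolute deviations are tied, the closed signrank distribution otherwise);
# normal approximation with continuity and tie correction beyond that.
signed_rank_p <- function(x, tau, exact_max = 12L) {
  d <- x - tau
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(0.5)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  has_ties <- anyDuplicated(r) > 0L
  if (n <= exact_max) {
    if (!has_ties)
      return(stats::psignrank(W - 1L, n, lower.tail = FALSE))
    total <- 0L
    for (mask in 0:(2^n - 1L)) {
      w <- sum(r[bitwAnd(bitwShiftL(1L, 0:(n - 1L)), mask) != 0L])
      if (w >= W) total <- total + 1L
    }
    return(total / 2^n)
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  stats::pnorm((W - mu - 0.5) / sqrt(v), lower.tail = FALSE)
}

#' Present/Marginal/Absent detection calls
#'
#' Per probe set and sample, computes the discrimination scores
#' \eqn{R_j = (PM_j - MM_j)/(PM_j + MM_j)} over the probe pairs and tests
#' \eqn{H_0:\ median(R) = \tau} against \eqn{>\tau} with a one-sided Wilcoxon
#' signed-rank test (exact null for 12 or fewer informative probes, normal
#' approximation with continuity correction beyond). Calls are Present when
#' \code{p < p_present}, Absent when \code{p > p_absent}, Marginal otherwise;
#' downstream filtering treats Marginal as Absent.
#'
#' @param dataset a \code{ProbeLevelDataset} (raw, unnormalized intensities).
#' @param tau discrimination-score offset under the null.
#' @param p_present,p_absent call thresholds.
#' @return object of class \code{DetectionCalls}: list with \code{call}
#'   (probe-set x sample character matrix over P/M/A) and \code{pvalue}.
#' @export
detection_calls <- function(dataset, tau = 0.015, p_present = 0.04,
                            p_absent = 0.04) {
  stopifnot(inherits(dataset, "ProbeLevelDataset"))
  R <- (dataset$pm - dataset$mm) / (dataset$pm + dataset$mm)
  groups <- split(seq_len(nrow(R)), dataset$probe_map$probeset_id)
  pv <- matrix(NA_real_, length(groups), ncol(R),
               dimnames = list(names(groups), colnames(R)))
  for (g in seq_along(groups)) {
    block <- R[groups[[g]], , drop = FALSE]
    for (i in seq_len(ncol(block)))
      pv[g, i] <- signed_rank_p(block[, i], tau)
  }
  call <- matrix("M", nrow(pv), ncol(pv), dimnames = dimnames(pv))
  call[pv < p_present] <- "P"
  call[pv > p_absent] <- "A"
  structure(list(call = call, pvalue = pv, tau = tau,
                 p_present = p_present, p_absent = p_absent),
            class = "DetectionCalls")
}

#' Expression-level filter from absent-call signal
#'
#' Defines "unexpressed" operationally: the threshold \code{T} is the
#' \code{percentile} quantile (linear-interpolation convention) of the
#' expression values of probe sets called Absent-or-Marginal in every sample,
#' pooled over samples; probe sets whose maximum expression across samples
#' falls below \code{T} are removed.
#'
#' @param expr probe-set x sample log2 expression matrix.
#' @param calls a [detection_calls()] result on the same probe sets/samples.
#' @param percentile quantile of the absent pool (default 0.99).
#' @param pooling \code{"pooled"} (default) pools absent expression values
#'   over samples into one threshold; \code{"per_sample"} computes one
#'   threshold per sample and removes probe sets below threshold in every
#'   sample.
#' @param threshold optional precomputed threshold. The threshold is a
#'   property of the full expression matrix: re-estimating it on an already
#'   filtered matrix would shift the quantile of the surviving absent pool
#'   upward. The filtered matrix therefore carries its threshold as an
#'   attribute, which a second application reuses, making the filter
#'   idempotent.
#' @return list with \code{expr} (filtered matrix), \code{threshold}, and
#'   \code{removed} (character vector of probe-set ids).
#' @export
expression_threshold_filter <- function(expr, calls, percentile = 0.99,
                                        pooling = c("pooled", "per_sample"),
                                        threshold = NULL) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(calls, "DetectionCalls"))
  if (is.null(threshold))
    threshold <- attr(expr, "expression_threshold")
  common <- intersect(rownames(expr), rownames(calls$call))
  if (length(common) != nrow(expr))
    sa_error("format", "expression matrix and calls cover different probe sets")
  cl <- calls$call[rownames(expr), colnames(expr), drop = FALSE]
  all_absent <- rowSums(cl == "P") == 0L
  if (is.null(threshold)) {
    if (!any(all_absent)) {
      warning("no probe set is absent in all samples; expression filter is vacuous")
      return(list(expr = expr, threshold = -Inf, removed = character(0)))
    }
    threshold <- if (pooling == "pooled")
      stats::quantile(expr[all_absent, , drop = FALSE], percentile,
                      names = FALSE, type = 7)
    else
      apply(expr[all_absent, , drop = FALSE], 2L, stats::quantile,
            probs = percentile, names = FALSE, type = 7)
  }
  keep <- if (length(threshold) == 1L)
    apply(expr, 1L, max) >= threshold
  else
    rowSums(sweep(expr, 2L, threshold, `>=`)) > 0L
  out <- expr[keep, , drop = FALSE]
  attr(out, "expression_threshold") <- threshold
  list(expr = out, threshold = threshold,
       removed = rownames(expr)[!keep])
}

#' Interquartile-range variability filter
#'
#' Removes probe sets whose IQR of log2 expression across all samples is
#' strictly less than \code{min_iqr}. Quartiles use the linear-interpolation
#' convention by default (\code{type = 7}); the convention is configurable
#' because it changes counts at the boundary.
#'
#' @param expr probe-set x sample log2 expression matrix (>= 4 samples).
#' @param min_iqr retention threshold (default 0.5).
#' @param type quantile type passed to [stats::quantile()].
#' @return list with \code{expr} (filtered) and \code{removed} ids.
#' @export
iqr_filter <- function(expr, min_iqr = 0.5, type = 7) {
  if (ncol(expr) < 4L) sa_error("format", "IQR filter needs >= 4 samples")
  iqr <- apply(expr, 1L, function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = type)
    q[2L] - q[1L]
  })
  keep <- iqr >= min_iqr
  list(expr = expr[keep, , drop = FALSE], removed = rownames(expr)[!keep],
       iqr = iqr)
}

#' Full RMA-style preprocessing of a probe-level dataset
#'
#' Background-corrects the PM matrix ([background_correct()]), quantile
#' normalizes across samples on the linear scale ([quantile_normalize()]),
#' takes log2, and summarizes each probe set by median polish
#' ([median_polish_summarize()]).
#'
#' @param dataset a \code{ProbeLevelDataset}.
#' @return list with \code{expr} (probe-set x sample log2 expression),
#'   \code{probes_log2} (background-corrected, normalized log2 probe matrix,
#'   the input to SFP residual analysis) and \code{background_models}.
#' @export
rma_preprocess <- function(dataset) {
  stopifnot(inherits(dataset, "ProbeLevelDataset"))
  bg <- background_correct(dataset$pm)
  normed <- quantile_normalize(bg$corrected)
  probes_log2 <- log2(normed)
  expr <- median_polish_summarize(probes_log2, dataset$probe_map)
  list(expr = expr, probes_log2 = probes_log2,
       background_models = bg$models)
}
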