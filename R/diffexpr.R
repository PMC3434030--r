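# Gene-wise linear models with empirical-Bayes variance moderation,
# contrasts for strain / domestication / sex, BH adjustment, fold changes and
# the range-overlap filter for domestication candidates.

#' Build a design matrix for the strain (means) model
#'
#' Cell-means parameterization with one column per strain; the model used for
#' the among-strain F test and the wild-vs-domesticated contrast.
#'
#' @param samples validated sample metadata.
#' @return design matrix (samples x strains) with attribute \code{"strains"}.
#' @export
strain_design <- function(samples) {
  samples <- validate_samples(samples)
  strains <- sort(unique(samples$strain))
  X <- stats::model.matrix(~ 0 + factor(samples$strain, levels = strains))
  dimnames(X) <- list(samples$sample_id, strains)
  attr(X, "strains") <- strains
  attr(X, "domestication") <-
    samples$domestication[match(strains, samples$strain)]
  X
}

#' Build a design matrix for the fully crossed strain x sex model
#'
#' Cell-means parameterization with one column per strain:sex cell; the model
#' used for the sex contrast.
#'
#' @param samples validated sample metadata.
#' @return design matrix with attributes \code{"strains"}, \code{"cells"}.
#' @export
factorial_design <- function(samples) {
  samples <- validate_samples(samples)
  strains <- sort(unique(samples$strain))
  cell <- interaction(factor(samples$strain, levels = strains),
                      factor(samples$sex, levels = c("F", "M")),
                      sep = ":", drop = FALSE)
  X <- stats::model.matrix(~ 0 + cell)
  dimnames(X) <- list(samples$sample_id, levels(cell))
  attr(X, "strains") <- strains
  attr(X, "cells") <- levels(cell)
  X
}

#' Gene-wise ordinary least squares
#'
#' Fits the same linear model to every probe set (row) of the expression
#' matrix: coefficient estimates, residual variance with its degrees of
#' freedom, and the unscaled covariance of the coefficients from the design's
#' normal equations.
#'
#' @param expr probe-set x sample log2 expression matrix.
#' @param design full-column-rank design matrix (samples x coefficients).
#' @return object of class \code{GeneFits}: list with \code{coefficients}
#'   (genes x coefficients), \code{sigma2}, \code{df_resid},
#'   \code{cov_unscaled} and the \code{design}.
#' @export
fit_gene_linear_models <- function(expr, design) {
  expr <- as.matrix(expr)
  design <- as.matrix(design)
  if (nrow(design) != ncol(expr))
    sa_error("design", "design rows must match expression columns")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    aliased <- colnames(design)[qrX$pivot[(qrX$rank + 1L):ncol(design)]]
    sa_error("design", paste("design matrix is rank deficient; aliased column(s):",
                             paste(aliased, collapse = ", ")))
  }
  df_resid <- nrow(design) - ncol(design)
  if (df_resid <= 0)
    sa_error("design", "no residual degrees of freedom")
  xtx_inv <- chol2inv(qr.R(qrX))
  dimnames(xtx_inv) <- list(colnames(design), colnames(design))
  beta <- t(qr.coef(qrX, t(expr)))
  fitted <- beta %*% t(design)
  rss <- rowSums((expr - fitted)^2)
  structure(list(coefficients = beta,
                 sigma2 = rss / df_resid,
                 df_resid = df_resid,
                 cov_unscaled = xtx_inv,
                 design = design),
            class = "GeneFits")
}

# Newton solve of trigamma(x) = y (y > 0), vectorized.
trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-6; out[lo] <- 1 / y[lo]
  hi <- y > 1e7;  out[hi] <- 1 / sqrt(y[hi])
  mid <- !lo & !hi
  x <- 0.5 + 1 / y[mid]
  for (i in seq_len(50L)) {
    tg <- trigamma(x)
    delta <- tg * (1 - tg / y[mid]) / psigamma(x, 2L)
    x <- x + delta
    if (max(abs(delta / x)) < 1e-10) break
  }
  out[mid] <- x
  out
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Shrinks each gene's residual variance toward a prior estimated across
#' genes. The prior \eqn{(d_0, s_0^2)} is obtained by matching the first two
#' moments of \eqn{\log s^2} to a scaled F (log chi-square) distribution via
#' digamma/trigamma identities; the posterior variance is
#' \deqn{\tilde s^2_g = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}}
#' and moderated t/F statistics gain \eqn{d_0} degrees of freedom. When the
#' observed log-variances are less dispersed than a chi-square with
#' \eqn{d_g} df allows (e.g. all \eqn{s^2} identical), \eqn{d_0 = \infty} and
#' every posterior variance equals \eqn{s_0^2}.
#'
#' @param fits a [fit_gene_linear_models()] object (>= 10 genes with positive
#'   residual df recommended for a stable prior).
#' @param d0 optional override of the prior degrees of freedom: \code{0}
#'   disables moderation (ordinary t), \code{Inf} pools to a single variance.
#' @return object of class \code{ModeratedFit}: the fit plus \code{d0},
#'   \code{s02} and \code{sigma2_post}.
#' @export
moderate_variances <- function(fits, d0 = NULL) {
  stopifnot(inherits(fits, "GeneFits"))
  s2 <- fits$sigma2
  dg <- fits$df_resid
  usable <- s2 > 0
  if (sum(usable) < 2L) {
    est_d0 <- Inf
    s02 <- if (any(usable)) mean(s2[usable]) else mean(s2)
  } else {
    z <- log(s2[usable])
    e <- z - digamma(dg / 2) + log(dg / 2)
    ebar <- mean(e)
    ve <- stats::var(e)
    excess <- ve - trigamma(dg / 2)
    if (is.na(excess) || excess <= 0) {
      est_d0 <- Inf
      s02 <- mean(s2[usable])   # pooled variance, the MLE when d0 is infinite
    } else {
      est_d0 <- 2 * trigamma_inverse(excess)
      s02 <- exp(ebar + digamma(est_d0 / 2) - log(est_d0 / 2))
    }
  }
  if (!is.null(d0)) {
    if (d0 < 0) sa_error("config", "d0 must be >= 0 or Inf")
    est_d0 <- d0
    if (!is.finite(d0) && !exists("s02")) s02 <- mean(s2)
  }
  post <- if (is.infinite(est_d0)) rep(s02, length(s2))
          else (est_d0 * s02 + dg * s2) / (est_d0 + dg)
  out <- fits
  out$d0 <- est_d0
  out$s02 <- s02
  out$sigma2_post <- post
  class(out) <- c("ModeratedFit", "GeneFits")
  out
}

moderated_t <- function(mfit, cvec) {
  est <- as.vector(mfit$coefficients %*% cvec)
  u <- sqrt(as.vector(t(cvec) %*% mfit$cov_unscaled %*% cvec))
  df <- mfit$d0 + mfit$df_resid
  se <- u * sqrt(unname(mfit$sigma2_post))
  # zero posterior variance: noiseless data, the contrast is exact
  tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(estimate = est, statistic = tstat, df = df, p = p)
}

moderated_F <- function(mfit, C) {
  C <- as.matrix(C)
  r <- qr(C)$rank
  V <- t(C) %*% mfit$cov_unscaled %*% C
  Vinv <- solve(V)
  B <- mfit$coefficients %*% C
  quad <- unname(rowSums((B %*% Vinv) * B))
  Fstat <- quad / (r * unname(mfit$sigma2_post))
  df2 <- mfit$d0 + mfit$df_resid
  p <- stats::pf(Fstat, r, df2, lower.tail = FALSE)
  p[!is.finite(Fstat)] <- 0
  zero <- quad == 0
  Fstat[zero] <- 0; p[zero] <- 1
  list(statistic = Fstat, df1 = r, df2 = df2, p = p)
}

#' Moderated contrasts for strain, domestication and sex
#'
#' \describe{
#'   \item{among_strain}{moderated F on the strain-difference coefficients of
#'     the strain (means) model.}
#'   \item{wild_vs_domesticated}{moderated t on
#'     \eqn{\tfrac12(\mu_{SH}+\mu_{TM1}) - \tfrac12(\mu_{Nadia}+\mu_{Gaighatta})}
#'     (generally: mean of domesticated minus mean of wild strain means);
#'     positive estimates mean higher expression in domesticated strains.}
#'   \item{sex}{moderated t on the male-minus-female cell-mean contrast of the
#'     fully crossed strain x sex model.}
#' }
#'
#' @param mfit a [moderate_variances()] fit on [strain_design()] (for the
#'   strain/domestication contrasts) or [factorial_design()] (for sex).
#' @param contrast one of \code{"among_strain"}, \code{"wild_vs_domesticated"},
#'   \code{"sex"}.
#' @return A \code{DEResult} data.frame: probeset_id, estimate (log2; NA for
#'   the F test), statistic, p, adj_p, fold_change, direction.
#' @export
test_contrasts <- function(mfit, contrast = c("among_strain",
                                              "wild_vs_domesticated", "sex")) {
  contrast <- match.arg(contrast)
  design <- mfit$design
  genes <- rownames(mfit$coefficients)
  if (contrast == "among_strain") {
    strains <- attr(design, "strains")
    if (is.null(strains) || !all(strains %in% colnames(design)))
      sa_error("design", "among_strain requires a strain means design")
    K <- length(strains)
    C <- matrix(0, K, K - 1L, dimnames = list(strains, NULL))
    for (k in 2:K) { C[1L, k - 1L] <- -1; C[k, k - 1L] <- 1 }
    ft <- moderated_F(mfit, C)
    res <- data.frame(probeset_id = genes, estimate = NA_real_,
                      statistic = ft$statistic, p = ft$p,
                      stringsAsFactors = FALSE)
  } else if (contrast == "wild_vs_domesticated") {
    strains <- attr(design, "strains")
    dom <- attr(design, "domestication")
    if (is.null(dom))
      sa_error("design", "wild_vs_domesticated requires strain domestication metadata")
    if (!any(dom == "wild") || !any(dom == "domesticated"))
      sa_error("design", "both wild and domesticated strains required")
    cvec <- ifelse(dom == "domesticated", 1 / sum(dom == "domesticated"),
                   -1 / sum(dom == "wild"))
    tt <- moderated_t(mfit, cvec)
    res <- data.frame(probeset_id = genes, estimate = tt$estimate,
                      statistic = tt$statistic, p = tt$p,
                      stringsAsFactors = FALSE)
  } else {
    cells <- attr(design, "cells")
    if (is.null(cells))
      sa_error("design", "sex contrast requires the factorial (strain x sex) design")
    is_m <- grepl(":M$", cells)
    cvec <- ifelse(is_m, 1 / sum(is_m), -1 / sum(!is_m))
    tt <- moderated_t(mfit, cvec)
    res <- data.frame(probeset_id = genes, estimate = tt$estimate,
                      statistic = tt$statistic, p = tt$p,
                      stringsAsFactors = FALSE)
  }
  res$adj_p <- bh_adjust(res$p)
  if (!all(is.na(res$estimate))) {
    res$fold_change <- 2^abs(res$estimate)
    res$direction <- ifelse(res$estimate >= 0, "up", "down")
  } else {
    res$fold_change <- NA_real_
    res$direction <- NA_character_
  }
  attr(res, "contrast") <- contrast
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values: with ordered p-values \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, \eqn{\tilde p_{(i)} = \min_{j \ge i} (m\,p_{(j)}/j)} capped at 1,
#' mapped back to the input order. Thin wrapper over
#' \code{stats::p.adjust(method = "BH")} with input validation.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    sa_error("value", "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Fold changes between sample groups
#'
#' For two groups: \eqn{FC = 2^{|\bar x_A - \bar x_B|}} with the direction of
#' the signed difference. For more than two groups (e.g. the four strains),
#' the reported fold change is the maximum over all pairwise comparisons of
#' group mean expression, so the "2-fold or greater" rule for an among-strain
#' list means at least one strain pair differs 2-fold.
#'
#' @param expr probe-set x sample log2 expression matrix.
#' @param groups factor/character vector of length \code{ncol(expr)}
#'   partitioning the samples.
#' @return data.frame: probeset_id, log2_diff (signed, A minus B for two
#'   groups; the maximal absolute pairwise difference otherwise),
#'   fold_change (>= 1), direction, and for > 2 groups the pair attaining the
#'   maximum.
#' @export
fold_changes <- function(expr, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0L) || nlevels(groups) < 2L)
    sa_error("design", "groups must be non-empty and at least two")
  gm <- vapply(levels(groups), function(g)
    rowMeans(expr[, groups == g, drop = FALSE]), numeric(nrow(expr)))
  gm <- matrix(gm, nrow = nrow(expr),
               dimnames = list(rownames(expr), levels(groups)))
  if (nlevels(groups) == 2L) {
    diff <- gm[, 1L] - gm[, 2L]
    return(data.frame(probeset_id = rownames(expr), log2_diff = diff,
                      fold_change = 2^abs(diff),
                      direction = ifelse(diff >= 0, "up", "down"),
                      stringsAsFactors = FALSE))
  }
  pairs <- utils::combn(levels(groups), 2L)
  diffs <- vapply(seq_len(ncol(pairs)), function(k)
    gm[, pairs[1L, k]] - gm[, pairs[2L, k]], numeric(nrow(expr)))
  diffs <- matrix(diffs, nrow = nrow(expr))
  best <- max.col(abs(diffs), ties.method = "first")
  diff <- diffs[cbind(seq_len(nrow(diffs)), best)]
  data.frame(probeset_id = rownames(expr), log2_diff = diff,
             fold_change = 2^abs(diff),
             direction = ifelse(diff >= 0, "up", "down"),
             pair = paste(pairs[1L, best], pairs[2L, best], sep = "-"),
             stringsAsFactors = FALSE)
}

#' Range-overlap filter for domestication candidates
#'
#' Retains a candidate gene only if the expression ranges of the wild and
#' domesticated samples overlap by no more than \code{max_overlap} samples.
#' The overlap count is the number of wild samples lying inside the
#' [min, max] range of the domesticated samples plus the number of
#' domesticated samples inside the wild range; values equal to a group
#' extreme count as inside.
#'
#' @param expr probe-set x sample log2 expression matrix.
#' @param wild_samples,domesticated_samples column ids of the two groups.
#' @param candidates probe-set ids to filter (must be rows of \code{expr}).
#' @param max_overlap maximum tolerated overlap count (default 1).
#' @return data.frame: probeset_id, overlap, retained.
#' @export
range_overlap_filter <- function(expr, wild_samples, domesticated_samples,
                                 candidates = rownames(expr), max_overlap = 1L) {
  if (!all(candidates %in% rownames(expr)))
    sa_error("format", "candidates must be rows of the expression matrix")
  if (length(wild_samples) == 0L || length(domesticated_samples) == 0L)
    sa_error("design", "both groups must be non-empty")
  w <- expr[candidates, wild_samples, drop = FALSE]
  d <- expr[candidates, domesticated_samples, drop = FALSE]
  w_min <- apply(w, 1L, min); w_max <- apply(w, 1L, max)
  d_min <- apply(d, 1L, min); d_max <- apply(d, 1L, max)
  overlap <- rowSums(w >= d_min & w <= d_max) +
             rowSums(d >= w_min & d <= w_max)
  data.frame(probeset_id = candidates, overlap = as.integer(overlap),
             retained = overlap <= max_overlap, stringsAsFactors = FALSE)
}
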