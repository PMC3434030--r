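# Behavior scoring, fixed-effects ANOVA with partial (Type-III-style) sums of
# squares, qRT-PCR ANCOVA with a reference-gene covariate, and Tukey
# studentized-range pairwise comparisons with compact letter display.

#' Score raw behavior observations into per-fish phenotypes
#'
#' Vertical Depth is the mean over observation periods of the mean vertical
#' zone within each period (1 = surface, 6 = bottom). Horizontal Position is
#' the proportion of all recordings with the front flag set. Incomplete
#' periods contribute their available recordings; fish with no recordings are
#' excluded with a warning.
#'
#' @param observations data.frame with columns \code{fish_id}, \code{strain},
#'   \code{sex}, \code{period}, \code{recording}, \code{vertical_zone},
#'   \code{front_flag} and optionally \code{domestication}.
#' @return data.frame of class \code{BehaviorScores}: fish_id, strain,
#'   (domestication,) sex, vertical_depth, horizontal_position, n_periods,
#'   n_recordings.
#' @export
score_behavior <- function(observations) {
  required <- c("fish_id", "strain", "sex", "period", "recording",
                "vertical_zone", "front_flag")
  missing <- setdiff(required, names(observations))
  if (length(missing) > 0L)
    sa_error("format", paste("observations missing column(s):",
                             paste(missing, collapse = ", ")))
  if (any(!observations$vertical_zone %in% 1:6))
    sa_error("value", "vertical_zone must be an integer in 1..6")
  if (any(!observations$front_flag %in% c(0L, 1L)))
    sa_error("value", "front_flag must be 0/1")
  fish_ids <- unique(observations$fish_id)
  per_fish <- lapply(fish_ids, function(f) {
    ob <- observations[observations$fish_id == f, , drop = FALSE]
    if (nrow(ob) == 0L) return(NULL)
    period_means <- tapply(ob$vertical_zone, ob$period, mean)
    meta <- ob[1L, intersect(c("strain", "domestication", "sex"), names(ob)),
               drop = FALSE]
    cbind(data.frame(fish_id = f, stringsAsFactors = FALSE), meta,
          data.frame(vertical_depth = mean(period_means),
                     horizontal_position = mean(ob$front_flag),
                     n_periods = length(period_means),
                     n_recordings = nrow(ob)))
  })
  scores <- do.call(rbind, per_fish)
  rownames(scores) <- NULL
  dropped <- setdiff(fish_ids, scores$fish_id)
  if (length(dropped) > 0L)
    warning(paste("fish with no recordings excluded:",
                  paste(dropped, collapse = ", ")))
  class(scores) <- c("BehaviorScores", "data.frame")
  scores
}

# Partial-SS engine shared by the behavior ANOVA and the qPCR ANCOVA.
# Character predictors become factors with sum-to-zero contrasts, so dropping
# all columns of a term from the full model yields Type-III-style SS.
partial_ss_fit <- function(formula, data, ss_type = c("III", "I")) {
  ss_type <- match.arg(ss_type)
  data <- as.data.frame(data)
  vars <- all.vars(formula)[-1L]
  for (v in vars)
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
  factors <- vars[vapply(vars, function(v) is.factor(data[[v]]), TRUE)]
  for (v in factors) {
    if (nlevels(droplevels(data[[v]])) < 2L)
      sa_error("design", paste("factor with a single observed level:", v))
  }
  contr <- stats::setNames(replicate(length(factors), "contr.sum",
                                     simplify = FALSE), factors)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf,
                           contrasts.arg = if (length(contr)) contr else NULL)
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(formula), "term.labels")
  n <- nrow(X)
  qr_full <- qr(X)
  if (qr_full$rank < ncol(X)) {
    # aliased columns are dropped (as lm() does through pivoting); a term is
    # inestimable only when every one of its columns is aliased
    retained <- sort(qr_full$pivot[seq_len(qr_full$rank)])
    lost_terms <- setdiff(unique(asgn[asgn > 0L]), unique(asgn[retained]))
    if (length(lost_terms) > 0L)
      sa_error("design", paste("inestimable (confounded) term(s):",
                               paste(labels[lost_terms], collapse = ", ")))
    X <- X[, retained, drop = FALSE]
    asgn <- asgn[retained]
  }
  if (n <= ncol(X))
    sa_error("design", "no residual degrees of freedom")
  fit <- stats::lm.fit(X, y)
  rss_full <- sum(fit$residuals^2)
  df_resid <- n - ncol(X)
  rows <- lapply(seq_along(labels), function(t) {
    if (ss_type == "III") {
      Xr <- X[, asgn != t, drop = FALSE]
      ss <- sum(stats::lm.fit(Xr, y)$residuals^2) - rss_full
    } else {
      Xb <- X[, asgn < t, drop = FALSE]
      Xa <- X[, asgn <= t, drop = FALSE]
      ss <- sum(stats::lm.fit(Xb, y)$residuals^2) -
            sum(stats::lm.fit(Xa, y)$residuals^2)
    }
    df <- sum(asgn == t)
    data.frame(term = labels[t], df = df, sum_sq = max(ss, 0),
               mean_sq = max(ss, 0) / df, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  mse <- rss_full / df_resid
  tab$statistic <- tab$mean_sq / mse
  tab$p <- stats::pf(tab$statistic, tab$df, df_resid, lower.tail = FALSE)
  if (mse == 0) {   # noiseless fit: any explained SS is infinitely significant
    tab$statistic <- ifelse(tab$sum_sq > 0, Inf, 0)
    tab$p <- ifelse(tab$sum_sq > 0, 0, 1)
  }
  tab <- rbind(tab, data.frame(term = "Residuals", df = df_resid,
                               sum_sq = rss_full, mean_sq = mse,
                               statistic = NA_real_, p = NA_real_))
  r <- fit$residuals
  m2 <- mean(r^2)
  diagnostics <- list(
    skewness = if (m2 > 0) mean(r^3) / m2^1.5 else 0,
    kurtosis_excess = if (m2 > 0) mean(r^4) / m2^2 - 3 else 0,
    shapiro_p = if (n >= 3 && n <= 5000 && m2 > 0)
      tryCatch(stats::shapiro.test(r)$p.value, error = function(e) NA_real_)
      else NA_real_)
  structure(list(table = tab, mse = mse, df_resid = df_resid,
                 coefficients = fit$coefficients, X = X, y = y,
                 residuals = r, diagnostics = diagnostics,
                 formula = formula, data = data, contrasts = contr),
            class = "AnovaTable")
}

#' @export
print.AnovaTable <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Fixed-effects ANOVA on behavior scores
#'
#' Least-squares fit of a fixed-effects model with partial (Type-III-style)
#' sums of squares per term (sequential Type-I available); F against the
#' residual mean square. Residual skewness, excess kurtosis and a
#' Shapiro-Wilk statistic are reported as a normality check but never gate
#' the analysis. The canonical models are the nested design
#' \code{~ sex + domestication + domestication:strain} and the one-way
#' \code{~ strain}.
#'
#' @param scores a [score_behavior()] data.frame (or any data.frame).
#' @param formula model formula, e.g.
#'   \code{vertical_depth ~ sex + domestication + domestication:strain}.
#' @param ss_type \code{"III"} (default, partial) or \code{"I"} (sequential).
#' @return An \code{AnovaTable}: per-term df, SS, MS, F, p plus the residual
#'   row; diagnostics in \code{$diagnostics}.
#' @export
fixed_effects_anova <- function(scores, formula, ss_type = c("III", "I")) {
  partial_ss_fit(formula, scores, ss_type = match.arg(ss_type))
}

#' qRT-PCR ANCOVA with a reference-gene covariate
#'
#' Fits \code{ct_target ~ ct_reference + strain * sex} by least squares:
#' expression of the target gene is analyzed while normalizing for input
#' amount through the reference-gene C_T covariate. Reports partial F tests
#' per term and covariate-adjusted strain means evaluated at the mean
#' reference C_T (averaged over sexes). If the reference C_T is constant the
#' covariate is dropped with a warning and the model reduces to a two-way
#' ANOVA on the target C_T.
#'
#' @param qpcr data.frame with columns \code{sample_id}, \code{strain},
#'   \code{sex}, \code{ct_target}, \code{ct_reference}.
#' @param ss_type partial (\code{"III"}, default) or sequential (\code{"I"}).
#' @return list with \code{anova} (an \code{AnovaTable}),
#'   \code{adjusted_means} (named numeric, one per strain) and
#'   \code{covariate_dropped}.
#' @export
qpcr_ancova <- function(qpcr, ss_type = c("III", "I")) {
  ss_type <- match.arg(ss_type)
  required <- c("strain", "sex", "ct_target", "ct_reference")
  if (!all(required %in% names(qpcr)))
    sa_error("format", paste("qpcr table must have columns:",
                             paste(required, collapse = ", ")))
  if (any(table(qpcr$strain) < 2L))
    sa_error("design", "need >= 2 samples per strain")
  dropped <- stats::sd(qpcr$ct_reference) == 0
  if (dropped)
    warning("constant reference C_T: covariate dropped, plain two-way ANOVA")
  form <- if (dropped) ct_target ~ strain + sex + strain:sex
          else ct_target ~ ct_reference + strain + sex + strain:sex
  fit <- partial_ss_fit(form, qpcr, ss_type = ss_type)
  strains <- sort(unique(as.character(qpcr$strain)))
  sexes <- sort(unique(as.character(qpcr$sex)))
  grid <- expand.grid(strain = strains, sex = sexes, stringsAsFactors = FALSE)
  grid$ct_reference <- mean(qpcr$ct_reference)
  gd <- grid
  gd$strain <- factor(gd$strain, levels = levels(factor(qpcr$strain)))
  gd$sex <- factor(gd$sex, levels = levels(factor(qpcr$sex)))
  Xg <- stats::model.matrix(stats::delete.response(stats::terms(form)), gd,
                            contrasts.arg = fit$contrasts)
  Xg <- Xg[, names(fit$coefficients), drop = FALSE]
  pred <- as.vector(Xg %*% fit$coefficients)
  adj <- tapply(pred, grid$strain, mean)
  adj <- stats::setNames(as.numeric(adj[strains]), strains)
  list(anova = fit, adjusted_means = adj, covariate_dropped = dropped)
}

#' Tukey studentized-range pairwise comparisons
#'
#' For each pair of groups, the studentized-range statistic
#' \deqn{q_{ij} = |m_i - m_j| / \sqrt{(MSE/2)(1/n_i + 1/n_j)}}
#' (harmonic Tukey-Kramer convention for unbalanced sizes) with p-values from
#' the studentized range distribution on (k groups, residual df). Grouping
#' letters are the standard compact letter display: letters correspond to
#' maximal sets of mutually non-significant groups, so two groups share a
#' letter if and only if they belong to a common non-significant set.
#'
#' @param group_means named numeric vector of group means.
#' @param mse residual mean square from the omnibus fit.
#' @param df_resid residual degrees of freedom.
#' @param group_sizes named integer vector of group sizes (recycled if
#'   unnamed scalar).
#' @param alpha significance level for the letters (default 0.05).
#' @return list with \code{comparisons} (data.frame: group1, group2, diff, q,
#'   p) and \code{letters} (named character).
#' @export
tukey_hsd <- function(group_means, mse, df_resid, group_sizes, alpha = 0.05) {
  k <- length(group_means)
  if (k < 2L) sa_error("design", "need at least 2 groups")
  groups <- names(group_means)
  if (is.null(groups)) groups <- paste0("g", seq_len(k))
  if (length(group_sizes) == 1L)
    group_sizes <- stats::setNames(rep(group_sizes, k), groups)
  if (is.null(names(group_sizes))) names(group_sizes) <- groups
  pairs <- utils::combn(groups, 2L)
  comp <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                     stringsAsFactors = FALSE)
  comp$diff <- group_means[comp$group1] - group_means[comp$group2]
  se <- sqrt((mse / 2) * (1 / group_sizes[comp$group1] +
                          1 / group_sizes[comp$group2]))
  comp$q <- ifelse(se > 0, abs(comp$diff) / se,
                   ifelse(comp$diff == 0, 0, Inf))
  comp$p <- ifelse(is.finite(comp$q),
                   stats::ptukey(comp$q, k, df_resid, lower.tail = FALSE), 0)
  rownames(comp) <- NULL
  # compact letter display: maximal mutually-non-significant sets
  ns <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (r in seq_len(nrow(comp))) {
    sig <- comp$p[r] < alpha
    ns[comp$group1[r], comp$group2[r]] <- !sig
    ns[comp$group2[r], comp$group1[r]] <- !sig
  }
  if (k > 16L) {
    letters_out <- stats::setNames(rep(NA_character_, k), groups)
  } else {
    cliques <- list()
    for (mask in seq_len(2^k - 1L)) {
      members <- which(bitwAnd(bitwShiftL(1L, seq_len(k) - 1L), mask) != 0L)
      if (all(ns[members, members])) cliques[[length(cliques) + 1L]] <- members
    }
    maximal <- Filter(function(cl) !any(vapply(cliques, function(other)
      length(other) > length(cl) && all(cl %in% other), TRUE)), cliques)
    maximal <- unique(maximal)
    ord <- order(vapply(maximal, function(cl) min(group_means[cl]), 1.0))
    maximal <- maximal[ord]
    letters_out <- stats::setNames(rep("", k), groups)
    for (i in seq_along(maximal))
      letters_out[maximal[[i]]] <- paste0(letters_out[maximal[[i]]], letters[i])
  }
  list(comparisons = comp, letters = letters_out, alpha = alpha)
}
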