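test_that("gene-wise least squares matches the normal-equations oracle", {
  set.seed(20)
  samples <- tiny_samples()
  X <- strain_design(samples)
  y <- sim_expression(10)
  fit <- fit_gene_linear_models(y, X)
  XtXi <- solve(t(X) %*% X)
  for (g in 1:10) {
    beta <- XtXi %*% t(X) %*% y[g, ]
    expect_equal(unname(fit$coefficients[g, ]), as.vector(beta),
                 tolerance = 1e-10)
    rss <- sum((y[g, ] - X %*% beta)^2)
    expect_equal(unname(fit$sigma2[g]), rss / fit$df_resid, tolerance = 1e-10)
  }
  # intercept-only design gives row means
  fit0 <- fit_gene_linear_models(y, matrix(1, 16, 1))
  expect_equal(unname(fit0$coefficients[, 1]), unname(rowMeans(y)))
  # noiseless two-group difference of 1.0
  y2 <- matrix(rep(c(0, 1), each = 8), 1, 16,
               dimnames = list("g", samples$sample_id))
  X2 <- cbind(1, rep(c(0, 1), each = 8))
  fit2 <- fit_gene_linear_models(y2, X2)
  expect_equal(unname(fit2$coefficients[1, 2]), 1)
  expect_equal(unname(fit2$sigma2), 0)
  # rank-deficient design names the aliased column
  X3 <- cbind(a = 1, b = rep(c(0, 1), each = 8), c = rep(c(0, 1), each = 8))
  expect_error(fit_gene_linear_models(y, X3), "aliased column")
})

test_that("variance moderation has the documented limiting behavior", {
  set.seed(21)
  y <- sim_expression(300, noise_sd = 0.5)
  X <- strain_design(tiny_samples())
  fit <- fit_gene_linear_models(y, X)
  # d0 = 0: moderated t equals the classical t exactly
  m0 <- moderate_variances(fit, d0 = 0)
  cvec <- c(-0.5, -0.5, 0.5, 0.5)
  tt <- strainarray:::moderated_t(m0, cvec)
  u <- sqrt(as.vector(t(cvec) %*% fit$cov_unscaled %*% cvec))
  t_classic <- as.vector(fit$coefficients %*% cvec) / (u * sqrt(unname(fit$sigma2)))
  expect_equal(tt$statistic, t_classic, tolerance = 1e-10)
  expect_equal(tt$df, fit$df_resid)
  # d0 = Inf: every posterior variance equals the pooled prior
  mInf <- moderate_variances(fit, d0 = Inf)
  expect_true(all(mInf$sigma2_post == mInf$s02))
  # posterior variance always lies between s2 and s02
  m <- moderate_variances(fit)
  expect_true(all(m$sigma2_post >= pmin(m$sigma2, m$s02) - 1e-12))
  expect_true(all(m$sigma2_post <= pmax(m$sigma2, m$s02) + 1e-12))
})

test_that("prior (d0, s02) is recovered from simulated variances", {
  set.seed(22)
  s2 <- 0.05 * rf(2000, 16, 4)   # d_g = 16, d0 = 4, s02 = 0.05
  fits <- structure(list(sigma2 = s2, df_resid = 16,
                         coefficients = matrix(0, 2000, 1),
                         cov_unscaled = matrix(1), design = matrix(1, 17)),
                    class = "GeneFits")
  m <- moderate_variances(fits)
  expect_lt(abs(m$d0 - 4) / 4, 0.25)
  expect_lt(abs(m$s02 - 0.05) / 0.05, 0.25)
})

test_that("moderated statistics agree with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(23)
  y <- matrix(rnorm(500 * 6, sd = rep(sqrt(0.05 * rf(500, 4, 5)), 6)), 500, 6)
  rownames(y) <- paste0("g", 1:500)
  X <- cbind(1, rep(0:1, each = 3))
  m <- moderate_variances(fit_gene_linear_models(y, X))
  lf <- limma::eBayes(limma::lmFit(y, X))
  expect_equal(m$d0, lf$df.prior, tolerance = 1e-8)
  expect_equal(m$s02, lf$s2.prior, tolerance = 1e-8)
  tt <- strainarray:::moderated_t(m, c(0, 1))
  expect_equal(tt$statistic, unname(lf$t[, 2]), tolerance = 1e-10)
})

test_that("contrasts behave correctly on planted and degenerate inputs", {
  samples <- tiny_samples()
  strains <- sort(unique(samples$strain))
  # all strain means equal, noiseless: F = 0, p = 1
  y <- sim_expression(5, noise_sd = 0)
  m <- moderate_variances(fit_gene_linear_models(y, strain_design(samples)))
  fres <- test_contrasts(m, "among_strain")
  expect_true(all(fres$statistic == 0))
  expect_true(all(fres$p == 1))
  # planted domestication effect of -2.483 log2 (5.59-fold down), noise 0.2
  set.seed(24)
  eff <- matrix(0, 50, 4, dimnames = list(NULL, strains))
  eff[, c("SH", "TM1")] <- -2.483
  y2 <- sim_expression(50, effects = eff, noise_sd = 0.2)
  m2 <- moderate_variances(fit_gene_linear_models(y2, strain_design(samples)))
  dres <- test_contrasts(m2, "wild_vs_domesticated")
  expect_equal(mean(dres$estimate), -2.483, tolerance = 0.1)
  expect_equal(mean(dres$fold_change), 5.59, tolerance = 0.15)
  expect_true(all(dres$direction == "down"))
  # swapping the class labels flips the contrast sign exactly
  samples_sw <- samples
  samples_sw$domestication <- ifelse(samples_sw$domestication == "wild",
                                     "domesticated", "wild")
  m2s <- moderate_variances(fit_gene_linear_models(y2, strain_design(samples_sw)))
  dres_sw <- test_contrasts(m2s, "wild_vs_domesticated")
  expect_equal(dres_sw$estimate, -dres$estimate, tolerance = 1e-12)
  # sex contrast from the factorial model detects a planted sex effect
  y3 <- sim_expression(20, noise_sd = 0.1)
  male <- samples$sex == "M"
  y3[1:10, male] <- y3[1:10, male] + 1
  m3 <- moderate_variances(fit_gene_linear_models(y3, factorial_design(samples)))
  sres <- test_contrasts(m3, "sex")
  expect_true(all(sres$adj_p[1:10] < 0.05))
  expect_equal(mean(sres$estimate[1:10]), 1, tolerance = 0.15)
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(25)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # monotone in the ranks of p
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "strainarray_value_error")
})

test_that("fold changes use group means with the inclusive 2-fold convention", {
  samples <- tiny_samples()
  expr <- sim_expression(3, noise_sd = 0)
  expr[2, samples$domestication == "wild"] <-
    expr[2, samples$domestication == "wild"] + 1
  expr[3, samples$domestication == "wild"] <-
    expr[3, samples$domestication == "wild"] + 2.4829
  fc <- fold_changes(expr, samples$domestication)
  expect_equal(fc$fold_change[1], 1)
  expect_equal(fc$fold_change[2], 2)
  expect_true(fc$fold_change[2] >= 2)        # boundary counts as 2-fold
  expect_equal(fc$fold_change[3], 5.59, tolerance = 1e-3)
  # among-strain: maximum over the 6 pairs
  expr2 <- sim_expression(1, noise_sd = 0)
  expr2[1, samples$strain == "TM1"] <- expr2[1, samples$strain == "TM1"] + 3
  fc2 <- fold_changes(expr2, samples$strain)
  expect_equal(fc2$fold_change, 8)
  expect_match(fc2$pair, "TM1")
  expect_error(fold_changes(expr, rep("A", 16)), class = "strainarray_design_error")
})

test_that("range-overlap filter counts boundary samples as inside", {
  samples <- tiny_samples()
  wild <- samples$sample_id[samples$domestication == "wild"][1:4]
  dom <- samples$sample_id[samples$domestication == "domesticated"][1:4]
  expr <- matrix(0, 3, 8, dimnames = list(c("disjoint", "identical", "partial"),
                                          c(wild, dom)))
  expr["disjoint", ] <- c(1, 2, 3, 4, 10, 11, 12, 13)
  expr["identical", ] <- c(1, 2, 3, 4, 1, 2, 3, 4)
  expr["partial", ] <- c(1, 2, 3, 4, 3.5, 5, 6, 7)
  out <- range_overlap_filter(expr, wild, dom)
  expect_equal(out$overlap[out$probeset_id == "disjoint"], 0L)
  expect_true(out$retained[out$probeset_id == "disjoint"])
  expect_gte(out$overlap[out$probeset_id == "identical"], 4L)
  expect_false(out$retained[out$probeset_id == "identical"])
  expect_equal(out$overlap[out$probeset_id == "partial"], 2L)
  expect_false(out$retained[out$probeset_id == "partial"])
})

test_that("planted effects are detected and null data stays null", {
  set.seed(26)
  samples <- tiny_samples()
  strains <- sort(unique(samples$strain))
  # power: |log2| >= 1 on one mixed strain pair, noise sd 0.25
  eff <- matrix(0, 200, 4, dimnames = list(NULL, strains))
  eff[1:100, c("Nadia", "SH")] <- 1
  y <- sim_expression(200, effects = eff, noise_sd = 0.25)
  m <- moderate_variances(fit_gene_linear_models(y, strain_design(samples)))
  res <- test_contrasts(m, "among_strain")
  expect_gte(mean(res$adj_p[1:100] < 0.05), 0.8)
  # type-I error under the complete null, all three contrasts
  fractions <- t(replicate(20, {
    y0 <- sim_expression(200, noise_sd = 0.25)
    ms <- moderate_variances(fit_gene_linear_models(y0, strain_design(samples)))
    mf <- moderate_variances(fit_gene_linear_models(y0, factorial_design(samples)))
    c(strain = mean(test_contrasts(ms, "among_strain")$adj_p < 0.05),
      dom = mean(test_contrasts(ms, "wild_vs_domesticated")$adj_p < 0.05),
      sex = mean(test_contrasts(mf, "sex")$adj_p < 0.05))
  }))
  for (ct in colnames(fractions)) {
    bound <- 0.05 + 2 * sd(fractions[, ct]) / sqrt(nrow(fractions))
    expect_lte(mean(fractions[, ct]), bound)
  }
})
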