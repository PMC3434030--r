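test_that("background correction is monotone, positive, and has the right limit", {
  set.seed(5)
  pm <- matrix(exp(rnorm(4000, log(300), 0.8)) + 80, 1000, 4,
               dimnames = list(NULL, paste0("s", 1:4)))
  bc <- background_correct(pm)
  expect_true(all(bc$corrected > 0))
  for (i in 1:4)
    expect_identical(order(bc$corrected[, i]), order(pm[, i]))
  # sigma -> 0 limit with observed >> mu: corrected -> o - mu - sigma^2 alpha
  o <- 5000; mu <- 100; alpha <- 0.01
  for (sigma in c(1, 0.1, 0.01))
    expect_equal(bg_posterior_mean(o, mu, sigma, alpha),
                 o - mu - sigma^2 * alpha, tolerance = 1e-9)
  # degenerate constant sample
  expect_error(background_correct(matrix(100, 50, 2)),
               class = "strainarray_estimation_error")
})

test_that("closed-form posterior mean matches numerical quadrature", {
  set.seed(7)
  relerr <- replicate(20, {
    mu <- runif(1, 50, 150); sigma <- runif(1, 5, 40)
    alpha <- 1 / runif(1, 100, 2000)
    o <- runif(1, mu - 1.5 * sigma, mu + 4 / alpha)
    f <- function(s) s * dnorm(o - s, mu, sigma) * exp(-alpha * s)
    g <- function(s) dnorm(o - s, mu, sigma) * exp(-alpha * s)
    num <- integrate(f, 0, o, rel.tol = 1e-12, abs.tol = 0)$value
    den <- integrate(g, 0, o, rel.tol = 1e-12, abs.tol = 0)$value
    abs(bg_posterior_mean(o, mu, sigma, alpha) - num / den) / (num / den)
  })
  expect_lt(max(relerr), 1e-6)
})

test_that("quantile normalization equalizes distributions as defined", {
  # single column unchanged
  x1 <- matrix(rnorm(10), 10, 1)
  expect_identical(quantile_normalize(x1), x1)
  # hand-computed rank means
  x <- cbind(c(2, 4, 6), c(1, 3, 5))
  expect_equal(unname(quantile_normalize(x)),
               cbind(c(1.5, 3.5, 5.5), c(1.5, 3.5, 5.5)))
  # post-condition: identical sorted columns, machine precision
  set.seed(1)
  y <- matrix(rnorm(500 * 6), 500, 6)
  qn <- quantile_normalize(y)
  ref <- sort(qn[, 1])
  for (i in 2:6) expect_equal(sort(qn[, i]), ref, tolerance = 1e-15)
  # rank order preserved within columns
  for (i in 1:6) expect_identical(order(qn[, i]), order(y[, i]))
  expect_error(quantile_normalize(cbind(c(1, NA), c(1, 2))),
               class = "strainarray_value_error")
})

test_that("quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(2)
  y <- matrix(rexp(300 * 5), 300, 5)
  expect_equal(unname(quantile_normalize(y)),
               unname(limma::normalizeQuantiles(y)), tolerance = 1e-12)
})

test_that("median polish recovers additive structure and resists outliers", {
  probes <- paste0("g:", 1:5)
  pmap <- data.frame(probe_id = probes, probeset_id = "g", probe_index = 1:5)
  e <- c(7, 8, 9, 8.5)
  phi <- c(-1, 0, 0.5, 1, -0.5)
  z <- outer(phi, e, `+`)
  rownames(z) <- probes
  out <- median_polish_summarize(z, pmap)
  expect_equal(unname(out[1, ] - out[1, 1]), e - e[1], tolerance = 1e-12)
  # constant matrix
  zc <- matrix(3.3, 5, 4, dimnames = list(probes, NULL))
  expect_equal(unname(median_polish_summarize(zc, pmap)[1, ]), rep(3.3, 4))
  # gross outlier: matches the independent median-polish oracle, not the mean
  set.seed(3)
  z2 <- outer(phi[1:3], c(5, 6, 7), `+`)
  z2[2, 2] <- z2[2, 2] + 10
  rownames(z2) <- probes[1:3]
  pmap3 <- pmap[1:3, ]
  mine <- median_polish_summarize(z2, pmap3, tol = 1e-13, maxiter = 500)
  ref <- stats::medpolish(z2, eps = 1e-13, maxiter = 500, trace.iter = FALSE)
  expect_equal(unname(mine[1, ]), unname(ref$overall + ref$col),
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(unname(mine[1, ]), unname(colMeans(z2)),
                                tolerance = 0.01)))
})

test_that("detection calls implement the exact signed-rank null and call map", {
  samples <- tiny_samples()
  n <- 11
  ids <- paste0("g:", 1:n)
  # all discrimination scores identical at 0.5: maximal statistic, p = 1/2048
  pm <- matrix(300, n, 16, dimnames = list(ids, samples$sample_id))
  mm <- matrix(100, n, 16, dimnames = list(ids, samples$sample_id))
  ds <- probe_level_dataset(pm, mm, samples)
  calls <- detection_calls(ds)
  expect_equal(calls$pvalue[1, 1], 1 / 2048)
  expect_true(all(calls$call == "P"))
  # boundary: p exactly equal to the cutoff is Marginal
  calls_b <- detection_calls(ds, p_present = 1 / 2048, p_absent = 1 / 2048)
  expect_true(all(calls_b$call == "M"))
  # scores below tau: wrong direction, p >= 0.5, Absent
  pm2 <- mm + 1          # R slightly above 0 but below tau = 0.015 only if small
  pm2 <- mm * (1 + 0.01) # R ~ 0.005 < tau
  rownames(pm2) <- ids
  ds2 <- probe_level_dataset(pm2, mm, samples)
  calls2 <- detection_calls(ds2)
  expect_true(all(calls2$pvalue >= 0.5))
  expect_true(all(calls2$call == "A"))
})

test_that("expression threshold filter follows the pooled-quantile definition", {
  samples <- tiny_samples()
  sim <- small_sim(n = 200, seed = 6)
  pre <- rma_preprocess(sim$dataset)
  calls <- detection_calls(sim$dataset)
  ef <- expression_threshold_filter(pre$expr, calls)
  all_absent <- rowSums(calls$call[rownames(pre$expr), ] == "P") == 0
  expect_equal(ef$threshold,
               unname(quantile(pre$expr[all_absent, ], 0.99, type = 7)))
  kept <- rownames(ef$expr)
  expect_true(all(apply(pre$expr[kept, , drop = FALSE], 1, max) >= ef$threshold))
  removed_max <- apply(pre$expr[ef$removed, , drop = FALSE], 1, max)
  expect_true(all(removed_max < ef$threshold))
  # idempotent
  ef2 <- expression_threshold_filter(ef$expr, calls)
  expect_identical(rownames(ef2$expr), rownames(ef$expr))
  # vacuous when nothing is absent everywhere
  calls_p <- calls
  calls_p$call[] <- "P"
  expect_warning(ef3 <- expression_threshold_filter(pre$expr, calls_p),
                 "vacuous")
  expect_identical(ef3$expr, pre$expr)
  expect_equal(ef3$threshold, -Inf)
})

test_that("IQR filter applies the linear-interpolation convention strictly", {
  x <- rbind(const = rep(1, 16),
             half = c(rep(0, 8), rep(0.5, 8)),
             unit = c(rep(0, 8), rep(1, 8)))
  colnames(x) <- paste0("s", 1:16)
  out <- iqr_filter(x, min_iqr = 0.5)
  expect_identical(out$removed, "const")              # IQR 0 removed
  expect_true("half" %in% rownames(out$expr))         # IQR exactly 0.5 retained
  expect_true("unit" %in% rownames(out$expr))         # IQR 1.0 retained
  expect_equal(unname(out$iqr["unit"]), 1.0)
  expect_error(iqr_filter(x[, 1:3]), class = "strainarray_format_error")
})

test_that("full RMA path on noiseless additive data recovers planted effects", {
  cfg <- sim_config(n_probesets = 200, measurement_noise_sd = 0,
                    background_sd = 5, biological_strain_sd = 0, seed = 12)
  sim <- generate_probe_level_dataset(cfg)
  pre <- rma_preprocess(sim$dataset)
  tr <- sim$truth$probesets
  dom <- tr$probeset_id[tr$de_domestication]
  s <- sim$dataset$samples
  diff <- rowMeans(pre$expr[dom, s$domestication == "domesticated"]) -
          rowMeans(pre$expr[dom, s$domestication == "wild"])
  err <- diff - tr$dom_effect_log2[match(dom, tr$probeset_id)]
  expect_lt(max(abs(err)), 0.05)
})

test_that("filters retain planted informative genes and drop unexpressed ones", {
  sim <- small_sim(n = 600, seed = 22)
  pre <- rma_preprocess(sim$dataset)
  calls <- detection_calls(sim$dataset)
  kept <- rownames(iqr_filter(expression_threshold_filter(pre$expr, calls)$expr)$expr)
  tr <- sim$truth$probesets
  de <- tr$probeset_id[tr$de_strain | tr$de_domestication | tr$de_sex]
  unexpr <- tr$probeset_id[!tr$expressed]
  expect_gte(mean(de %in% kept), 0.95)
  expect_gte(mean(!(unexpr %in% kept)), 0.90)
})
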