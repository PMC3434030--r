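make_obs <- function(fish_id, zones, flags, strain = "A", sex = "F",
                     recordings_per_period = 3) {
  n <- length(zones)
  data.frame(fish_id = fish_id, strain = strain, sex = sex,
             period = rep(seq_len(ceiling(n / recordings_per_period)),
                          each = recordings_per_period)[1:n],
             recording = rep(seq_len(recordings_per_period),
                             times = ceiling(n / recordings_per_period))[1:n],
             vertical_zone = zones, front_flag = flags,
             stringsAsFactors = FALSE)
}

test_that("behavior scoring computes period means and front proportions", {
  # all recordings zone 6, flag 0
  ob <- make_obs("f1", rep(6L, 90), rep(0L, 90))
  sc <- score_behavior(ob)
  expect_equal(sc$vertical_depth, 6)
  expect_equal(sc$horizontal_position, 0)
  # two periods with period-mean zones 2 and 4
  ob2 <- make_obs("f2", c(1L, 2L, 3L, 4L, 4L, 4L), c(0L, 0L, 0L, 1L, 1L, 1L))
  sc2 <- score_behavior(ob2)
  expect_equal(sc2$vertical_depth, 3)
  # 90 recordings, 27 front
  ob3 <- make_obs("f3", rep(3L, 90), c(rep(1L, 27), rep(0L, 63)))
  expect_equal(score_behavior(ob3)$horizontal_position, 0.30)
  # invariant to recording order within periods
  ob4 <- ob3[sample(nrow(ob3)), ]
  expect_equal(score_behavior(ob4)$vertical_depth,
               score_behavior(ob3)$vertical_depth)
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(40)
  d <- data.frame(y = rnorm(20) + rep(c(0, 1), each = 10),
                  g = rep(c("a", "b"), each = 10))
  an <- fixed_effects_anova(d, y ~ g)
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(an$table$statistic[1], unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(an$table$p[1], tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA degrees of freedom follow the design", {
  set.seed(41)
  # one-way, 4 strains, 62 fish: df = (3, 58)
  d <- data.frame(y = rnorm(62),
                  strain = c(rep(c("G", "N", "S", "T"), each = 15), "G", "N"))
  an <- fixed_effects_anova(d, y ~ strain)
  expect_equal(an$table$df[an$table$term == "strain"], 3)
  expect_equal(an$table$df[an$table$term == "Residuals"], 58)
  # term df + residual df = n - 1 for the nested model
  b <- generate_behavior_data(8, seed = 3)
  sc <- score_behavior(b$observations)
  an2 <- fixed_effects_anova(sc, vertical_depth ~ sex + domestication +
                                   domestication:strain)
  expect_equal(sum(an2$table$df), nrow(sc) - 1)
})

test_that("partial SS matches the projection-matrix oracle on a balanced design", {
  set.seed(42)
  d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:5)
  d$y <- rnorm(20) + (d$a == "x") * 0.8 + (d$b == "u") * 0.4
  an <- fixed_effects_anova(d, y ~ a + b + a:b)
  # oracle: hat-matrix projections with sum contrasts
  X <- model.matrix(~ a + b + a:b, d,
                    contrasts.arg = list(a = contr.sum, b = contr.sum))
  proj <- function(M) M %*% solve(t(M) %*% M) %*% t(M)
  rss <- function(M) sum(((diag(20) - proj(M)) %*% d$y)^2)
  full <- rss(X)
  for (t in 1:3) {
    ss_oracle <- rss(X[, attr(X, "assign") != t, drop = FALSE]) - full
    expect_equal(an$table$sum_sq[t], ss_oracle, tolerance = 1e-8)
  }
  # balanced design: SS decomposition is exact
  expect_equal(sum(an$table$sum_sq),
               sum((d$y - mean(d$y))^2), tolerance = 1e-8)
})

test_that("partial SS agrees with the car type-III reference", {
  skip_if_not_installed("car")
  set.seed(43)
  d <- data.frame(y = rnorm(30), a = factor(sample(c("x", "y"), 30, TRUE)),
                  b = factor(sample(c("u", "v", "w"), 30, TRUE)))
  an <- fixed_effects_anova(d, y ~ a + b + a:b)
  mod <- lm(y ~ a + b + a:b, data = d,
            contrasts = list(a = contr.sum, b = contr.sum))
  ca <- car::Anova(mod, type = 3)
  expect_equal(an$table$sum_sq[1:3], ca[2:4, "Sum Sq"], tolerance = 1e-8)
  expect_equal(an$table$p[1:3], ca[2:4, "Pr(>F)"], tolerance = 1e-8)
})

test_that("confounded terms are reported by name", {
  d <- data.frame(y = rnorm(12), a = rep(c("x", "y"), each = 6),
                  b = rep(c("u", "v"), each = 6))   # b aliased with a
  expect_error(fixed_effects_anova(d, y ~ a + b), "confounded")
})

test_that("domestication effects on behavior are reliably detected at study size", {
  ps <- replicate(20, {
    b <- generate_behavior_data(16, seed = sample.int(1e6, 1))
    sc <- score_behavior(b$observations)
    an <- fixed_effects_anova(sc, vertical_depth ~ sex + domestication +
                                    domestication:strain)
    an$table$p[an$table$term == "domestication"]
  })
  expect_gte(mean(ps < 0.001), 0.95)
})

test_that("the ANCOVA adjusts for the reference covariate correctly", {
  # ct_target = ct_reference + strain constant, no residual noise
  set.seed(44)
  q <- generate_qpcr_data(c(A = 24, B = 25, C = 26, D = 27),
                          noise_sd = 0.3, beta = 1,
                          domestication = c(A = "wild", B = "wild",
                                            C = "domesticated", D = "domesticated"),
                          seed = 6)$qpcr
  q$ct_target <- q$ct_reference + c(A = 0, B = 1, C = 2, D = 3)[q$strain]
  an <- qpcr_ancova(q)
  expect_equal(unname(diff(an$adjusted_means)), c(1, 1, 1), tolerance = 1e-8)
  expect_equal(an$anova$table$p[an$anova$table$term == "strain"], 0)
  # constant covariate reduces to the plain two-way ANOVA
  q2 <- q
  q2$ct_reference <- 20
  q2$ct_target <- rnorm(16) + c(A = 0, B = 1, C = 2, D = 3)[q2$strain]
  expect_warning(an2 <- qpcr_ancova(q2), "constant reference")
  plain <- fixed_effects_anova(q2, ct_target ~ strain + sex + strain:sex)
  expect_equal(an2$anova$table$sum_sq, plain$table$sum_sq, tolerance = 1e-10)
})

test_that("ANCOVA adjusted means agree with the emmeans reference", {
  skip_if_not_installed("emmeans")
  q <- generate_qpcr_data(seed = 7)$qpcr
  an <- qpcr_ancova(q)
  mod <- lm(ct_target ~ ct_reference + strain * sex, data = q)
  em <- summary(emmeans::emmeans(mod, "strain"))
  expect_equal(unname(an$adjusted_means),
               em$emmean[match(names(an$adjusted_means), em$strain)],
               tolerance = 1e-10)
})

test_that("Tukey comparisons collapse to the pooled t for two groups", {
  set.seed(45)
  y <- rnorm(20) + rep(c(0, 0.8), each = 10)
  g <- rep(c("a", "b"), each = 10)
  fit <- lm(y ~ g)
  mse <- sum(resid(fit)^2) / fit$df.residual
  means <- tapply(y, g, mean)
  th <- tukey_hsd(means, mse, fit$df.residual, c(a = 10, b = 10))
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(th$comparisons$q, unname(abs(tt$statistic)) * sqrt(2),
               tolerance = 1e-8)
  expect_equal(th$comparisons$p, tt$p.value, tolerance = 1e-8)
})

test_that("Tukey letters separate a distant group and merge equal ones", {
  means <- c(a = 0, b = 0.01, c = 0.02, d = 10)   # d is ~10 sd away
  th <- tukey_hsd(means, mse = 1, df_resid = 28, group_sizes = 8)
  expect_true(all(th$comparisons$p[th$comparisons$group1 == "d" |
                                   th$comparisons$group2 == "d"] < 0.05))
  expect_false(th$letters[["d"]] %in% th$letters[c("a", "b", "c")])
  expect_true(all(th$letters[c("a", "b", "c")] == th$letters[["a"]]))
  # all means equal: one shared letter, p ~ 1
  th2 <- tukey_hsd(c(a = 1, b = 1, c = 1), mse = 1, df_resid = 20,
                   group_sizes = 5)
  expect_true(all(th2$comparisons$p > 0.99))
  expect_true(all(th2$letters == th2$letters[[1]]))
  expect_error(tukey_hsd(c(a = 1), 1, 10, 5), class = "strainarray_design_error")
})
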