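test_that("mixed model matches an OLS oracle when the random effect vanishes", {
  tab <- make_sai_table(30, ranef_sd = 0, noise_sd = 8, seed = 3)
  fit <- fit_sai_recalibration_model(tab)
  conf <- as.numeric(tab$session == "conflict")
  d <- data.frame(y = tab$delta_sai,
                  vp = (1 - conf) * tab$recal_p, cp = conf * tab$recal_p,
                  vv = (1 - conf) * tab$recal_v, cv = conf * tab$recal_v)
  ols <- lm(y ~ vp + cp + vv + cv, data = d)
  if (!fit$converged) {
    expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
  } else {
    # non-degenerate REML fit: still close to OLS for iid data
    expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 0.05)
  }
  expect_equal(fit$n_observations, 60)
  expect_equal(unique(fit$terms$df), 55)
})

test_that("mixed model recovers generative slopes and flags structure", {
  # n and noise sized so the slope's sampling SD (~0.07) is well inside the
  # 0.2 tolerance
  tab <- make_sai_table(400, betas = c(intercept = 105, ver_p = 0,
                                       conf_p = 1.8, ver_v = 0, conf_v = 0),
                        noise_sd = 8, ranef_sd = 6, seed = 9)
  fit <- fit_sai_recalibration_model(tab)
  tm <- fit$terms
  cp <- tm[tm$term == "conf_recal_p", ]
  expect_lt(abs(cp$beta - 1.8), 0.2)
  expect_lt(cp$p, 0.05)
  for (nm in c("ver_recal_p", "ver_recal_v")) {
    row <- tm[tm$term == nm, ]
    expect_true(row$ci_low <= 0 && row$ci_high >= 0)
  }
  expect_true(all(tm$ci_low <= tm$beta & tm$beta <= tm$ci_high))
  expect_true(all(fit$vif >= 1))
})

test_that("constant outcome gives zero slopes and the constant intercept", {
  tab <- make_sai_table(20, seed = 5)
  tab$delta_sai <- 107
  fit <- fit_sai_recalibration_model(tab)
  tm <- fit$terms
  expect_equal(tm$beta[tm$term == "(Intercept)"], 107)
  expect_equal(tm$beta[tm$term != "(Intercept)"], rep(0, 4),
               tolerance = 1e-10)
})

test_that("collinear predictors raise an error; incomplete participants are dropped", {
  tab <- make_sai_table(20, seed = 6)
  tab$recal_v <- tab$recal_p          # duplicated predictor
  expect_error(fit_sai_recalibration_model(tab), "collinear")

  tab2 <- make_sai_table(20, seed = 7)
  tab2 <- tab2[-1, ]                  # participant 1 missing a session
  expect_warning(fit <- fit_sai_recalibration_model(tab2), "excluding")
  expect_equal(fit$n_participants, 19)
})

test_that("VIF is 1 for orthogonal predictors", {
  # orthogonal by construction: each predictor varies in a different session
  n <- 40
  tab <- data.frame(participant = rep(1:n, 2),
                    session = rep(c("conflict", "veridical"), each = n))
  set.seed(8)
  tab$recal_p <- rnorm(2 * n)
  tab$recal_v <- rnorm(2 * n)
  conf <- as.numeric(tab$session == "conflict")
  X <- data.frame(a = conf * tab$recal_p, b = (1 - conf) * tab$recal_p)
  # orthogonalize explicitly
  X$b <- resid(lm(X$b ~ X$a))
  v <- vpalign:::.vif(X)
  expect_equal(unname(v), c(1, 1), tolerance = 1e-8)
})

test_that("predictor residuals isolate the unique component", {
  set.seed(4)
  n <- 50
  other <- rnorm(n)
  e <- rnorm(n)
  tab <- data.frame(target = other + e, other = other,
                    delta_sai = rnorm(n))
  r <- predictor_residuals(tab, "target", "other")
  fit <- lm(tab$target ~ tab$other)
  expect_equal(r$residual, unname(resid(fit)), tolerance = 1e-9)
  # exact linear dependence -> all residuals zero
  tab2 <- data.frame(target = 2 * other, other = other)
  expect_equal(predictor_residuals(tab2, "target", "other")$residual,
               rep(0, n), tolerance = 1e-9)
  # zero-variance other -> centred target
  tab3 <- data.frame(target = other, other = rep(1, n))
  expect_equal(predictor_residuals(tab3, "target", "other")$residual,
               other - mean(other), tolerance = 1e-12)
})

test_that("2x2 repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(12)
  vals <- expand.grid(participant = 1:8, a = c("x", "y"), b = c("u", "v"),
                      stringsAsFactors = FALSE)
  vals$value <- rnorm(nrow(vals), 10, 3) + rep(rnorm(8, 0, 2), 4)
  res <- rm_anova_2x2(vals)
  orc <- oracle_rm_anova_2x2(vals)
  expect_equal(res$a$statistic, orc$a, tolerance = 1e-9)
  expect_equal(res$b$statistic, orc$b, tolerance = 1e-9)
  expect_equal(res$a_x_b$statistic, orc$a_x_b, tolerance = 1e-9)
  expect_equal(res$a$df, c(1, 7))

  # constructed null: equal cell means -> F = 0 for everything
  vals0 <- vals
  vals0$value <- rep(rnorm(8), 4)
  res0 <- rm_anova_2x2(vals0)
  expect_equal(res0$a$statistic, 0)
  expect_equal(res0$a_x_b$statistic, 0)

  # crossover design: interaction clearly detected, with noise well below it
  vals1 <- vals
  vals1$value <- 5 + 4 * (vals1$a == "y") * (vals1$b == "v") +
    rep(rnorm(8), 4) + rnorm(32, 0, 0.2)
  res1 <- rm_anova_2x2(vals1)
  expect_lt(res1$a_x_b$p, 0.001)
  expect_error(rm_anova_2x2(vals[-1, ]), "incomplete")
})

test_that("group comparison matches hand-computed sums of squares", {
  vals <- c(1, 2, 3, 4, 5, 6, 9, 8, 10)
  grp <- rep(c("a", "b", "c"), each = 3)
  means <- tapply(vals, grp, mean)
  ssb <- 3 * sum((means - mean(vals))^2)
  ssw <- sum((vals - means[match(grp, names(means))])^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  res <- group_comparison(vals, grp, "anova_tukey")
  expect_equal(res$statistic, f_hand, tolerance = 1e-9)
  expect_equal(res$effect_size, ssb / (ssb + ssw), tolerance = 1e-9)
  expect_equal(res$df, c(2, 6))
  # significant omnibus attaches Tukey-adjusted pairwise table
  if (res$p < 0.05) expect_s3_class(res$pairwise, "data.frame")

  # equal group means -> F = 0
  res0 <- group_comparison(rep(c(1, 2, 3), 3), grp, "anova_tukey")
  expect_equal(res0$statistic, 0)
  expect_null(res0$pairwise)

  # rank path agrees with the base implementation
  k <- group_comparison(vals, grp, "kruskal_wallis")
  k0 <- kruskal.test(vals, factor(grp))
  expect_equal(k$statistic, unname(k0$statistic))
  expect_error(group_comparison(vals[1:6], grp[1:6][grp[1:6] != "c"]),
               "3 groups")
})

test_that("Pearson correlation and one-sample t match closed forms", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, x)$statistic, 1)
  expect_equal(pearson_r(x, -x)$statistic, -1)
  r <- pearson_r(c(1, 2, 3), c(2, 1, 3))
  expect_equal(r$statistic, 0.5, tolerance = 1e-12)
  expect_equal(r$df, 1)
  expect_error(pearson_r(c(1, 1, 1), x), "zero variance")

  tt <- one_sample_t(c(1, 2, 3))
  expect_equal(tt$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(tt$df, 2)
  expect_equal(tt$effect_size, 2)
  expect_equal(one_sample_t(c(-1, 0, 1))$statistic, 0)
  expect_error(one_sample_t(c(2, 2)), "zero standard deviation")
})

test_that("package VIF agrees with the car implementation", {
  skip_if_not_installed("car")
  set.seed(10)
  X <- data.frame(a = rnorm(50), b = rnorm(50))
  X$c <- 0.6 * X$a + rnorm(50, 0, 0.5)
  y <- rnorm(50)
  ours <- vpalign:::.vif(X)
  theirs <- car::vif(lm(y ~ a + b + c, data = X))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})
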