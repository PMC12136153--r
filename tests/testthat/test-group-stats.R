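test_that("proportions carry exact binomial standard errors", {
  p <- proportion_with_sem(34, 48)
  expect_equal(p$p_hat, 34 / 48)
  expect_equal(p$sem, sqrt(p$p_hat * (1 - p$p_hat) / 48))
  z <- proportion_with_sem(0, 20)
  expect_equal(z$pct, 0)
  expect_equal(z$pct_sem, 0)
  expect_error(proportion_with_sem(1, 0), "n must")
  expect_error(proportion_with_sem(5, 3), "0 <= k <= n")
})

test_that("logistic GLMM at the variance boundary equals ordinary logistic", {
  # within-group homogeneous individuals: no overdispersion, so the
  # random-intercept MLE sits at zero and fixed effects match glm
  d <- rbind(
    do.call(rbind, lapply(1:8, function(i) data.frame(
      group = "A", individual_id = paste0("A", i),
      inhibited = c(TRUE, TRUE, FALSE, FALSE, FALSE)))),
    do.call(rbind, lapply(1:8, function(i) data.frame(
      group = "B", individual_id = paste0("B", i),
      inhibited = c(TRUE, TRUE, TRUE, TRUE, FALSE)))))
  f <- fit_logistic_mixed(d)
  g <- stats::glm(inhibited ~ group, binomial, data = d)
  expect_equal(f$ranef_var, 0, tolerance = 1e-8)
  expect_equal(f$coefficients$estimate, unname(coef(g)), tolerance = 1e-4)
})

test_that("identical balanced groups give a near-zero contrast", {
  set.seed(31)
  d <- data.frame(group = rep(c("A", "B"), each = 100),
                  individual_id = rep(1:40, each = 5),
                  inhibited = runif(200) < 0.5)
  f <- fit_logistic_mixed(d)
  expect_lt(abs(f$coefficients$statistic[2]), 2)
  expect_equal(f$link, "logit")
})

test_that("linear mixed model matches OLS at zero random variance", {
  d <- data.frame(group = rep(c("A", "B"), each = 12),
                  individual_id = rep(1:8, each = 3),
                  lambda_max = rep(c(360, 380), each = 12) +
                    rep(c(-2, 0, 2), 8))
  f <- fit_linear_mixed(d)
  o <- stats::lm(lambda_max ~ group, data = d)
  expect_equal(f$ranef_var, 0, tolerance = 1e-6)
  expect_equal(f$coefficients$estimate, unname(coef(o)), tolerance = 1e-6)
})

test_that("a simulated 20 nm group shift is recovered within its CI", {
  set.seed(32)
  id <- rep(1:20, each = 4)
  d <- data.frame(group = rep(c("A", "B"), each = 40),
                  individual_id = id,
                  lambda_max = 370 + 20 * (rep(c(0, 1), each = 40)) +
                    rnorm(20, 0, 3)[id] + rnorm(80, 0, 8))
  f <- fit_linear_mixed(d)
  cf <- f$coefficients[2, ]
  expect_lt(abs(cf$estimate - 20), 2.2 * cf$se)
})

test_that("pairwise tests cover every group pair", {
  set.seed(33)
  d <- data.frame(group = rep(c("a", "b", "c"), each = 30),
                  individual_id = rep(1:18, each = 5),
                  inhibited = runif(90) < rep(c(0.2, 0.5, 0.8), each = 30))
  pw <- pairwise_group_tests(d, link = "logit")
  expect_equal(nrow(pw), 3)
  expect_setequal(paste(pw$group1, pw$group2),
                  c("a b", "a c", "b c"))
})

test_that("one-sample t-tests match the closed form and Bonferroni scaling", {
  x <- c(352, 358, 349, 361, 355, 357)
  tt <- ttest_vs_expected(x, 350, n_comparisons = 4)
  t_manual <- (mean(x) - 350) / (sd(x) / sqrt(length(x)))
  expect_equal(tt$t, t_manual, tolerance = 1e-12)
  expect_equal(tt$p_corrected, min(1, tt$p_value * 4))
  one <- ttest_vs_expected(x, 350, n_comparisons = 1)
  expect_equal(one$p_corrected, one$p_value)
  same <- ttest_vs_expected(rep(355, 5), 355)
  expect_equal(same$t, 0)
  expect_equal(same$p_corrected, 1)
  expect_error(ttest_vs_expected(c(1, 2), 0), "at least 3")
})

test_that("two-group ANOVA reduces to the pooled t-test (t^2 = F)", {
  set.seed(34)
  v <- c(rnorm(15, 50, 8), rnorm(15, 60, 8))
  g <- rep(c("A", "B"), each = 15)
  a <- anova_tukey(v, g)
  t2 <- unname(stats::t.test(v ~ g, var.equal = TRUE)$statistic^2)
  expect_equal(a$F, t2, tolerance = 1e-9)
  expect_equal(a$df, c(1, 28))
})

test_that("Tukey letters isolate an extreme group and merge identical ones", {
  set.seed(35)
  v <- c(rnorm(20, 0, 1), rnorm(20, 0.2, 1), rnorm(20, 10, 1))
  g <- rep(c("a", "b", "c"), each = 20)
  a <- anova_tukey(v, g)
  expect_identical(a$letters[["a"]], a$letters[["b"]])
  expect_false(a$letters[["c"]] %in% a$letters[c("a", "b")])
  expect_error(anova_tukey(v[1:20], g[1:20]), "2 groups")
})
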