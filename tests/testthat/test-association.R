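test_that("centering zeroes means and only moves the intercept", {
  df <- data.frame(x = c(1, 2, 3), k = c(5, 5, 5), y = c(2, 4, 7))
  cen <- center_predictors(df, c("x", "k"))
  expect_equal(cen$data$x, c(-1, 0, 1))
  expect_equal(cen$data$k, c(0, 0, 0))
  expect_equal(cen$centers, c(x = 2, k = 5))

  set.seed(40)
  df2 <- data.frame(x = rnorm(50), y = rnorm(50))
  raw <- fit_linear(y ~ x, df2)
  cen2 <- center_predictors(df2, "x")
  ctr <- fit_linear(y ~ x, cen2$data)
  expect_equal(raw$coefficients$estimate[2], ctr$coefficients$estimate[2],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(raw$coefficients$estimate[1],
                                ctr$coefficients$estimate[1])))
})

test_that("OLS matches the normal-equations oracle", {
  df <- data.frame(x = c(0, 1), y = c(0, 1))
  fit <- fit_linear(y ~ x, df)
  expect_equal(fit$coefficients$estimate, c(0, 1), tolerance = 1e-12)

  set.seed(41)
  X <- cbind(1, matrix(rnorm(150), 50, 3))
  y <- X %*% c(1, 0.5, -0.3, 0.2) + rnorm(50)
  df2 <- data.frame(y = as.numeric(y), x1 = X[, 2], x2 = X[, 3], x3 = X[, 4])
  fit2 <- fit_linear(y ~ x1 + x2 + x3, df2)
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit2$coefficients$estimate, as.numeric(oracle),
               tolerance = 1e-8)

  # exact linear response
  df3 <- data.frame(x = 1:10, y = 2 * (1:10) + 3)
  fit3 <- suppressWarnings(fit_linear(y ~ x, df3))  # exact fit warns in summary()
  expect_equal(fit3$r_squared, 1)
  expect_lt(fit3$rss, 1e-20)

  # collinearity is a named error
  df4 <- data.frame(y = rnorm(20), a = 1:20, b = 2 * (1:20))
  expect_error(fit_linear(y ~ a + b, df4), "collinear")
})

test_that("logistic fits match closed forms and the cross-product OR", {
  set.seed(42)
  y <- rbinom(1000, 1, 0.3)
  fit <- fit_logistic(y ~ 1, data.frame(y = y))
  p_hat <- mean(y)
  expect_equal(fit$coefficients$estimate[1], log(p_hat / (1 - p_hat)),
               tolerance = 1e-8)

  x <- rbinom(1000, 1, 0.5)
  y2 <- rbinom(1000, 1, plogis(-1 + 0.8 * x))
  fit2 <- fit_logistic(y2 ~ x, data.frame(y2 = y2, x = x))
  tab <- table(x, y2)
  or_oracle <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
  expect_equal(fit2$coefficients$odds_ratio[2], or_oracle, tolerance = 1e-6)
  expect_true(all(fit2$fitted_probabilities > 0 &
                    fit2$fitted_probabilities < 1))

  expect_error(fit_logistic(y ~ 1, data.frame(y = rep(1, 30))), "single class")
  sep <- data.frame(y = c(rep(0, 15), rep(1, 15)), x = c(rnorm(15), rnorm(15) + 50))
  expect_error(fit_logistic(y ~ x, sep), "separation")
})

test_that("interaction scan accepts planted terms and stays null-calibrated", {
  # planted sex-by-score interaction worth ~1% of variance at n = 2348
  set.seed(48)
  accept <- replicate(50, {
    n <- 2348
    sex <- rbinom(n, 1, 0.5)
    x <- rnorm(n)
    inter <- (sex - 0.5) * x           # orthogonal to both main effects
    y <- 0.3 * x + sqrt(0.01) * inter / stats::sd(inter) +
      rnorm(n, 0, sqrt(1 - 0.09 - 0.01))
    res <- scan_interactions(y ~ x + sex, data.frame(y = y, x = x, sex = sex),
                             candidates = "sex:x", alpha = 0.002)
    length(res$accepted) == 1
  })
  expect_gte(mean(accept), 0.9)

  # null calibration at alpha = 0.05
  set.seed(43)
  false_pos <- replicate(400, {
    n <- 150
    x <- rnorm(n); sex <- rbinom(n, 1, 0.5); y <- rnorm(n)
    res <- scan_interactions(y ~ x + sex, data.frame(y = y, x = x, sex = sex),
                             candidates = "sex:x", alpha = 0.05)
    length(res$accepted) == 1
  })
  rate <- mean(false_pos)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))

  # alpha = 0 accepts nothing
  res0 <- scan_interactions(y ~ x, data.frame(y = rnorm(50), x = rnorm(50)),
                            candidates = "x:x", alpha = 0)
  expect_length(res0$accepted, 0)
})

test_that("nested F test follows the RSS formula and its distribution", {
  mk <- function(rss, terms, n) {
    structure(list(rss = rss, terms = terms, n = n,
                   df_residual = n - length(terms), r_squared = NA),
              class = "model_fit")
  }
  # plug-in example: RSS_r=110, RSS_f=100, q=2, n-p_f=50 -> F=2.5
  red <- mk(110, c("(Intercept)", "a"), 54)
  ful <- mk(100, c("(Intercept)", "a", "b", "c"), 54)
  res <- nested_f_test(red, ful)
  expect_equal(res$F, 2.5)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 50)
  expect_equal(res$p, stats::pf(2.5, 2, 50, lower.tail = FALSE))

  ident <- nested_f_test(red, red)
  expect_equal(ident$F, 0)
  expect_equal(ident$p, 1)
  expect_error(nested_f_test(ful, red), "not nested")

  # adding pure noise: F ~ F(1, n-p); mean over reps near (n-p)/(n-p-2)
  set.seed(44)
  n <- 30
  fs <- replicate(300, {
    df <- data.frame(y = rnorm(n), x = rnorm(n), z = rnorm(n))
    nested_f_test(fit_linear(y ~ x, df), fit_linear(y ~ x + z, df))$F
  })
  mu <- (n - 3) / (n - 3 - 2)
  expect_lt(abs(mean(fs) - mu), 3 * stats::sd(fs) / sqrt(300))
})

test_that("incremental R2 and the F identity agree", {
  set.seed(45)
  df <- data.frame(y = rnorm(200), x = rnorm(200), z = rnorm(200),
                   w = rnorm(200))
  red <- fit_linear(y ~ x, df)
  ful <- fit_linear(y ~ x + z + w, df)
  dr2 <- incremental_r2(red, ful)
  expect_equal(dr2, ful$r_squared - red$r_squared, tolerance = 1e-12)
  expect_equal(incremental_r2(red, red), 0)

  # F = (dR2/q) / ((1-R2_full)/(n-p_f)) within 1e-9
  fres <- nested_f_test(red, ful)
  lhs <- fres$F
  rhs <- (dr2 / fres$df1) / ((1 - ful$r_squared) / fres$df2)
  expect_equal(lhs, rhs, tolerance = 1e-9)

  # sequential attribution over a nested list
  mid <- fit_linear(y ~ x + z, df)
  steps <- incremental_r2(list(red, mid, ful))
  expect_equal(sum(steps$delta_r2), ful$r_squared - red$r_squared,
               tolerance = 1e-12)

  # adding a centered constant-like column changes nothing
  df$c0 <- 0
  expect_error(fit_linear(y ~ x + c0, df), "collinear")
})

test_that("planted variance fractions are recovered as incremental R2", {
  set.seed(46)
  dr2 <- replicate(50, {
    n <- 2348
    x <- rnorm(n)
    score <- rnorm(n)
    y <- 0.3 * x + sqrt(0.03) * score + rnorm(n, 0, sqrt(1 - 0.09 - 0.03))
    df <- data.frame(y = y, x = x, score = score)
    incremental_r2(fit_linear(y ~ x, df), fit_linear(y ~ x + score, df))
  })
  se <- stats::sd(dr2) / sqrt(50)
  expect_lt(abs(mean(dr2) - 0.03), 3 * se + 0.001)
})

test_that("2x2 chi-square matches both formulas and printed descriptives", {
  # sex-by-nicotine-dependence table: 531/1011 males, 617/1337 females
  nd <- matrix(c(531, 1011 - 531, 617, 1337 - 617), 2, 2, byrow = TRUE)
  res <- pearson_chi2_2x2(nd)
  expect_equal(res$chi2, 9.36, tolerance = 0.005)
  expect_lt(abs(res$p - 0.002), 5e-4)    # printed value rounded to 0.002

  # equal proportions -> 0
  expect_equal(pearson_chi2_2x2(matrix(c(20, 30, 40, 60), 2, 2))$chi2, 0)

  # cross-product formula == sum((O-E)^2/E) oracle and chisq.test
  set.seed(47)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 40) + 1, 2, 2)
    res <- pearson_chi2_2x2(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$chi2, sum((tab - E)^2 / E), tolerance = 1e-9)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-9)
  }
  expect_error(pearson_chi2_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
})
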