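test_that("identical samples give p = 1 under the t test", {
  gc <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)), "continuous")
  expect_equal(gc$test, "t-test")
  expect_equal(gc$p_value, 1.0)
  expect_error(compare_groups(list(a = c(1, 1), b = c(2, 2)), "continuous"),
               class = "gaitbelt_degenerate_input_error")
  expect_error(compare_groups(list(a = 1:3), "continuous"),
               class = "gaitbelt_parameter_error")
})

test_that("three or more groups are compared by one-way ANOVA", {
  set.seed(12)
  gc <- compare_groups(list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 2)),
                       "continuous")
  expect_equal(gc$test, "anova")
  expect_lt(gc$p_value, 0.01)
})

test_that("discrete comparisons switch to Fisher when an expected cell is < 5", {
  # current-smoker counts 6/13 vs 10/93: smallest expected cell is about 2
  smoking <- list(
    sarcopenia = rep(c("current", "other"), c(6, 7)),
    normal = rep(c("current", "other"), c(10, 83)))
  gc <- compare_groups(smoking, "discrete")
  expect_equal(gc$test, "Fisher")
  expect_equal(unname(gc$counts), c(13, 93))

  big <- list(a = rep(c("x", "y"), c(40, 60)), b = rep(c("x", "y"), c(60, 40)))
  expect_equal(compare_groups(big, "discrete")$test, "chi-square")
})

test_that("the two-group t test is well powered at a one-SD mean shift", {
  set.seed(14)
  rejections <- 0L
  for (rep in 1:200) {
    gc <- compare_groups(list(a = rnorm(200, 0, 1), b = rnorm(200, 1, 1)),
                         "continuous")
    if (gc$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections, 198L)
})

test_that("correlation matrix reproduces exact linear relations", {
  x <- 1:20
  cm <- correlation_matrix(data.frame(x = x, y = 2 * x + 1, z = -x))
  expect_equal(unname(cm$r["x", "y"]), 1.0)
  expect_equal(unname(cm$r["x", "z"]), -1.0)
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_identical(cm$r, t(cm$r))
  expect_error(correlation_matrix(data.frame(x = x, k = rep(2, 20))),
               "constant", class = "gaitbelt_undefined_correlation_error")
})

test_that("correlation r and p agree with cor.test on pairwise-complete data", {
  set.seed(15)
  df <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  df$b[c(3, 10)] <- NA
  cm <- correlation_matrix(df)
  ok <- !is.na(df$b)
  ct <- cor.test(df$a[ok], df$b[ok])
  expect_equal(unname(cm$r["a", "b"]), unname(ct$estimate))
  expect_equal(unname(cm$p["a", "b"]), ct$p.value)
  expect_equal(unname(cm$n["a", "b"]), 48)
})

test_that("correlations are invariant under positive affine column transforms", {
  set.seed(16)
  df <- data.frame(a = rnorm(40), b = rnorm(40))
  cm1 <- correlation_matrix(df)
  cm2 <- correlation_matrix(data.frame(a = 3 * df$a + 7, b = df$b / 5 - 1))
  expect_equal(cm1$r, cm2$r, tolerance = 1e-12)
})

test_that("sampling variability of r at rho = 0.5, n = 106 stays in the Fisher-z band", {
  set.seed(17)
  inside <- 0L
  for (rep in 1:50) {
    z <- rnorm(106)
    x <- z
    y <- 0.5 * z + sqrt(1 - 0.25) * rnorm(106)
    r <- correlation_matrix(data.frame(x = x, y = y))$r["x", "y"]
    if (r >= 0.33 && r <= 0.64) inside <- inside + 1L
  }
  expect_gte(inside, 45L)
})

test_that("orthogonal predictors have unit VIF and noiseless fits are exact", {
  n <- 32
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)
  y <- 2 + 3 * x1 - 0.5 * x2
  fit <- suppressWarnings(   # lm warns about the (intended) perfect fit
    fit_linear_model(data.frame(y = y, x1 = x1, x2 = x2), "y", c("x1", "x2")))
  expect_equal(fit$coefficients$vif, c(1, 1))
  expect_equal(fit$coefficients$B, c(3, -0.5), tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("standardized betas and VIFs match brute-force and car reference", {
  set.seed(18)
  n <- 120
  z1 <- rnorm(n); z2 <- rnorm(n); z3 <- rnorm(n)
  d <- data.frame(x1 = z1, x2 = 0.6 * z1 + 0.8 * z2, x3 = z3)
  d$y <- 1 + 0.5 * d$x1 - 0.3 * d$x2 + 0.2 * d$x3 + rnorm(n, 0, 0.5)
  fit <- fit_linear_model(d, "y", c("x1", "x2", "x3"))

  # beta equals the slope from the z-scored regression
  zfit <- lm(scale(y) ~ scale(x1) + scale(x2) + scale(x3), data = d)
  expect_equal(fit$coefficients$beta, unname(coef(zfit)[-1]), tolerance = 1e-10)
  # VIF formula equals refitting each auxiliary regression (car reference)
  ref <- unname(car::vif(lm(y ~ x1 + x2 + x3, data = d)))
  expect_equal(fit$coefficients$vif, ref, tolerance = 1e-10)
  expect_true(all(fit$coefficients$vif >= 1))
  expect_identical(sign(fit$coefficients$beta), sign(fit$coefficients$B))
})

test_that("predictors correlated at exactly 0.9 have VIF 1/(1-0.81)", {
  set.seed(19)
  n <- 200
  z1 <- as.numeric(scale(rnorm(n)))
  z2 <- rnorm(n)
  z2 <- as.numeric(scale(lm(z2 ~ z1)$residuals))   # empirically orthogonal
  x1 <- z1
  x2 <- 0.9 * z1 + sqrt(1 - 0.81) * z2             # sample cor exactly 0.9
  d <- data.frame(x1 = x1, x2 = x2)
  d$y <- x1 + x2 + rnorm(n)
  fit <- fit_linear_model(d, "y", c("x1", "x2"))
  expect_equal(fit$coefficients$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-8)
  expect_true(all(fit$coefficients$vif > 5))
})

test_that("degenerate designs are rejected", {
  d <- data.frame(y = rnorm(10), x1 = 1:10, x2 = 2 * (1:10), k = rep(1, 10))
  expect_error(fit_linear_model(d, "y", c("x1", "x2")),
               class = "gaitbelt_singular_design_error")
  expect_error(fit_linear_model(d, "y", c("x1", "k")),
               class = "gaitbelt_singular_design_error")
  expect_error(fit_linear_model(d[1:3, ], "y", c("x1", "x2")),
               class = "gaitbelt_parameter_error")
})
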