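test_that("G and Pearson statistics vanish exactly on independence tables", {
  prop <- matrix(c(10, 20, 20, 40), 2, byrow = TRUE)
  expect_equal(lr_chi_square(prop)$statistic, 0)
  expect_equal(pearson_chi_square(prop)$statistic, 0)
  expect_equal(lr_chi_square(prop)$p.value, 1)
  # nonnegativity on random tables
  set.seed(2)
  for (i in 1:20) {
    m <- matrix(rpois(4, 30) + 1, 2)
    expect_gte(lr_chi_square(m)$statistic, 0)
    expect_gte(pearson_chi_square(m)$statistic, 0)
  }
})

test_that("Pearson statistic matches chisq.test without correction", {
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(rpois(6, 40) + 1, 2, 3)
    ours <- pearson_chi_square(m)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p.value, ref$p.value)
  }
  # Yates-corrected variant against the base oracle on a 2x2
  m <- matrix(c(12, 5, 7, 19), 2)
  expect_equal(pearson_chi_square(m, correct = TRUE)$statistic,
               unname(chisq.test(m, correct = TRUE)$statistic))
})

test_that("G approaches Pearson on large balanced tables", {
  set.seed(9)
  for (i in 1:50) {
    p <- runif(1, 0.35, 0.65)
    m <- rbind(c(rbinom(1, 4000, p)), c(rbinom(1, 4000, p + 0.02)))
    m <- cbind(m, 4000 - m)
    g <- lr_chi_square(m)$statistic
    x2 <- pearson_chi_square(m)$statistic
    if (x2 > 1) expect_lt(abs(g - x2) / x2, 0.05)
  }
})

test_that("degenerate tables are rejected", {
  expect_error(lr_chi_square(matrix(c(0, 0, 5, 3), 2, byrow = TRUE)),
               "degenerate")
  expect_error(pearson_chi_square(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  expect_error(lr_chi_square(matrix(1:3, 3, 1)), "2 x 2")
})

test_that("compare_rates builds the 2x2 table and dispatches methods", {
  # equal rates -> statistic 0
  expect_equal(compare_rates(30, 60, 15, 30)$statistic, 0)
  r <- compare_rates(52, 90, 123, 142, method = "lr")
  expect_equal(r$rate_a, 100 * 52 / 90)
  expect_equal(r$statistic,
               lr_chi_square(rbind(c(52, 38), c(123, 19)))$statistic)
  expect_error(compare_rates(10, 5, 1, 2), "k <= n")
})

test_that("WLS with unit weights reduces exactly to OLS", {
  set.seed(21)
  x <- runif(60, 0, 10)
  y <- 1.5 * x - 2 + rnorm(60, 0, 0.7)
  ours <- wls_fit(y, data.frame(x = x), weight_scheme = "unit")
  ref <- lm(y ~ x)
  expect_equal(ours$coefficients$b, unname(coef(ref)))
  expect_equal(ours$coefficients$se,
               unname(summary(ref)$coefficients[, 2]))
  expect_equal(ours$r.squared, summary(ref)$r.squared)
  # standardized beta of a simple regression equals the correlation
  expect_equal(ours$coefficients$beta[2], cor(x, y))
  # exact linear data -> R = 1, zero residuals (summary.lm warns about
  # the perfect fit; the coefficients are what we assert on)
  exact <- suppressWarnings(
    wls_fit(1.5 * x - 2, data.frame(x = x), weight_scheme = "unit"))
  expect_equal(exact$R, 1)
  expect_lt(max(abs(residuals(exact$lm))), 1e-10)
})

test_that("WLS coefficients are invariant to a constant weight rescale", {
  set.seed(22)
  x <- runif(50, 0, 5)
  y <- 2 * x + rnorm(50, 0, x + 0.5)
  w <- 1 / (x + 0.5)^2
  f1 <- wls_fit(y, data.frame(x = x), weights = w)
  f2 <- wls_fit(y, data.frame(x = x), weights = 1000 * w)
  expect_equal(f1$coefficients$b, f2$coefficients$b)
  expect_equal(f1$coefficients$beta, f2$coefficients$beta)
  expect_equal(f1$R, f2$R)
})

test_that("variance-function weights improve on OLS under heteroscedasticity", {
  set.seed(23)
  x <- runif(400, 1, 10)
  y <- 0.7 * x + rnorm(400, 0, 0.15 * x)
  f <- wls_fit(y, data.frame(x = x))          # two-pass default
  expect_true(all(f$weights > 0))
  # low-mean observations get more weight than high-mean ones
  expect_gt(mean(f$weights[x < 3]), mean(f$weights[x > 8]))
  ci <- wls_confint(f, "x")
  expect_gt(0.7, ci["lower"]); expect_lt(0.7, ci["upper"])
  expect_error(wls_fit(y, data.frame(a = x, b = 2 * x)), "rank-deficient")
})

test_that("Mann-Whitney matches wilcox.test and is antisymmetric", {
  set.seed(31)
  a <- rnorm(25, 1); b <- rnorm(30, 1.4)
  ours <- mann_whitney(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  # antisymmetry: swapping groups flips Z
  expect_equal(mann_whitney(b, a)$Z, -ours$Z)
  # identical groups -> Z ~ 0, p ~ 1
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$Z, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1)
  # ties handled via midranks + tie correction
  x <- c(1, 1, 2, 2, 3); y <- c(2, 3, 3, 4)
  reft <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(mann_whitney(x, y)$p.value, reft$p.value, tolerance = 1e-10)
})

test_that("complete separation gives the maximal |Z| for the sample sizes", {
  a <- 1:10; b <- 101:110
  z_sep <- abs(mann_whitney(a, b)$Z)
  set.seed(32)
  for (i in 1:20) {
    mix <- sample(20)
    z <- abs(mann_whitney(mix[1:10], mix[11:20])$Z)
    expect_lte(z, z_sep + 1e-12)
  }
})

test_that("group summaries report median and IQR with interpolated quartiles", {
  x <- c(1, 2, 3, 10)
  s <- mann_whitney(x, c(5, 6))$summary
  expect_equal(s$median[1], median(x))
  expect_equal(s$IQR[1], unname(diff(quantile(x, c(0.25, 0.75)))))
  expect_equal(s$min[1], 1); expect_equal(s$max[1], 10)
  expect_equal(format_p(1e-9), "0.000")
  expect_equal(format_p(0.0225), "0.022")
})
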