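#' @title Statistical comparison machinery
#' @description
#' Chi-square tests on contingency tables (likelihood-ratio G statistic
#' by default, Pearson with optional Yates correction as alternatives),
#' rate comparisons, weighted least-squares regression with
#' standardized coefficients, and the Mann-Whitney U test with a
#' tie-corrected normal-approximation Z.
#' @name compare
NULL

.check_contingency <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) {
    stop("contingency table must hold non-negative integer counts")
  }
  if (nrow(m) < 2L || ncol(m) < 2L) stop("table must be at least 2 x 2")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: a zero row or column marginal")
  }
  m
}

.expected_counts <- function(m) outer(rowSums(m), colSums(m)) / sum(m)

#' Likelihood-ratio chi-square (G) test of independence
#'
#' `G = 2 * sum(O * log(O / E))` over the cells, with expected counts
#' from the independence model; zero-count cells contribute 0. `G` is
#' asymptotically chi-square with `(r - 1)(k - 1)` degrees of freedom.
#'
#' @param table an r x k matrix/table of non-negative integer counts
#'   with positive marginals.
#' @return a list with `statistic`, `df`, `p.value`, `method` and
#'   `expected`.
#' @export
lr_chi_square <- function(table) {
  m <- .check_contingency(table)
  e <- .expected_counts(m)
  nz <- m > 0
  g <- 2 * sum(m[nz] * log(m[nz] / e[nz]))
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(statistic = g, df = df,
       p.value = stats::pchisq(g, df, lower.tail = FALSE),
       method = "likelihood-ratio chi-square", expected = e)
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum((O - E)^2 / E)`, optionally with the Yates continuity
#' correction on 2 x 2 tables.
#'
#' @inheritParams lr_chi_square
#' @param correct apply the Yates continuity correction (2 x 2 only).
#' @return a list with `statistic`, `df`, `p.value`, `method` and
#'   `expected`.
#' @export
pearson_chi_square <- function(table, correct = FALSE) {
  m <- .check_contingency(table)
  e <- .expected_counts(m)
  dev <- abs(m - e)
  if (correct) {
    if (!all(dim(m) == 2L)) stop("Yates correction applies to 2 x 2 tables")
    dev <- pmax(dev - 0.5, 0)
  }
  x2 <- sum(dev^2 / e)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(statistic = x2, df = df,
       p.value = stats::pchisq(x2, df, lower.tail = FALSE),
       method = if (correct) "Pearson chi-square (Yates)" else "Pearson chi-square",
       expected = e)
}

#' Chi-square test with selectable flavor
#'
#' @inheritParams lr_chi_square
#' @param method `"lr"` (likelihood-ratio G, the default), `"pearson"`,
#'   or `"yates"` (Pearson with continuity correction).
#' @export
chi_square_test <- function(table, method = c("lr", "pearson", "yates")) {
  method <- match.arg(method)
  switch(method,
         lr = lr_chi_square(table),
         pearson = pearson_chi_square(table, correct = FALSE),
         yates = pearson_chi_square(table, correct = TRUE))
}

#' Compare two success rates via a 2 x 2 chi-square test
#'
#' Builds the 2 x 2 success/failure table from the two counts and
#' dispatches to [chi_square_test()].
#'
#' @param k_a,n_a successes and trials in the first sample.
#' @param k_b,n_b successes and trials in the second sample.
#' @param method chi-square flavor; see [chi_square_test()].
#' @return the test list, plus `rate_a` and `rate_b` in percent.
#' @export
compare_rates <- function(k_a, n_a, k_b, n_b, method = "lr") {
  if (k_a > n_a || k_b > n_b || min(k_a, k_b, n_a, n_b) < 0) {
    stop("need 0 <= k <= n in both samples")
  }
  tab <- rbind(c(k_a, n_a - k_a), c(k_b, n_b - k_b))
  res <- chi_square_test(tab, method)
  res$rate_a <- 100 * k_a / n_a
  res$rate_b <- 100 * k_b / n_b
  res
}

# compare_rates that degrades gracefully on degenerate tables (an empty
# stratum, or both rates at 0% or 100%): reports the rates with an NA
# statistic instead of failing a whole pipeline run
.safe_compare_rates <- function(k_a, n_a, k_b, n_b, method = "lr") {
  tryCatch(compare_rates(k_a, n_a, k_b, n_b, method),
           error = function(e) {
             list(statistic = NA_real_, df = NA_integer_,
                  p.value = NA_real_, method = conditionMessage(e),
                  rate_a = if (n_a > 0) 100 * k_a / n_a else NA_real_,
                  rate_b = if (n_b > 0) 100 * k_b / n_b else NA_real_)
           })
}

# ---- weighted least squares ----------------------------------------------

# Two-pass variance-function weights: fit OLS, regress log squared
# residuals on log |fitted|, and weight by the inverse fitted variance.
# Standard remedy for count-derived outcomes whose spread grows with the
# mean, as uptake data do.
.variance_function_weights <- function(y, X) {
  fit0 <- stats::lm.fit(cbind(1, X), y)
  r2 <- fit0$residuals^2
  eps <- .Machine$double.eps
  lf <- log(pmax(abs(fit0$fitted.values), eps))
  lr <- log(pmax(r2, eps))
  vf <- stats::lm.fit(cbind(1, lf), lr)
  pred <- cbind(1, lf) %*% vf$coefficients
  w <- as.numeric(exp(-pred))
  w / mean(w)
}

#' Weighted least-squares linear fit with standardized coefficients
#'
#' Fits `y ~ X` by weighted least squares and reports, per predictor,
#' the raw slope `b`, its standard error, the standardized coefficient
#' `beta = b * sd_w(x) / sd_w(y)` (weighted SDs under the fitting
#' weights), `t` and `p`; and for the model the multiple correlation
#' `R`, `R^2`, adjusted `R^2` and the ANOVA `F`. With unit weights the
#' fit reduces exactly to ordinary least squares.
#'
#' @param y numeric outcome vector.
#' @param X predictors: a numeric vector, matrix or data frame (one
#'   column per predictor).
#' @param weights per-observation non-negative weights, or `NULL` to
#'   use `weight_scheme`.
#' @param weight_scheme how to choose weights when none are supplied:
#'   `"variance-function"` (two-pass inverse-variance weights estimated
#'   from the OLS residuals, the default) or `"unit"`.
#' @return an object of class `wls_fit`: `coefficients` data frame
#'   (term, b, se, beta, t, p), `R`, `r.squared`, `adj.r.squared`, `F`,
#'   `df`, `p.value`, `weights`, and the underlying `lm` object.
#' @export
wls_fit <- function(y, X, weights = NULL,
                    weight_scheme = c("variance-function", "unit")) {
  weight_scheme <- match.arg(weight_scheme)
  X <- as.matrix(as.data.frame(X))
  if (!is.numeric(X)) stop("predictors must be numeric")
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("y and X sizes disagree")
  if (n <= p + 1L) stop("need n > number of predictors + 1")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (is.null(weights)) {
    weights <- switch(weight_scheme,
                      "variance-function" = .variance_function_weights(y, X),
                      unit = rep(1, n))
  }
  if (length(weights) != n || any(weights < 0) || all(weights == 0)) {
    stop("weights must be non-negative, not all zero, one per observation")
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", colnames(X)), response = ".y")
  fit <- stats::lm(fml, data = dat, weights = weights)
  if (fit$rank < p + 1L) stop("rank-deficient design matrix")
  sm <- summary(fit)
  co <- sm$coefficients
  wsd <- function(v) {
    mw <- stats::weighted.mean(v, weights)
    sqrt(sum(weights * (v - mw)^2) / sum(weights))
  }
  sd_ratio <- vapply(colnames(X), function(j) wsd(X[, j]) / wsd(y), numeric(1))
  beta <- c(NA_real_, unname(co[-1, 1]) * sd_ratio)
  fstat <- sm$fstatistic
  structure(list(
    coefficients = data.frame(
      term = c("(intercept)", colnames(X)),
      b = unname(co[, 1]), se = unname(co[, 2]),
      beta = unname(beta), t = unname(co[, 3]), p = unname(co[, 4]),
      row.names = NULL),
    R = sqrt(sm$r.squared),
    r.squared = sm$r.squared,
    adj.r.squared = sm$adj.r.squared,
    F = unname(fstat[1]), df = unname(fstat[2:3]),
    p.value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    weights = weights, lm = fit
  ), class = "wls_fit")
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf("weighted least-squares fit: R = %.3f, adj R^2 = %.3f, F = %.4g (p = %.3g)\n",
              x$R, x$adj.r.squared, x$F, x$p.value))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Confidence interval for a wls_fit slope
#' @param fit a [wls_fit()] object.
#' @param term predictor name (as in `fit$coefficients$term`).
#' @param level confidence level.
#' @return lower/upper bounds for the raw slope `b`.
#' @export
wls_confint <- function(fit, term, level = 0.95) {
  stopifnot(inherits(fit, "wls_fit"))
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("unknown term: ", term)
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df[2])
  b <- fit$coefficients$b[i]
  se <- fit$coefficients$se[i]
  c(lower = b - tq * se, upper = b + tq * se)
}

# ---- Mann-Whitney ---------------------------------------------------------

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Computes the U statistic from midranks, the tie-corrected
#' normal-approximation `Z = (U - n1 n2 / 2) / sigma_U` (no continuity
#' correction) and the two-sided p-value, plus the per-group summaries
#' reported as median +/- IQR (`M +/- IQR`, linear-interpolation
#' quartiles).
#'
#' @param group_a,group_b numeric samples (non-empty).
#' @return an object of class `group_comparison`: `summary` data frame
#'   (group, n, median, IQR, min, max), `U`, `Z`, `p.value`.
#' @export
mann_whitney <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))                    # midranks for ties
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- if (sigma2 > 0) (u1 - mu) / sqrt(sigma2) else 0
  p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
  summ <- function(x, g) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(group = g, n = length(x), median = q[2], IQR = q[3] - q[1],
               min = min(x), max = max(x))
  }
  structure(list(summary = rbind(summ(a, "a"), summ(b, "b")),
                 U = u1, Z = z, p.value = p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %.4g, Z = %.2f, p = %s\n",
              x$U, x$Z, format_p(x$p.value)))
  s <- x$summary
  s$`M+/-IQR` <- sprintf("%.2f+/-%.2f", s$median, s$IQR)
  print(s, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Format a p-value with a 3-decimal floor display
#'
#' Mirrors the tabular convention of reporting very small p-values as
#' `"0.000"`.
#'
#' @param p p-value(s).
#' @param digits decimals to show.
#' @export
format_p <- function(p, digits = 3) {
  formatC(round(p, digits), format = "f", digits = digits)
}
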