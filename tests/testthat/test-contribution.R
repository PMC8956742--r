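rand_design <- function(n = 60, k = 4, seed = 1, coef = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("X", 1:k)))
  if (is.null(coef)) coef <- rnorm(k)
  y <- 2 + X %*% coef + rnorm(n)
  regression_design(as.vector(y), X)
}

test_that("the full-model regression sum of squares behaves at the extremes", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3)
  y <- 1 + X %*% c(2, -1, 0.5)             # exact linear response
  d <- regression_design(as.vector(y), X)
  f <- fit_ols(d)
  expect_equal(f$U, sum((y - mean(y))^2), tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  d0 <- regression_design(rep(3, 20), X)   # constant response
  f0 <- fit_ols(d0)
  expect_equal(f0$U, 0, tolerance = 1e-20)
  expect_equal(unname(f0$coefficients[-1]), rep(0, 3), tolerance = 1e-12)
})

test_that("coefficients match the normal equations", {
  d <- rand_design(n = 50, k = 5, seed = 2)
  f <- fit_ols(d)
  A <- cbind(1, d$X)
  ref <- solve(t(A) %*% A, t(A) %*% d$y)
  expect_equal(unname(f$coefficients), as.vector(ref), tolerance = 1e-8)
})

test_that("exactly collinear designs are rejected", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  X <- cbind(X, X[, 1] + X[, 2])
  d <- regression_design(rnorm(20), X)
  expect_error(fit_ols(d), "collinear")
})

test_that("published partial sums give the published contribution rates", {
  # first-year block: P for (X1..X5), printed S, printed full-model U
  P <- c(X1 = 0.06357, X2 = 0.00856, X3 = 0.00002, X4 = 0.13735,
         X5 = 0.00038)
  S <- 100 * P / sum(P)
  expect_equal(round(unname(S), 2), c(30.29, 4.08, 0.01, 65.44, 0.18))
  expect_equal(sum(P), 0.20988, tolerance = 1e-12)
})

test_that("partial contributions are non-negative and sum to 100 percent", {
  for (seed in 1:5) {
    d <- rand_design(n = 40 + 5 * seed, k = 4, seed = seed)
    ct <- partial_contributions(d)
    expect_true(all(ct$table$P >= 0))
    expect_equal(sum(ct$table$S_pct), 100, tolerance = 1e-9)
    full <- fit_ols(d)
    expect_true(all(ct$table$U_reduced <= full$U + 1e-10))
  }
})

test_that("contribution rates are invariant to rescaling y or any predictor", {
  d <- rand_design(n = 45, k = 3, seed = 6)
  base <- partial_contributions(d)$table$S_pct
  d2 <- d; d2$y <- 7 * d$y
  expect_equal(partial_contributions(d2)$table$S_pct, base, tolerance = 1e-8)
  d3 <- d; d3$X[, 2] <- 100 * d$X[, 2]
  expect_equal(partial_contributions(d3)$table$S_pct, base, tolerance = 1e-8)
})

test_that("the single informative predictor takes all the contribution", {
  set.seed(7)
  n <- 4000
  X <- matrix(rnorm(n * 4), n, 4)
  y <- 3 * X[, 2] + rnorm(n, 0, 0.5)
  ct <- partial_contributions(regression_design(y, X))
  expect_gt(ct$table$S_pct[2], 99)
})

test_that("orthogonal predictors split contribution by squared slope", {
  set.seed(8)
  M <- scale(matrix(rnorm(200 * 2), 200, 2), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))  # orthonormal columns spanning a mean-centered space
  b <- c(2, 0.7)
  y <- Q %*% b                                   # noise-free for the closed form
  ct <- partial_contributions(regression_design(as.vector(y), Q))
  # with orthonormal centered-ish predictors, P_i = b_i^2 * sum(x_i^2)
  expect_equal(ct$table$S_pct[1] / ct$table$S_pct[2], (b[1] / b[2])^2,
               tolerance = 1e-6)
})

test_that("univariate fits report slopes and correlation limits", {
  x <- 1:20
  d <- regression_design(2 * x + 3, cbind(up = x, down = -x, noise = rnorm(20)))
  sr <- simple_regressions(d)
  expect_equal(sr$r[sr$predictor == "up"], 1, tolerance = 1e-12)
  expect_equal(sr$r[sr$predictor == "down"], -1, tolerance = 1e-12)
  expect_equal(sr$slope[sr$predictor == "up"], 2, tolerance = 1e-12)
  expect_equal(sr$intercept[sr$predictor == "up"], 3, tolerance = 1e-10)

  set.seed(9)
  n <- 5000
  d2 <- regression_design(rnorm(n), cbind(a = rnorm(n), b = rnorm(n)))
  sr2 <- simple_regressions(d2)
  expect_true(all(abs(sr2$r) < 3 / sqrt(n)))

  d3 <- regression_design(rnorm(20), cbind(flat = rep(1, 20), x = rnorm(20)))
  expect_warning(sr3 <- simple_regressions(d3), "zero variance")
  expect_equal(sr3$predictor, "x")
})

test_that("designs enforce completeness and minimum size", {
  expect_error(regression_design(1:3, matrix(rnorm(6), 3, 2)), "k \\+ 2")
  d <- regression_design(c(1, 2, NA, 4:10), matrix(rnorm(20), 10, 2))
  expect_equal(length(d$y), 9)  # incomplete samples dropped
})
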