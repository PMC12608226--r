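test_that("noiseless exponential data are recovered exactly", {
  x <- seq(0, 1, 0.1)
  y <- 2 * exp(3 * x)
  m <- fit_exponential(x, y)
  expect_equal(m$a, 2, tolerance = 1e-9)
  expect_equal(m$b, 3, tolerance = 1e-9)
  met <- evaluate_metrics(m, x, y)
  expect_equal(met$r2, 1, tolerance = 1e-9)
  expect_equal(met$rmse, 0, tolerance = 1e-9)
  expect_equal(met$re_percent, 0, tolerance = 1e-9)
})

test_that("constant response gives a = level, b = 0", {
  x <- seq(0, 1, 0.2)
  m <- fit_exponential(x, rep(5, length(x)))
  expect_equal(m$a, 5)
  expect_equal(m$b, 0)
})

test_that("noisy exponential recovery agrees with a brute-force grid oracle", {
  withr::local_seed(7)
  n <- 200
  x <- runif(n, 0, 1)
  y <- 2 * exp(3 * x) * exp(rnorm(n, 0, 0.05))
  m <- fit_exponential(x, y)
  expect_lt(abs(m$a - 2) / 2, 0.05)
  expect_lt(abs(m$b - 3) / 3, 0.05)
  # independent oracle: exhaustive (a, b) grid minimizing log-space SSE
  grid_a <- seq(1.6, 2.4, by = 0.01)
  grid_b <- seq(2.6, 3.4, by = 0.01)
  sse <- outer(grid_a, grid_b, Vectorize(function(a, b) {
    sum((log(y) - log(a) - b * x)^2)
  }))
  best <- which(sse == min(sse), arr.ind = TRUE)
  expect_lt(abs(m$a - grid_a[best[1]]), 0.011)
  expect_lt(abs(m$b - grid_b[best[2]]), 0.011)
})

test_that("original-space refinement runs and stays close to the log fit", {
  withr::local_seed(17)
  x <- runif(100)
  y <- 4 * exp(2 * x) * exp(rnorm(100, 0, 0.1))
  m0 <- fit_exponential(x, y)
  m1 <- fit_exponential(x, y, refine = TRUE)
  expect_true(m1$refined)
  expect_lt(abs(m1$a - m0$a) / m0$a, 0.1)
  # refinement cannot worsen the original-space RMSE
  expect_lte(evaluate_metrics(m1, x, y)$rmse,
             evaluate_metrics(m0, x, y)$rmse + 1e-9)
})

test_that("hand-computed metrics for a small prediction set", {
  # y=(4,6,10), yhat=(5,5,10): rmse = sqrt(2/3), re = 10%
  m <- structure(list(a = 1, b = 0, n_valid = 3, n_dropped = 0,
                      refined = FALSE), class = "exp_model")
  # craft vi so that predictions are (5,5,10) with a manual model
  m$a <- 1; m$b <- 1
  vi <- log(c(5, 5, 10))
  met <- evaluate_metrics(m, vi, c(4, 6, 10))
  expect_equal(met$rmse, sqrt(2 / 3))
  expect_equal(met$re_percent, mean(c(1, 1, 0)) * 100 / mean(c(4, 6, 10)))
  # a model predicting the constant mean has R2 = 0
  y <- c(4, 6, 10)
  mbar <- structure(list(a = mean(y), b = 0, n_valid = 3, n_dropped = 0,
                         refined = FALSE), class = "exp_model")
  expect_equal(evaluate_metrics(mbar, c(0.1, 0.5, 0.9), y)$r2, 0)
})

test_that("R2 never exceeds 1 and degrades with added noise", {
  withr::local_seed(21)
  x <- runif(60)
  y0 <- 3 * exp(1.5 * x)
  r2s <- vapply(c(0, 0.05, 0.15, 0.4), function(s) {
    y <- y0 * exp(rnorm(60, 0, s))
    m <- fit_exponential(x, y)
    evaluate_metrics(m, x, y)$r2
  }, numeric(1))
  expect_true(all(r2s <= 1))
  expect_true(all(diff(r2s) < 0))
})

test_that("RMSE is scale-equivariant; R2 and RE scale-invariant", {
  withr::local_seed(22)
  x <- runif(50)
  y <- 2 * exp(2 * x) * exp(rnorm(50, 0, 0.1))
  m <- fit_exponential(x, y)
  met <- evaluate_metrics(m, x, y)
  alpha <- 3.7
  m2 <- fit_exponential(x, alpha * y)
  met2 <- evaluate_metrics(m2, x, alpha * y)
  expect_equal(met2$rmse, alpha * met$rmse)
  expect_equal(met2$r2, met$r2)
  expect_equal(met2$re_percent, met$re_percent)
})

test_that("fit quality converges to perfection as noise vanishes", {
  withr::local_seed(23)
  x <- runif(80)
  tol <- list(c(0.05, 0.2), c(0.005, 0.02), c(5e-4, 2e-3))
  for (k in seq_along(tol)) {
    s <- 10^(-k)  # noise sd ladder: 0.1, 0.01, 0.001
    y <- 2 * exp(2 * x) * exp(rnorm(80, 0, s))
    met <- evaluate_metrics(fit_exponential(x, y), x, y)
    expect_gt(met$r2, 1 - tol[[k]][1])
    expect_lt(met$rmse, 10 * tol[[k]][2] * mean(y))
  }
})

test_that("invalid pairs are excluded and degenerate inputs rejected", {
  x <- c(NA, 0.1, 0.5, 0.9, 0.3)
  y <- c(5, 6, -1, 8, 7)
  m <- fit_exponential(x, y)
  expect_equal(m$n_valid, 3)
  expect_equal(m$n_dropped, 2)
  expect_error(fit_exponential(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_exponential(rep(0.5, 5), 1:5), "variance")
  expect_warning(evaluate_metrics(m, c(0.1, 0.5, 0.9), rep(2, 3)),
                 "zero variance")
})

test_that("literal metric variants differ from standard ones by design", {
  withr::local_seed(24)
  x <- runif(30)
  y <- 2 * exp(2 * x) * exp(rnorm(30, 0, 0.2))
  m <- fit_exponential(x, y)
  std <- evaluate_metrics(m, x, y)
  lit <- evaluate_metrics(m, x, y, literal = TRUE)
  expect_false(isTRUE(all.equal(std$r2, lit$r2)))
  expect_false(isTRUE(all.equal(std$rmse, lit$rmse)))
  expect_equal(std$re_percent, lit$re_percent)  # RE shared
})
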