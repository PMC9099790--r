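test_that("error reduction ratio is the squared cosine and scale invariant", {
  expect_equal(err_ratio(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(err_ratio(c(1, 0), c(0, 1)), 0)
  expect_equal(err_ratio(c(1, 2), c(1, 0)), 0.2)
  set.seed(7)
  y <- rnorm(20); p <- rnorm(20)
  expect_equal(err_ratio(3.7 * y, p), err_ratio(y, p))
  expect_equal(err_ratio(y, 0.004 * p), err_ratio(y, p))
  expect_error(err_ratio(y, rep(0, 20)), class = "corrqsar_division_by_zero")
})

test_that("weight estimation solves least squares and flags rank deficiency", {
  expect_equal(estimate_weights(diag(3), c(4, 5, 6)), c(4, 5, 6))
  z <- c(1, 2, 3)
  expect_equal(estimate_weights(cbind(z), 2 * z), 2)
  expect_equal(estimate_weights(cbind(1, 0:2), c(1, 2, 3)), c(1, 1))
  # residual orthogonal to columns
  set.seed(3)
  Z <- matrix(rnorm(60), 20); y <- rnorm(20)
  b <- estimate_weights(Z, y)
  expect_lt(max(abs(crossprod(Z, y - Z %*% b))), 1e-10)
  expect_error(estimate_weights(cbind(z, 2 * z), y[1:3]),
               class = "corrqsar_rank_deficient")
})

test_that("an exactly representable response is found at step one", {
  sys <- make_linear_system(30, 6, support = 3, weights = 1, seed = 11)
  m <- frols_select(list(X = sys$X, y = sys$X[, 3]))
  expect_equal(m$terms, 3L)
  expect_equal(m$err_per_term, 1, tolerance = 1e-12)
  expect_lt(m$esr, 1e-12)
  expect_equal(m$stop_rule, "esr")
})

test_that("noiseless sparse systems are recovered exactly and match the subset oracle", {
  for (seed in 1:5) {
    sys <- make_linear_system(40, 10, support = c(2, 5),
                              weights = c(3, 0.5), seed = seed)
    m <- frols_select(sys, rho = 0.005)
    expect_setequal(m$terms, c(2L, 5L))
    expect_lt(m$esr, 1e-10)
    expect_equal(unname(coef(m)[order(m$terms)]), c(3, 0.5), tolerance = 1e-8)
    oracle <- best_subset(sys$X, sys$y, 2)
    expect_setequal(m$terms, oracle$subset)
  }
})

test_that("with rho = 0 and no gain threshold the full model equals ordinary least squares", {
  sys <- make_linear_system(6, 3, support = c(1, 2), weights = c(2, -1),
                            noise_sd = 0.3, seed = 9)
  m <- frols_select(sys, rho = 0, max_terms = 3, min_gain = 0)
  expect_length(m$terms, 3)
  ols <- qr.solve(sys$X, sys$y)
  expect_equal(unname(coef(m))[order(m$terms)], unname(ols), tolerance = 1e-8)
})

test_that("greedy selection matches exhaustive best subsets on orthogonal designs", {
  set.seed(21)
  Q <- qr.Q(qr(matrix(rnorm(30 * 5), 30)))   # orthonormal columns
  y <- drop(Q %*% c(5, 0.2, -3, 0.05, 1)) + rnorm(30, 0, 0.1)
  for (k in 1:4) {
    m <- frols_select(list(X = Q, y = y), rho = 0, max_terms = k, min_gain = 0)
    oracle <- best_subset(Q, y, k)
    rss <- sum((y - Q[, m$terms, drop = FALSE] %*% m$weights)^2)
    expect_equal(rss, oracle$rss, tolerance = 1e-10)
    expect_setequal(m$terms, oracle$subset)
  }
})

test_that("ERR bookkeeping: SERR bounded by one, ESR non-increasing", {
  sys <- make_linear_system(50, 8, support = c(1, 4, 7),
                            weights = c(2, -3, 1), noise_sd = 1, seed = 13)
  m <- frols_select(sys, rho = 0, max_terms = 8, min_gain = 0)
  expect_true(all(m$err_per_term >= 0 & m$err_per_term <= 1))
  expect_lte(m$serr, 1 + 1e-10)
  esr_path <- 1 - cumsum(m$err_per_term)
  expect_true(all(diff(esr_path) <= 1e-12))
})

test_that("ties break to the lowest index and collinear candidates are skipped", {
  set.seed(5)
  x <- rnorm(25)
  X <- cbind(x, rnorm(25), x)    # column 3 duplicates column 1
  y <- 2 * x + rnorm(25, 0, 0.2) # noise keeps selection going past step 1
  expect_warning(m <- frols_select(list(X = X, y = y), rho = 0,
                                   max_terms = 3, min_gain = 0),
                 "collinear")
  expect_equal(m$terms[1], 1L)         # tie with column 3 goes to index 1
  expect_true(3L %in% m$skipped)
  expect_setequal(m$terms, c(1L, 2L))
})

test_that("empty dictionaries and degenerate responses are rejected", {
  expect_error(frols_select(list(X = matrix(numeric(0), 0, 0), y = numeric(0))),
               class = "corrqsar_empty_dictionary")
  expect_error(frols_select(list(X = matrix(1, 3, 1), y = rep(0, 3))),
               class = "corrqsar_division_by_zero")
})

test_that("model serialization round-trips weights bit-exactly", {
  sys <- make_linear_system(40, 10, support = c(2, 5), weights = c(3, 0.5),
                            noise_sd = 0.5, seed = 2)
  m <- frols_select(sys, rho = 0, max_terms = 4, min_gain = 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_frols(m, path)
  m2 <- read_frols(path)
  expect_identical(m2$weights, m$weights)
  expect_identical(m2$terms, m$terms)
  expect_equal(m2$err_per_term, m$err_per_term)
  expect_equal(predict(m2, sys$X), predict(m, sys$X))
})

test_that("prediction is the plain dot product over selected terms", {
  sys <- make_linear_system(20, 5, support = 2, weights = 4, seed = 8)
  m <- frols_select(sys, rho = 0.005)
  new <- matrix(0, 2, 5, dimnames = list(NULL, paste0("x", 1:5)))
  expect_equal(predict(m, new), c(0, 0))   # no intercept
  expect_error(predict(m, new[, -2, drop = FALSE]),
               class = "corrqsar_unknown_label")
})
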