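test_that("PLS recovers exact low-rank linear relations", {
  set.seed(31)
  Tt <- matrix(rnorm(40 * 5), 40)
  X <- Tt %*% matrix(rnorm(5 * 30), 5)
  y <- as.numeric(Tt %*% rnorm(5))
  fit <- pls_fit(X, y, n_components = 5)
  expect_gte(evaluate(y, predict(fit, X))$r2, 0.999)
  expect_true(all(is.finite(predict(fit, X))))
  fit2 <- pls_fit(X, y, n_components = 5)
  expect_identical(predict(fit, X), predict(fit2, X))
  expect_error(pls_fit(matrix(1, 10, 4), rnorm(10)), "degenerate")
})

test_that("linear SVR fits linear data and behaves affinely", {
  set.seed(32)
  X <- matrix(rnorm(40 * 10), 40)
  y <- 2 * X[, 3] + 1
  fit <- svr_fit(X, y, C = 100, epsilon = 0.01)
  Xnew <- matrix(rnorm(20 * 10), 20)
  expect_gte(evaluate(2 * Xnew[, 3] + 1, predict(fit, Xnew))$r2, 0.99)
  # duplicate training rows leave predictions (nearly) unchanged
  fit_dup <- svr_fit(rbind(X, X), c(y, y), C = 100, epsilon = 0.01)
  expect_equal(predict(fit_dup, Xnew), predict(fit, Xnew), tolerance = 1e-2)
  # affine in the inputs: midpoint prediction = mean of predictions
  x1 <- Xnew[1, , drop = FALSE]; x2 <- Xnew[2, , drop = FALSE]
  expect_equal(predict(fit, (x1 + x2) / 2),
               mean(predict(fit, rbind(x1, x2))), tolerance = 1e-8)
  expect_warning(svr_fit(X, y, gamma = 0.001), "linear kernel")
})

test_that("DS recovers a known invertible instrument map", {
  set.seed(33)
  L <- 12; n <- 30
  master <- matrix(rnorm(n * L), n)
  Tmap <- diag(L) + 0.1 * matrix(rnorm(L * L), L)
  slave <- master %*% Tmap
  map <- ds_fit(master, slave, ridge = 1e-10)
  expect_lt(max(abs(ds_apply(map, slave) - master)), 1e-6)
  # identity when the instruments agree
  mid <- ds_fit(master, master, ridge = 1e-10)
  expect_lt(max(abs(ds_apply(mid, master) - master)), 1e-8)
  # enormous ridge shrinks the map to the intercept
  mbig <- ds_fit(master, slave, ridge = 1e12)
  expect_lt(max(abs(mbig$F)), 1e-6)
  expect_equal(ds_apply(mbig, slave),
               matrix(rep(colMeans(master), each = n), n), tolerance = 1e-4)
  expect_error(ds_fit(master, slave[-1, ]), "matching rows")
})

test_that("PDS: per-column slopes, full-window equivalence, banded support", {
  set.seed(34)
  master <- matrix(rnorm(20 * 10), 20)
  # window 0 with slave = c * master recovers 1/c per column
  slave <- 2.5 * master
  m0 <- pds_fit(master, slave, window = 0, ridge = 1e-12)
  expect_equal(unname(diag(m0$F)), rep(1 / 2.5, 10), tolerance = 1e-6)
  expect_lt(max(abs(pds_apply(m0, slave) - master)), 1e-6)
  # identity transform
  mi <- pds_fit(master, master, window = 2, ridge = 1e-12)
  expect_lt(max(abs(pds_apply(mi, master) - master)), 1e-8)
  # full window coincides with DS at the same ridge
  slave2 <- master %*% (diag(10) + 0.05 * matrix(rnorm(100), 10))
  pfull <- pds_fit(master, slave2, window = 9, ridge = 1e-8)
  dfull <- ds_fit(master, slave2, ridge = 1e-8)
  expect_lt(max(abs(pds_apply(pfull, slave2) - ds_apply(dfull, slave2))),
            1e-6)
  # band structure: zero outside |i - j| <= window
  m2 <- pds_fit(master, slave2, window = 2, ridge = 1e-6)
  for (j in 1:10) {
    outside <- setdiff(1:10, max(1, j - 2):min(10, j + 2))
    expect_true(all(m2$F[outside, j] == 0))
  }
  expect_error(pds_fit(master, slave2, window = 10), "window")
})

test_that("DS and PDS corrections are linear operators in intercept-free mode", {
  set.seed(35)
  master <- matrix(rnorm(15 * 8), 15)
  slave <- master %*% (diag(8) + 0.2 * matrix(rnorm(64), 8))
  for (map in list(ds_fit(master, slave, center = FALSE),
                   pds_fit(master, slave, window = 3, center = FALSE))) {
    X1 <- matrix(rnorm(4 * 8), 4); X2 <- matrix(rnorm(4 * 8), 4)
    expect_equal(ds_apply(map, 2 * X1 - 3 * X2),
                 2 * ds_apply(map, X1) - 3 * ds_apply(map, X2),
                 tolerance = 1e-10)
  }
})

test_that("SBC inverts a constructed affine prediction bias", {
  y_ref <- c(2, 4, 6, 9, 13)
  yhat_slave <- (y_ref - 1) / 2
  corr <- sbc_fit(y_ref, yhat_slave)
  expect_equal(corr$slope, 2, tolerance = 1e-12)
  expect_equal(corr$bias, 1, tolerance = 1e-12)
  expect_equal(sbc_apply(corr, yhat_slave), y_ref, tolerance = 1e-12)
  cid <- sbc_fit(y_ref, y_ref)
  expect_equal(cid$slope, 1, tolerance = 1e-12)
  expect_equal(cid$bias, 0, tolerance = 1e-10)
  # OLS residual property: zero mean error on the standards, and never a
  # worse in-standard MSE than the uncorrected predictions
  set.seed(36)
  yh <- rnorm(20); yr <- 1.4 * yh - 2 + rnorm(20, 0, 0.1)
  c2 <- sbc_fit(yr, yh)
  expect_equal(mean(yr - sbc_apply(c2, yh)), 0, tolerance = 1e-10)
  expect_lte(mean((yr - sbc_apply(c2, yh))^2), mean((yr - yh)^2))
  expect_error(sbc_fit(c(1, 2, 3), c(5, 5, 5)), "constant")
})
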