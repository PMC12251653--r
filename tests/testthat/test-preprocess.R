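test_that("Kennard-Stone picks maximally spread samples (hand cases)", {
  sp <- kennard_stone_split(matrix(c(0, 1, 10)), 2 / 3)
  expect_setequal(sp$train_indices, c(1, 3))
  expect_equal(sp$test_indices, 2)
  sp4 <- kennard_stone_split(matrix(c(0, 1, 2, 3)), 1 / 2)
  expect_setequal(sp4$train_indices, c(1, 4))
  # all points identical: deterministic lowest-index tie-break, no crash
  spd <- kennard_stone_split(matrix(1, 5, 2), 0.6)
  expect_equal(spd$train_indices, c(1, 2, 3))
})

test_that("Kennard-Stone and SPXY match exhaustive max-min brute force", {
  set.seed(42)
  for (trial in 1:100) {
    n <- sample(4:10, 1)
    X <- matrix(rnorm(n * 3), n)
    frac <- runif(1, 0.35, 0.85)
    n_train <- floor(frac * n + 0.5)
    if (n_train < 2) next
    sp <- kennard_stone_split(X, frac)
    expect_equal(sp$train_indices,
                 ks_brute_force(as.matrix(dist(X)), n_train))
    Y <- matrix(rnorm(n), n)
    DX <- as.matrix(dist(X)); DY <- as.matrix(dist(Y))
    DJ <- DX / max(DX) + DY / max(DY)
    expect_equal(spxy_split(X, Y, frac)$train_indices,
                 ks_brute_force(DJ, n_train))
  }
})

test_that("train sizes follow round-half-up of ratio * n", {
  X80 <- matrix(rnorm(160), 80)
  sp <- kennard_stone_split(X80, 0.8)
  expect_length(sp$train_indices, 64)
  expect_length(sp$test_indices, 16)
  X636 <- matrix(rnorm(636 * 2), 636)
  expect_length(kennard_stone_split(X636, 0.8)$train_indices, 509)
  expect_error(kennard_stone_split(matrix(rnorm(20), 10), 0.05), "fewer")
})

test_that("splitters are deterministic and permutation-covariant", {
  set.seed(7)
  X <- matrix(rnorm(16 * 4), 16)
  Y <- rnorm(16)
  expect_identical(kennard_stone_split(X, 0.5),
                   kennard_stone_split(X, 0.5))
  expect_identical(spxy_split(X, Y, 0.5), spxy_split(X, Y, 0.5))
  perm <- sample(16)
  sp1 <- kennard_stone_split(X, 0.5)
  sp2 <- kennard_stone_split(X[perm, ], 0.5)
  expect_setequal(perm[sp2$train_indices], sp1$train_indices)
})

test_that("SPXY limit cases: constant Y reduces to K-S; constant X uses Y", {
  set.seed(8)
  X <- matrix(rnorm(24), 8)
  expect_equal(spxy_split(X, rep(1, 8), 0.5)$train_indices,
               kennard_stone_split(X, 0.5)$train_indices)
  Xc <- matrix(1, 3, 4)
  spy <- spxy_split(Xc, c(0, 1, 10), 2 / 3)
  expect_setequal(spy$train_indices, c(1, 3))
  expect_error(spxy_split(Xc, rep(2, 3), 2 / 3), "degenerate")
})

test_that("LOO-PLS screen flags exactly the corrupted sample", {
  set.seed(13)
  n <- 30
  Tt <- matrix(rnorm(n * 5), n)
  P <- matrix(rnorm(5 * 20), 5)
  X <- Tt %*% P
  w <- rnorm(5)
  y <- as.numeric(Tt %*% w)
  y <- y * (0.1 / sd(y))            # exact rank-5 linear relation, sd 0.1
  rep0 <- loo_pls_outlier_screen(X, y, n_components = 5, threshold = 30)
  expect_length(rep0$removed_indices, 0)
  yc <- y
  yc[7] <- yc[7] + 100 * sd(y)
  rep1 <- loo_pls_outlier_screen(X, yc, n_components = 5, threshold = 30)
  expect_equal(rep1$removed_indices, 7L)
  expect_gt(rep1$per_sample_mse[7], 30)
  # removed <=> error above threshold
  expect_equal(which(rep1$per_sample_mse > 30), rep1$removed_indices)
  # +Inf threshold removes nothing
  expect_length(loo_pls_outlier_screen(X, yc, 5, Inf)$removed_indices, 0)
  expect_error(loo_pls_outlier_screen(X, y, 5, -1), "threshold")
})

test_that("outlier screen is threshold-monotone", {
  set.seed(21)
  Tt <- matrix(rnorm(20 * 3), 20)
  X <- Tt %*% matrix(rnorm(3 * 12), 3)
  y <- as.numeric(Tt %*% rnorm(3)) + rnorm(20, 0, 0.5)
  rep <- loo_pls_outlier_screen(X, y, 3, threshold = 1e-6)
  counts <- vapply(c(1e-6, 1e-3, 0.1, 1, 30),
                   function(th) sum(rep$per_sample_mse > th), numeric(1))
  expect_true(all(diff(counts) <= 0))
  counts2 <- vapply(c(1e-6, 0.1, 30), function(th)
    length(loo_pls_outlier_screen(X, y, 3, th)$removed_indices), numeric(1))
  expect_true(all(diff(counts2) <= 0))
})

test_that("wavelength truncation keeps the leading columns", {
  wl <- seq(600, by = 2, length.out = 650)
  set <- spectra_set(matrix(rnorm(4 * 650), 4), wl, rnorm(4))
  tr <- truncate_wavelengths(set, 530)
  expect_equal(ncol(tr$X), 530L)
  expect_equal(tr$wavelengths, wl[1:530])
  expect_equal(truncate_wavelengths(set, 650)$X, set$X)
  expect_equal(ncol(truncate_wavelengths(set, 1)$X), 1L)
  expect_error(truncate_wavelengths(set, 0), "n_first")
  expect_error(truncate_wavelengths(set, 651), "n_first")
})

test_that("SNV centers and scales rows; MSC inverts exact scatter", {
  expect_equal(as.numeric(snv(matrix(c(1, 2, 3), 1))), c(-1, 0, 1))
  set.seed(3)
  X <- matrix(rnorm(5 * 20), 5)
  expect_equal(snv(snv(X)), snv(X))
  expect_error(snv(rbind(X, 0)), "zero-variance")
  ref <- as.numeric(X[1, ])
  a <- c(1.2, 0.8, 2, 0.5); b <- c(0.1, -0.3, 0, 1)
  Xs <- sweep(sweep(matrix(rep(ref, 4), 4, byrow = TRUE), 1, a, "*"),
              1, b, "+")
  corrected <- msc(Xs, reference = ref)
  expect_equal(corrected, matrix(rep(ref, 4), 4, byrow = TRUE))
  expect_error(msc(X, reference = rep(1, 20)), "variance")
})
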