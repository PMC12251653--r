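test_that("component profiles are reproducible, nonnegative and well shaped", {
  wl <- seq(1100, by = 2, length.out = 700)
  P1 <- generate_component_profiles(3, wl, seed = 11)
  P2 <- generate_component_profiles(3, wl, seed = 11)
  expect_identical(unclass(P1), unclass(P2))
  expect_equal(dim(P1), c(3L, 700L))
  expect_gte(min(P1), 0)
  expect_error(generate_component_profiles(2, numeric(0)), "grid")
  expect_error(generate_component_profiles(2, wl, peak_width_range = c(-1, 2)),
               "width")
})

test_that("a narrow single peak concentrates at the drawn center", {
  wl <- seq(1000, by = 2, length.out = 100)
  P <- generate_component_profiles(1, wl, peaks_per_component = 1,
                                   peak_width_range = c(0.8, 0.8), seed = 5)
  # oracle: replay the draws and evaluate the Gaussian directly
  set.seed(5)
  center <- runif(1, min(wl), max(wl))
  width <- runif(1, 0.8, 0.8)
  amp <- runif(1, 0.2, 1)
  expect_equal(as.numeric(P), amp * exp(-(wl - center)^2 / (2 * width^2)))
  expect_equal(which.max(P[1, ]), which.min(abs(wl - center)))
})

test_that("noise-free master spectra have rank equal to the component count", {
  wl <- seq(1100, by = 2, length.out = 120)
  P <- generate_component_profiles(3, wl, seed = 2)
  m <- generate_master_spectra(P, 40, rep(list(c(0, 1)), 3),
                               baseline_amp = 0, noise_sd = 0, seed = 3)
  sv <- svd(m$X)$d
  expect_equal(sum(sv > 1e-8 * sv[1]), 3)
  expect_equal(dim(m$X), c(40L, 120L))
  expect_equal(dim(m$Y), c(40L, 3L))
  expect_identical(m$instrument_id, "master")
})

test_that("master spectra contracts: shapes, determinism, degenerate ranges", {
  wl <- seq(1100, by = 2, length.out = 700)
  P <- generate_component_profiles(3, wl, seed = 1)
  m1 <- generate_master_spectra(P, 80, rep(list(c(0, 1)), 3), seed = 9)
  m2 <- generate_master_spectra(P, 80, rep(list(c(0, 1)), 3), seed = 9)
  expect_identical(m1$X, m2$X)
  expect_equal(dim(m1$X), c(80L, 700L))
  # all-degenerate concentration ranges, no noise -> identical rows
  md <- generate_master_spectra(P, 6, rep(list(c(0.4, 0.4)), 3),
                                baseline_amp = 0, noise_sd = 0, seed = 2)
  expect_equal(max(abs(sweep(md$X, 2, md$X[1, ]))), 0)
  expect_error(generate_master_spectra(P, 5, list(c(0, 1))), "interval")
})

test_that("instrument transform: identity, offset, gain and composition laws", {
  sc <- tiny_scenario(seed = 3, noise_sd = 0)
  m <- sc$master
  id <- instrument_transform()
  expect_equal(apply_instrument_transform(m, id)$X, m$X)
  off <- apply_instrument_transform(m, instrument_transform(offset = 0.7))
  expect_equal(off$X - m$X, matrix(0.7, nrow(m$X), ncol(m$X)))
  g2 <- apply_instrument_transform(m, instrument_transform(gain = 2))
  expect_equal(g2$X, 2 * m$X)
  g6 <- apply_instrument_transform(
    apply_instrument_transform(m, instrument_transform(gain = 2)),
    instrument_transform(gain = 3))
  expect_equal(g6$X, apply_instrument_transform(
    m, instrument_transform(gain = 6))$X)
})

test_that("reference values are copied unchanged and shifts are bounded", {
  sc <- tiny_scenario(seed = 7)
  tr <- instrument_transform(shift_nm = 5, broaden_sigma_nm = 3, gain = 1.2,
                             offset = 0.1, scatter_sd = 0.05, noise_sd = 0.01,
                             seed = 4, instrument_id = "s")
  out <- apply_instrument_transform(sc$master, tr)
  expect_identical(out$Y, sc$master$Y)
  expect_identical(out$instrument_id, "s")
  expect_error(apply_instrument_transform(
    sc$master, instrument_transform(shift_nm = 1e5)), "span")
  expect_error(instrument_transform(gain = 0), "gain")
  expect_error(instrument_transform(noise_sd = -1), "noise")
})

test_that("presets produce the two documented regimes", {
  sim <- simulate_transfer_scenario("corn-like", seed = 2)
  expect_equal(dim(sim$master$X), c(80L, 700L))
  expect_equal(ncol(sim$master$Y), 4L)
  expect_length(sim$slaves, 2)
  sim2 <- simulate_transfer_scenario("corn-like", seed = 2)
  expect_identical(sim$master$X, sim2$master$X)
  expect_identical(sim$slaves$slave1$X, sim2$slaves$slave1$X)
})
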