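#' Generate nonnegative component absorptivity profiles
#'
#' Builds a component-by-wavelength matrix of synthetic absorptivity
#' profiles, each a sum of Gaussian absorption bands with random centers,
#' widths and amplitudes. Together with [generate_master_spectra()] this
#' provides a Beer-Lambert mixing model for simulated calibration data.
#'
#' @param n_components number of chemical components (rows), >= 1.
#' @param wavelengths strictly increasing nm grid (>= 8 points).
#' @param peaks_per_component number of Gaussian bands per component.
#' @param peak_width_range length-2 vector, nm interval the band standard
#'   deviations are drawn from; both endpoints must be > 0.
#' @param seed integer RNG seed; the output is reproducible for a fixed seed.
#' @return A matrix of class `absorptivity_matrix` with attribute
#'   `wavelengths`; dimensions `n_components` x `length(wavelengths)`, all
#'   entries finite and >= 0.
#' @examples
#' P <- generate_component_profiles(3, seq(1100, 2498, 2), seed = 1)
#' dim(P)
#' @export
generate_component_profiles <- function(n_components, wavelengths,
                                        peaks_per_component = 4L,
                                        peak_width_range = c(20, 80),
                                        seed = 1L) {
  if (length(wavelengths) < 8) stop("wavelength grid must have >= 8 points")
  if (n_components < 1) stop("n_components must be >= 1")
  if (any(peak_width_range <= 0)) stop("peak widths must be > 0")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  set.seed(as.integer(seed))
  lo <- min(wavelengths); hi <- max(wavelengths)
  P <- matrix(0, n_components, length(wavelengths))
  for (c in seq_len(n_components)) {
    for (p in seq_len(peaks_per_component)) {
      center <- runif(1, lo, hi)
      width  <- runif(1, peak_width_range[1], peak_width_range[2])
      amp    <- runif(1, 0.2, 1)
      P[c, ] <- P[c, ] + amp * exp(-(wavelengths - center)^2 / (2 * width^2))
    }
  }
  structure(P, wavelengths = as.numeric(wavelengths),
            class = c("absorptivity_matrix", "matrix", "array"))
}

#' Simulate master-instrument mixture spectra
#'
#' Draws per-sample concentrations uniformly from `conc_ranges` and forms
#' absorbance spectra by linear Beer-Lambert mixing, `X = C %*% profiles`,
#' plus an optional random low-order polynomial baseline and white noise.
#' The drawn concentration matrix is returned as the reference values `Y`.
#'
#' @param profiles an [generate_component_profiles()] result.
#' @param n_samples number of samples, >= 1.
#' @param conc_ranges list of length-2 numeric vectors, one concentration
#'   interval per component (degenerate intervals are allowed).
#' @param baseline_amp amplitude (a.u.) of a per-sample random quadratic
#'   baseline; 0 disables it.
#' @param noise_sd standard deviation (a.u.) of additive white noise.
#' @param seed integer RNG seed.
#' @param target_names optional component labels.
#' @return A [spectra_set()] with `instrument_id = "master"`.
#' @examples
#' P <- generate_component_profiles(3, seq(1100, 1298, 2), seed = 1)
#' m <- generate_master_spectra(P, 10, rep(list(c(0, 1)), 3), seed = 2)
#' dim(m$X)
#' @export
generate_master_spectra <- function(profiles, n_samples, conc_ranges,
                                    baseline_amp = 0, noise_sd = 0,
                                    seed = 1L, target_names = NULL) {
  wl <- attr(profiles, "wavelengths")
  if (is.null(wl)) stop("profiles must carry a 'wavelengths' attribute")
  if (length(conc_ranges) != nrow(profiles))
    stop("conc_ranges must supply one interval per component (",
         nrow(profiles), " needed, ", length(conc_ranges), " given)")
  if (n_samples < 1) stop("n_samples must be >= 1")
  set.seed(as.integer(seed))
  k <- nrow(profiles); L <- ncol(profiles)
  C <- sapply(conc_ranges, function(r) runif(n_samples, r[1], r[2]))
  C <- matrix(C, nrow = n_samples, ncol = k)
  X <- C %*% unclass(profiles)
  if (baseline_amp != 0) {
    t <- seq(-1, 1, length.out = L)
    for (i in seq_len(n_samples)) {
      cf <- runif(3, -1, 1)
      X[i, ] <- X[i, ] + baseline_amp * (cf[1] + cf[2] * t + cf[3] * t^2)
    }
  }
  if (noise_sd > 0) X <- X + matrix(rnorm(n_samples * L, 0, noise_sd), n_samples, L)
  spectra_set(X, wl, C, target_names = target_names, instrument_id = "master")
}

#' Parametric master-to-slave instrument distortion
#'
#' Describes the systematic differences between a master spectrometer and a
#' slave unit: a wavelength registration shift, resolution broadening, a
#' global gain and baseline offset, per-sample multiplicative scatter, and
#' measurement noise.
#'
#' @param shift_nm wavelength offset in nm (slave grid reads the sample at
#'   `wavelength + shift_nm`).
#' @param broaden_sigma_nm Gaussian smoothing width in nm, >= 0.
#' @param gain global multiplicative factor, non-zero.
#' @param offset global additive baseline, a.u.
#' @param scatter_sd standard deviation of the per-sample multiplicative
#'   scatter factor `(1 + scatter_i)`, >= 0.
#' @param noise_sd additive white-noise level, a.u., >= 0.
#' @param seed integer RNG seed used for scatter and noise draws.
#' @param instrument_id label for the simulated slave instrument.
#' @return An object of class `instrument_transform`.
#' @export
instrument_transform <- function(shift_nm = 0, broaden_sigma_nm = 0, gain = 1,
                                 offset = 0, scatter_sd = 0, noise_sd = 0,
                                 seed = 1L, instrument_id = "slave") {
  if (broaden_sigma_nm < 0) stop("broaden_sigma_nm must be >= 0")
  if (scatter_sd < 0) stop("scatter_sd must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (gain == 0) stop("gain must be non-zero")
  structure(list(shift_nm = shift_nm, broaden_sigma_nm = broaden_sigma_nm,
                 gain = gain, offset = offset, scatter_sd = scatter_sd,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 instrument_id = instrument_id),
            class = "instrument_transform")
}

#' @export
print.instrument_transform <- function(x, ...) {
  cat(sprintf(
    "<instrument_transform '%s'> shift %g nm, broaden %g nm, gain %g, offset %g, scatter %g, noise %g\n",
    x$instrument_id, x$shift_nm, x$broaden_sigma_nm, x$gain, x$offset,
    x$scatter_sd, x$noise_sd))
  invisible(x)
}

# Gaussian smoothing along the wavelength axis; kernel truncated at +-4 sigma
# and renormalized to sum 1 so total absorbance mass is conserved.
gaussian_broaden <- function(X, sigma_pts) {
  if (sigma_pts <= 0) return(X)
  half <- max(1L, ceiling(4 * sigma_pts))
  ker <- exp(-((-half):half)^2 / (2 * sigma_pts^2))
  ker <- ker / sum(ker)
  L <- ncol(X)
  # edge-pad by replication, then convolve
  idx <- c(rep(1L, half), seq_len(L), rep(L, half))
  Xp <- X[, idx, drop = FALSE]
  out <- matrix(0, nrow(X), L)
  for (j in seq_along(ker))
    out <- out + ker[j] * Xp[, j:(j + L - 1), drop = FALSE]
  out
}

#' Apply an instrument transform to a master spectra set
#'
#' Derives slave-instrument spectra from master spectra. Per sample, the
#' spectrum is (1) resampled at `wavelengths + shift_nm` by linear
#' interpolation with edge values held, (2) smoothed with a Gaussian kernel
#' of width `broaden_sigma_nm` (truncated at 4 sigma, renormalized),
#' (3) scaled by `gain * (1 + scatter_i)` with `scatter_i ~ N(0, scatter_sd)`,
#' and (4) shifted by `offset` plus `N(0, noise_sd)` noise. Reference values
#' `Y` are copied unchanged: the samples are the same physical specimens.
#'
#' @param master a [spectra_set()].
#' @param t an [instrument_transform()].
#' @return A [spectra_set()] on the same wavelength grid with
#'   `instrument_id = t$instrument_id`.
#' @export
apply_instrument_transform <- function(master, t) {
  validate_spectra_set(master)
  stopifnot(inherits(t, "instrument_transform"))
  wl <- master$wavelengths
  span <- diff(range(wl))
  if (abs(t$shift_nm) >= span)
    stop("shift_nm (", t$shift_nm, ") exceeds the wavelength span (", span, ")")
  step <- if (length(wl) > 1) wl[2] - wl[1] else 1
  X <- master$X
  n <- nrow(X)
  if (t$shift_nm != 0 && n > 0) {
    q <- wl + t$shift_nm
    X <- t(apply(X, 1, function(row)
      approx(wl, row, xout = q, rule = 2)$y))
  }
  X <- gaussian_broaden(X, t$broaden_sigma_nm / step)
  set.seed(t$seed)
  scatter <- if (t$scatter_sd > 0) rnorm(n, 0, t$scatter_sd) else numeric(n)
  X <- X * (t$gain * (1 + scatter))
  X <- X + t$offset
  if (t$noise_sd > 0) X <- X + matrix(rnorm(length(X), 0, t$noise_sd), n)
  spectra_set(X, wl, master$Y, master$target_names, t$instrument_id)
}

#' Simulate a paired-instrument calibration-transfer scenario
#'
#' Preset factories mirroring the two regimes common in public
#' calibration-transfer benchmarks:
#' \describe{
#'   \item{`"corn-like"`}{80 samples, 700 wavelength points (1100-2498 nm,
#'     2 nm step), 4 constituents (moisture, oil, protein, starch), two
#'     slave instruments with a *large* distortion so that a master model
#'     fails on the slaves before transfer.}
#'   \item{`"tablet-like"`}{655 samples, 650 points (600-1898 nm, 2 nm
#'     step), 1 constituent (active ingredient, mg), one slave instrument
#'     with a *small* distortion.}
#' }
#'
#' @param preset `"corn-like"` or `"tablet-like"`.
#' @param seed integer RNG seed controlling profiles, concentrations and
#'   instrument noise.
#' @return A list with elements `master` (a [spectra_set()]), `slaves`
#'   (named list of slave [spectra_set()]s), and `transforms` (the
#'   [instrument_transform()]s used).
#' @examples
#' sim <- simulate_transfer_scenario("corn-like", seed = 1)
#' sim$master
#' names(sim$slaves)
#' @export
simulate_transfer_scenario <- function(preset = c("corn-like", "tablet-like"),
                                       seed = 1L) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  if (preset == "corn-like") {
    wl <- seq(1100, by = 2, length.out = 700)
    targets <- c("moisture", "oil", "protein", "starch")
    ranges <- list(c(9, 11), c(3, 4), c(7.5, 9.5), c(62, 66))
    prof <- generate_component_profiles(4, wl, peaks_per_component = 5,
                                        peak_width_range = c(15, 70),
                                        seed = seed)
    # scale profiles so each constituent's contribution is O(0.1) a.u.
    prof[] <- unclass(prof) / rowMeans(unclass(prof)) *
      c(0.02, 0.05, 0.03, 0.004)
    master <- generate_master_spectra(prof, 80, ranges, baseline_amp = 0.05,
                                      noise_sd = 0.002, seed = seed + 1L,
                                      target_names = targets)
    transforms <- list(
      slave1 = instrument_transform(shift_nm = 2, broaden_sigma_nm = 4,
                                    gain = 1.10, offset = 0.06,
                                    scatter_sd = 0.02, noise_sd = 0.003,
                                    seed = seed + 2L, instrument_id = "slave1"),
      slave2 = instrument_transform(shift_nm = -1.5, broaden_sigma_nm = 5,
                                    gain = 0.92, offset = -0.04,
                                    scatter_sd = 0.03, noise_sd = 0.003,
                                    seed = seed + 3L, instrument_id = "slave2"))
  } else {
    wl <- seq(600, by = 2, length.out = 650)
    targets <- "active"
    ranges <- list(c(150, 250))
    prof <- generate_component_profiles(1, wl, peaks_per_component = 6,
                                        peak_width_range = c(15, 60),
                                        seed = seed)
    prof[] <- unclass(prof) / rowMeans(unclass(prof)) * 0.002
    master <- generate_master_spectra(prof, 655, ranges, baseline_amp = 0.05,
                                      noise_sd = 0.002, seed = seed + 1L,
                                      target_names = targets)
    transforms <- list(
      slave1 = instrument_transform(shift_nm = 1, broaden_sigma_nm = 2,
                                    gain = 1.03, offset = 0.02,
                                    scatter_sd = 0.01, noise_sd = 0.002,
                                    seed = seed + 2L, instrument_id = "slave1"))
  }
  slaves <- lapply(transforms, function(tr)
    apply_instrument_transform(master, tr))
  list(master = master, slaves = slaves, transforms = transforms)
}
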