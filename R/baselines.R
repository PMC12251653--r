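#' Partial least squares regression baseline
#'
#' NIPALS PLS regression (via \pkg{mixOmics}) on unscaled, centered
#' spectra. The reference setup retains a minimum of 5 components.
#'
#' @param X spectra matrix.
#' @param y reference-value vector.
#' @param n_components number of latent variables (capped at
#'   `min(n - 1, p)`).
#' @return An object of class `pls_model` with a [predict()] method.
#' @export
pls_fit <- function(X, y, n_components = 5L) {
  X <- as.matrix(X)
  if (all(apply(X, 2, var) == 0)) stop("degenerate X: zero variance")
  eng <- pls_engine(X, as.numeric(y), n_components)
  structure(list(engine = eng, n_components = eng$ncomp),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  object$engine$predict(as.matrix(newdata))
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components\n", x$n_components))
  invisible(x)
}

#' Support vector regression baseline
#'
#' Epsilon-insensitive support vector regression (via \pkg{e1071}); the
#' reference comparison uses a linear kernel. A `gamma` value is accepted
#' for configuration fidelity, but note that it has no effect on a linear
#' kernel (a warning is emitted if it is supplied with one).
#'
#' @param X spectra matrix.
#' @param y reference-value vector.
#' @param kernel kernel name, default `"linear"`.
#' @param C regularization (cost) parameter.
#' @param epsilon width of the insensitive tube.
#' @param gamma kernel coefficient; inert for linear kernels.
#' @return An object of class `svr_model` with a [predict()] method.
#' @export
svr_fit <- function(X, y, kernel = "linear", C = 1, epsilon = 0.1,
                    gamma = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples")
  if (!is.null(gamma) && kernel == "linear")
    warning("gamma has no effect with a linear kernel; accepted for ",
            "configuration fidelity only")
  args <- list(x = X, y = as.numeric(y), type = "eps-regression",
               kernel = kernel, cost = C, epsilon = epsilon, scale = FALSE)
  if (!is.null(gamma) && kernel != "linear") args$gamma <- gamma
  fit <- do.call(e1071::svm, args)
  structure(list(fit = fit), class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  as.numeric(predict(object$fit, as.matrix(newdata)))
}

# ridge-regularized multi-response least squares: minimizes
# ||M - S B||^2 + ridge ||B||^2 columnwise
ridge_solve <- function(S, M, ridge) {
  A <- crossprod(S) + diag(ridge, ncol(S))
  solve(A, crossprod(S, M))
}

#' Direct standardization (DS)
#'
#' Estimates a full slave-to-master spectral mapping matrix `F` from
#' transfer standards (the same samples measured on both instruments, in
#' matching row order) by ridge-regularized least squares, optionally with
#' a column intercept (centered mode). Corrected slave spectra
#' `slave_X %*% F + intercept` can then be fed to any master-instrument
#' model.
#'
#' @param master_std,slave_std standards measured on the master and slave
#'   instruments, matched rows.
#' @param ridge regularization weight (>= 0).
#' @param center logical; estimate the map on centered spectra and carry
#'   an additive intercept row.
#' @return An object of class `standardization_map` with fields `F`
#'   (wavelengths x wavelengths), `intercept`, `window` (`NA` for DS) and
#'   `ridge`.
#' @export
ds_fit <- function(master_std, slave_std, ridge = 1e-6, center = TRUE) {
  master_std <- as.matrix(master_std); slave_std <- as.matrix(slave_std)
  if (nrow(master_std) != nrow(slave_std))
    stop("standards must have matching rows on both instruments")
  mm <- if (center) colMeans(master_std) else numeric(ncol(master_std))
  ms <- if (center) colMeans(slave_std) else numeric(ncol(slave_std))
  Fmat <- ridge_solve(sweep(slave_std, 2, ms), sweep(master_std, 2, mm),
                      ridge)
  intercept <- mm - as.numeric(ms %*% Fmat)
  structure(list(F = Fmat, intercept = intercept, window = NA_integer_,
                 ridge = ridge, method = "ds"),
            class = "standardization_map")
}

#' Apply a standardization map to slave spectra
#'
#' @param map a [ds_fit()] or [pds_fit()] result.
#' @param slave_X slave spectra matrix.
#' @return Corrected (master-like) spectra.
#' @export
ds_apply <- function(map, slave_X) {
  stopifnot(inherits(map, "standardization_map"))
  sweep(as.matrix(slave_X) %*% map$F, 2, map$intercept, "+")
}

#' Piecewise direct standardization (PDS)
#'
#' As [ds_fit()], but each master wavelength is regressed only on the
#' slave wavelengths inside a window of half-width `window` grid points
#' (truncated at the edges), yielding a banded mapping matrix. With a
#' window spanning the whole grid PDS coincides with DS at the same
#' ridge.
#'
#' @inheritParams ds_fit
#' @param window half-width in grid points (>= 0, < grid length).
#' @return A `standardization_map` with banded `F`.
#' @export
pds_fit <- function(master_std, slave_std, window = 5L, ridge = 1e-6,
                    center = TRUE) {
  master_std <- as.matrix(master_std); slave_std <- as.matrix(slave_std)
  if (nrow(master_std) != nrow(slave_std))
    stop("standards must have matching rows on both instruments")
  L <- ncol(master_std)
  if (window < 0 || window >= L)
    stop("window must lie in [0, grid length)")
  mm <- if (center) colMeans(master_std) else numeric(L)
  ms <- if (center) colMeans(slave_std) else numeric(ncol(slave_std))
  Mc <- sweep(master_std, 2, mm)
  Sc <- sweep(slave_std, 2, ms)
  Fmat <- matrix(0, ncol(slave_std), L)
  for (j in seq_len(L)) {
    cols <- max(1L, j - window):min(ncol(slave_std), j + window)
    Fmat[cols, j] <- ridge_solve(Sc[, cols, drop = FALSE],
                                 Mc[, j, drop = FALSE], ridge)
  }
  intercept <- mm - as.numeric(ms %*% Fmat)
  structure(list(F = Fmat, intercept = intercept,
                 window = as.integer(window), ridge = ridge,
                 method = "pds"),
            class = "standardization_map")
}

#' @rdname ds_apply
#' @export
pds_apply <- function(map, slave_X) ds_apply(map, slave_X)

#' @export
print.standardization_map <- function(x, ...) {
  cat(sprintf("<standardization_map %s> %d x %d%s, ridge %g\n",
              toupper(x$method), nrow(x$F), ncol(x$F),
              if (!is.na(x$window)) sprintf(", window %d", x$window) else "",
              x$ridge))
  invisible(x)
}

#' Slope and bias correction (SBC)
#'
#' Ordinary least squares of the reference values of the transfer
#' standards on the master model's predictions for their slave spectra;
#' the fitted affine map `corrected = slope * yhat + bias` is then applied
#' to new predictions.
#'
#' @param y_ref reference values of the standards.
#' @param yhat_slave master-model predictions on the slave-measured
#'   standards (non-constant, >= 2 values).
#' @return An object of class `affine_correction` with `slope` and `bias`.
#' @export
sbc_fit <- function(y_ref, yhat_slave) {
  y_ref <- as.numeric(y_ref); yhat_slave <- as.numeric(yhat_slave)
  if (length(y_ref) < 2 || length(y_ref) != length(yhat_slave))
    stop("need >= 2 matched standards")
  if (var(yhat_slave) == 0)
    stop("constant predictions on the standards: slope is unidentifiable")
  cf <- coef(lm(y_ref ~ yhat_slave))
  structure(list(slope = unname(cf[2]), bias = unname(cf[1])),
            class = "affine_correction")
}

#' @rdname sbc_fit
#' @param corr an `affine_correction`.
#' @param yhat predictions to correct.
#' @return `sbc_apply`: the corrected predictions.
#' @export
sbc_apply <- function(corr, yhat) {
  stopifnot(inherits(corr, "affine_correction"))
  corr$slope * as.numeric(yhat) + corr$bias
}

#' @export
print.affine_correction <- function(x, ...) {
  cat(sprintf("<affine_correction> slope %.6g, bias %.6g\n", x$slope, x$bias))
  invisible(x)
}
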