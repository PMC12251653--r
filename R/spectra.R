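#' Spectra set: absorbance matrix plus wavelength grid and reference values
#'
#' The universal exchange object of the package. `X` holds one spectrum per
#' row (absorbance, a.u.), `wavelengths` the strictly increasing nm grid
#' (one entry per column of `X`), and `Y` the per-sample reference values
#' (one column per constituent, e.g. moisture or protein content).
#'
#' @param X numeric matrix, samples by wavelengths.
#' @param wavelengths numeric vector of nm positions, strictly increasing,
#'   length equal to `ncol(X)`.
#' @param Y numeric matrix of reference values, `nrow(Y) == nrow(X)`. A
#'   vector is treated as a single-column matrix.
#' @param target_names character vector of constituent labels; defaults to
#'   the column names of `Y` or `target1`, `target2`, ...
#' @param instrument_id single string naming the instrument that produced
#'   the spectra.
#' @return An object of class `spectra_set`.
#' @examples
#' s <- spectra_set(matrix(rnorm(20), 4, 5), wavelengths = seq(1100, 1108, 2),
#'                  Y = runif(4), instrument_id = "master")
#' s
#' @export
spectra_set <- function(X, wavelengths, Y, target_names = NULL,
                        instrument_id = "unknown") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(dim(Y))) Y <- matrix(as.numeric(Y), ncol = 1L)
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (is.null(target_names)) {
    target_names <- colnames(Y)
    if (is.null(target_names) && ncol(Y) > 0)
      target_names <- paste0("target", seq_len(ncol(Y)))
    if (is.null(target_names)) target_names <- character(0)
  }
  colnames(Y) <- target_names
  obj <- structure(
    list(X = X, wavelengths = as.numeric(wavelengths), Y = Y,
         target_names = target_names,
         instrument_id = as.character(instrument_id)[1]),
    class = "spectra_set")
  validate_spectra_set(obj)
  obj
}

#' Validate a spectra_set
#'
#' Checks the structural invariants: matching sample counts between `X` and
#' `Y`, a strictly increasing wavelength grid of the right length, and the
#' absence of non-finite values.
#'
#' @param set a [spectra_set()].
#' @return `set`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_spectra_set <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  if (nrow(set$X) != nrow(set$Y))
    stop("spectra_set: X has ", nrow(set$X), " rows but Y has ",
         nrow(set$Y), call. = FALSE)
  if (length(set$wavelengths) != ncol(set$X))
    stop("spectra_set: wavelength grid length (", length(set$wavelengths),
         ") != number of spectral columns (", ncol(set$X), ")", call. = FALSE)
  if (length(set$wavelengths) > 1 && any(diff(set$wavelengths) <= 0))
    stop("spectra_set: wavelengths must be strictly increasing", call. = FALSE)
  if (nrow(set$X) > 0 && (!all(is.finite(set$X)) || !all(is.finite(set$Y))))
    stop("spectra_set: X and Y must be finite (no NaN/Inf)", call. = FALSE)
  if (length(set$target_names) != ncol(set$Y))
    stop("spectra_set: target_names length != ncol(Y)", call. = FALSE)
  invisible(set)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> instrument '%s': %d samples x %d wavelengths (%g-%g nm)\n",
              x$instrument_id, nrow(x$X), ncol(x$X),
              if (length(x$wavelengths)) min(x$wavelengths) else NA,
              if (length(x$wavelengths)) max(x$wavelengths) else NA))
  if (length(x$target_names))
    cat("  targets:", paste(x$target_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$X)

#' Subset the samples of a spectra_set
#'
#' @param set a [spectra_set()].
#' @param i integer or logical index over samples (rows).
#' @return A `spectra_set` containing the selected samples.
#' @export
subset_samples <- function(set, i) {
  validate_spectra_set(set)
  spectra_set(set$X[i, , drop = FALSE], set$wavelengths,
              set$Y[i, , drop = FALSE], set$target_names, set$instrument_id)
}

# Resolve a target column given a name or index; returns the column index.
resolve_target <- function(set, target) {
  if (is.character(target)) {
    idx <- match(target, set$target_names)
    if (is.na(idx))
      stop("unknown target '", target, "'; available: ",
           paste(set$target_names, collapse = ", "), call. = FALSE)
    return(idx)
  }
  target <- as.integer(target)
  if (target < 1L || target > ncol(set$Y))
    stop("target index out of range", call. = FALSE)
  target
}
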