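#' Kennard-Stone calibration/test split
#'
#' Deterministic sample selection by sequential max-min Euclidean distance:
#' the first two training picks are a pair at maximum pairwise distance;
#' each subsequent pick maximizes its minimum distance to the already
#' selected set. Ties are broken toward the lowest sample index so the
#' result is platform independent.
#'
#' @param X numeric matrix, samples by variables.
#' @param train_fraction fraction in (0, 1); the training size is
#'   `round(train_fraction * n)` with ties rounded half up (so an 8:2 split
#'   of 80 samples gives 64/16).
#' @return A list of class `split_result` with `train_indices` (in pick
#'   order), `test_indices`, `method` and `ratio`.
#' @examples
#' ks <- kennard_stone_split(matrix(c(0, 1, 10)), 2/3)
#' ks$train_indices
#' @export
kennard_stone_split <- function(X, train_fraction) {
  X <- as.matrix(X)
  D <- as.matrix(stats::dist(X))
  ks_core(D, nrow(X), train_fraction, method = "ks")
}

#' SPXY calibration/test split
#'
#' Kennard-Stone selection on the joint normalized distance
#' `d = d_X / max(d_X) + d_Y / max(d_Y)`, so that both spectral and
#' reference-value spread drive the selection. If either block is constant
#' its term is dropped; if both are constant the input is degenerate and an
#' error is raised.
#'
#' @param X numeric matrix of spectra.
#' @param Y numeric matrix or vector of reference values (rows match `X`).
#' @inheritParams kennard_stone_split
#' @return A `split_result` (see [kennard_stone_split()]), `method = "spxy"`.
#' @export
spxy_split <- function(X, Y, train_fraction) {
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  if (nrow(Y) != nrow(X)) stop("Y rows must match X rows")
  DX <- as.matrix(stats::dist(X))
  DY <- as.matrix(stats::dist(Y))
  mx <- max(DX); my <- max(DY)
  if (mx == 0 && my == 0)
    stop("degenerate input: all joint SPXY distances are zero")
  D <- (if (mx > 0) DX / mx else 0) + (if (my > 0) DY / my else 0)
  ks_core(D, nrow(X), train_fraction, method = "spxy")
}

# Shared max-min selection on a precomputed distance matrix.
ks_core <- function(D, n, train_fraction, method) {
  if (n < 2) stop("need at least 2 samples")
  if (!is.finite(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  n_train <- floor(train_fraction * n + 0.5)  # round half up
  if (n_train < 2) stop("train_fraction yields fewer than 2 training samples")
  # first pair: maximum distance, lexicographically smallest on ties
  best <- which(D == max(D), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  if (nrow(best) == 0) best <- matrix(c(1L, 2L), 1)  # all-identical input
  ord <- order(best[, 1], best[, 2])
  sel <- as.integer(best[ord[1], ])
  mind <- unname(pmin(D[, sel[1]], D[, sel[2]]))
  while (length(sel) < n_train) {
    mind[sel] <- -Inf
    # which.max returns the first (lowest index) tie
    sel <- c(sel, as.integer(which.max(mind)))
    mind <- pmin(mind, D[, sel[length(sel)]])
  }
  structure(list(train_indices = sel,
                 test_indices = setdiff(seq_len(n), sel),
                 method = method, ratio = train_fraction),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result %s> %d train / %d test (ratio %.3g)\n",
              x$method, length(x$train_indices), length(x$test_indices),
              x$ratio))
  invisible(x)
}

#' Random calibration/test split
#'
#' Convenience counterpart to [kennard_stone_split()] using uniform random
#' selection, with the same rounding rule for the training size.
#'
#' @inheritParams kennard_stone_split
#' @param n number of samples.
#' @param seed integer RNG seed.
#' @return A `split_result`, `method = "random"`.
#' @export
random_split <- function(n, train_fraction, seed = 1L) {
  if (n < 2) stop("need at least 2 samples")
  n_train <- floor(train_fraction * n + 0.5)
  if (n_train < 2) stop("train_fraction yields fewer than 2 training samples")
  set.seed(as.integer(seed))
  tr <- sort(sample.int(n, n_train))
  structure(list(train_indices = tr, test_indices = setdiff(seq_len(n), tr),
                 method = "random", ratio = train_fraction),
            class = "split_result")
}

# Internal PLS wrapper shared by the outlier screen and the baselines.
# NIPALS PLS regression via mixOmics; returns a predict closure.
pls_engine <- function(X, y, n_components) {
  n_components <- min(n_components, nrow(X) - 1L, ncol(X))
  X <- as.matrix(X)
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  fit <- mixOmics::pls(X, matrix(y, ncol = 1), ncomp = n_components,
                       mode = "regression", scale = FALSE)
  list(fit = fit, ncomp = n_components,
       predict = function(newX) {
         newX <- as.matrix(newX)
         colnames(newX) <- paste0("V", seq_len(ncol(newX)))
         p <- predict(fit, newX)$predict
         as.numeric(p[, 1, n_components])
       })
}

#' Leave-one-out PLS outlier screen
#'
#' For every sample, fits a PLS regression on all remaining samples and
#' records the squared prediction error at the held-out sample. Samples
#' whose error exceeds `threshold` are flagged for removal.
#'
#' @param X spectra matrix.
#' @param y reference-value vector.
#' @param n_components PLS components used inside the screen (default 5,
#'   matching the floor used by the PLS baseline).
#' @param threshold squared-error cutoff (target units squared), > 0. The
#'   conventional screening threshold for assay-scale targets is 30.
#' @return A list of class `outlier_report` with `per_sample_mse`,
#'   `removed_indices` and `threshold`.
#' @export
loo_pls_outlier_screen <- function(X, y, n_components = 5L, threshold = 30) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (!is.finite(threshold) && threshold > 0) {
    # +Inf is a valid "remove nothing" limit
  } else if (!(threshold > 0)) stop("threshold must be > 0")
  if (n <= n_components + 1)
    stop("need more than n_components + 1 samples for the LOO screen")
  err <- vapply(seq_len(n), function(i) {
    eng <- pls_engine(X[-i, , drop = FALSE], y[-i], n_components)
    (y[i] - eng$predict(X[i, , drop = FALSE]))^2
  }, numeric(1))
  structure(list(per_sample_mse = err,
                 removed_indices = which(err > threshold),
                 threshold = threshold),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d/%d samples above threshold %g\n",
              length(x$removed_indices), length(x$per_sample_mse),
              x$threshold))
  if (length(x$removed_indices))
    cat("  removed:", paste(x$removed_indices, collapse = ", "), "\n")
  invisible(x)
}

#' Keep only the first wavelengths of a spectra set
#'
#' Detector back-end channels are often noise dominated; truncating the
#' grid to the first `n_first` points (e.g. 530 of 650) discards them.
#'
#' @param set a [spectra_set()].
#' @param n_first number of leading wavelength columns to keep.
#' @return The truncated [spectra_set()].
#' @export
truncate_wavelengths <- function(set, n_first) {
  validate_spectra_set(set)
  L <- ncol(set$X)
  if (n_first < 1 || n_first > L)
    stop("n_first must lie in [1, ", L, "]")
  spectra_set(set$X[, seq_len(n_first), drop = FALSE],
              set$wavelengths[seq_len(n_first)],
              set$Y, set$target_names, set$instrument_id)
}

#' Standard normal variate (SNV) transform
#'
#' Centers each spectrum (row) and scales it to unit sample standard
#' deviation (divisor `n - 1`), the usual chemometric scatter correction.
#'
#' @param X spectra matrix.
#' @return The transformed matrix.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  s <- apply(X, 1, sd)
  if (any(s == 0))
    stop("snv: zero-variance row(s): ", paste(which(s == 0), collapse = ", "))
  (X - rowMeans(X)) / s
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum (`x_i = a_i * ref + b_i`
#' by ordinary least squares) and corrects it to `(x_i - b_i) / a_i`.
#'
#' @param X spectra matrix.
#' @param reference reference spectrum; defaults to the column-mean spectrum.
#' @return The corrected matrix.
#' @export
msc <- function(X, reference = colMeans(X)) {
  X <- as.matrix(X)
  ref <- as.numeric(reference)
  if (length(ref) != ncol(X)) stop("reference length must equal ncol(X)")
  v <- sum((ref - mean(ref))^2)
  if (v == 0) stop("msc: reference spectrum has zero variance")
  rc <- ref - mean(ref)
  a <- as.numeric((X %*% rc) - rowSums(X) * mean(rc)) / v
  b <- rowMeans(X) - a * mean(ref)
  if (any(a == 0))
    stop("msc: zero slope for row(s): ", paste(which(a == 0), collapse = ", "))
  (X - b) / a
}
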