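#' Maximum mean discrepancy estimator configuration
#'
#' @param kernel `"rbf"` (Gaussian, `k(x, y) = exp(-||x - y||^2 / (2 s^2))`)
#'   or `"linear"` (`k(x, y) = <x, y>`).
#' @param bandwidth_rule `"median"` computes the bandwidth per batch as the
#'   median of the non-zero pooled pairwise distances (the median
#'   heuristic); `"fixed"` uses `bandwidth`.
#' @param bandwidth positive scalar, used when `bandwidth_rule = "fixed"`.
#' @return An object of class `mmd_config`.
#' @export
mmd_config <- function(kernel = c("rbf", "linear"),
                       bandwidth_rule = c("median", "fixed"),
                       bandwidth = 1) {
  kernel <- match.arg(kernel)
  bandwidth_rule <- match.arg(bandwidth_rule)
  if (bandwidth_rule == "fixed" && !(bandwidth > 0))
    stop("bandwidth must be > 0 when fixed")
  structure(list(kernel = kernel, bandwidth_rule = bandwidth_rule,
                 bandwidth = bandwidth),
            class = "mmd_config")
}

as_feature_matrix <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  as.matrix(X)
}

mmd_bandwidth <- function(Xs, Xt, cfg) {
  if (cfg$bandwidth_rule == "fixed") return(cfg$bandwidth)
  Z <- rbind(Xs, Xt)
  d <- as.numeric(stats::dist(Z))
  d <- d[d > 0]
  if (length(d) == 0) return(1)
  median(d)
}

sq_dists <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

#' Squared maximum mean discrepancy between two feature batches
#'
#' Biased V-statistic estimator of the squared distance between the kernel
#' mean embeddings of the source and target batches:
#' `mean(K_ss) + mean(K_tt) - 2 mean(K_st)`. Nonnegative up to numerical
#' tolerance; tiny negative values are clipped to 0.
#'
#' @param Xs,Xt source / target batches, rows are samples (vectors are
#'   treated as single-column matrices). Feature dimensions must agree.
#' @param cfg an [mmd_config()].
#' @return A nonnegative scalar.
#' @examples
#' mmd2(matrix(0), matrix(1), mmd_config("rbf", "fixed", 1))  # 2 - 2 exp(-1/2)
#' @export
mmd2 <- function(Xs, Xt, cfg = mmd_config()) {
  mmd2_full(Xs, Xt, cfg, want_grad = FALSE)$value
}

# shared implementation; gradients treat a median-heuristic bandwidth as a
# constant (the standard stop-gradient convention)
mmd2_full <- function(Xs, Xt, cfg, want_grad = FALSE) {
  Xs <- as_feature_matrix(Xs); Xt <- as_feature_matrix(Xt)
  if (ncol(Xs) != ncol(Xt))
    stop("shape error: source and target feature dimensions differ (",
         ncol(Xs), " vs ", ncol(Xt), ")")
  n <- nrow(Xs); m <- nrow(Xt)
  if (n < 1 || m < 1) stop("each batch needs at least one sample")
  if (cfg$kernel == "linear") {
    delta <- colMeans(Xs) - colMeans(Xt)
    val <- sum(delta^2)
    out <- list(value = max(val, 0))
    if (want_grad) {
      out$dXs <- matrix(rep(2 * delta / n, each = n), n)
      out$dXt <- matrix(rep(-2 * delta / m, each = m), m)
    }
    return(out)
  }
  s <- mmd_bandwidth(Xs, Xt, cfg)
  Kss <- exp(-sq_dists(Xs, Xs) / (2 * s^2))
  Ktt <- exp(-sq_dists(Xt, Xt) / (2 * s^2))
  Kst <- exp(-sq_dists(Xs, Xt) / (2 * s^2))
  val <- mean(Kss) + mean(Ktt) - 2 * mean(Kst)
  out <- list(value = max(val, 0))
  if (want_grad) {
    # d k(x,y)/dx = -k(x,y) (x - y) / s^2
    gXs <- matrix(0, n, ncol(Xs))
    gXt <- matrix(0, m, ncol(Xt))
    # within-source: (1/n^2) * 2 * sum_b k'(xi, xb)
    W <- Kss / s^2
    gXs <- gXs - (2 / n^2) * (diag(rowSums(W), n) %*% Xs - W %*% Xs)
    W <- Ktt / s^2
    gXt <- gXt - (2 / m^2) * (diag(rowSums(W), m) %*% Xt - W %*% Xt)
    W <- Kst / s^2
    gXs <- gXs + (2 / (n * m)) * (diag(rowSums(W), n) %*% Xs - W %*% Xt)
    gXt <- gXt + (2 / (n * m)) * (diag(colSums(W), m) %*% Xt - t(W) %*% Xs)
    out$dXs <- gXs
    out$dXt <- gXt
  }
  out
}

#' Marginal distribution adaptation loss
#'
#' The squared MMD between source- and target-domain feature batches; by
#' default the features are the first fully connected layer activations of
#' the network.
#'
#' @inheritParams mmd2
#' @return A nonnegative scalar, identical to [mmd2()].
#' @export
mda_loss <- function(Xs, Xt, cfg = mmd_config()) mmd2(Xs, Xt, cfg)

#' Conditional distribution adaptation loss
#'
#' The squared MMD between the model outputs (predictions) of the source
#' and target domains.
#'
#' @param Ys,Yt source / target prediction vectors (or n x 1 matrices).
#' @inheritParams mmd2
#' @return A nonnegative scalar.
#' @export
cda_loss <- function(Ys, Yt, cfg = mmd_config()) {
  mmd2(as_feature_matrix(Ys), as_feature_matrix(Yt), cfg)
}

#' Mean squared error loss
#'
#' @param y reference values.
#' @param yhat predictions, same length.
#' @return Mean of squared residuals.
#' @export
mse_loss <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("shape error: y and yhat lengths differ")
  mean((y - yhat)^2)
}

#' Weights of the balanced distribution adaptation objective
#'
#' `lambda1` scales the whole BDA block (marginal plus conditional terms)
#' in the total loss; `lambda2` scales the conditional term within that
#' block.
#'
#' @param lambda1,lambda2 nonnegative scalars.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 1) {
  if (lambda1 < 0 || lambda2 < 0) stop("loss weights must be >= 0")
  structure(list(lambda1 = lambda1, lambda2 = lambda2),
            class = "loss_weights")
}

#' Total fine-tuning objective
#'
#' Combines the task loss with the balanced distribution adaptation terms:
#' `total = mse + lambda1 * mda + lambda1 * lambda2 * cda`.
#'
#' @param mse task (mean squared error) loss, >= 0.
#' @param mda marginal distribution adaptation loss.
#' @param cda conditional distribution adaptation loss.
#' @param w a [loss_weights()].
#' @return The combined scalar loss.
#' @examples
#' total_loss(1, 0.5, 0.2, loss_weights(1, 1))    # 1.7
#' total_loss(1, 0.5, 0.2, loss_weights(0.5, 2))  # 1.45
#' @export
total_loss <- function(mse, mda, cda, w = loss_weights()) {
  stopifnot(inherits(w, "loss_weights"))
  if (!all(is.finite(c(mse, mda, cda)))) stop("loss terms must be finite")
  if (mse < 0) stop("mse must be >= 0")
  mse + w$lambda1 * mda + w$lambda1 * w$lambda2 * cda
}
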