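#' Evaluate predictions against reference values
#'
#' Computes the standard evaluation triad: the coefficient of
#' determination `R2 = 1 - SSres / SStot` (with `SStot` taken about the
#' mean of the supplied reference values, so a model worse than that mean
#' yields a negative `R2`), the root mean square error, and the mean
#' absolute error.
#'
#' @param y reference values (non-constant for `R2`).
#' @param yhat predictions, same length.
#' @return A list of class `eval_report` with `r2`, `rmse`, `mae`, `n`.
#'   For constant `y` a warning is raised and `r2` is `NA` while `rmse`
#'   and `mae` are still reported.
#' @examples
#' evaluate(c(0, 0), c(3, 4))  # rmse sqrt(12.5), mae 3.5
#' @export
evaluate <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) == 0 || length(y) != length(yhat))
    stop("y and yhat must have equal nonzero length")
  res <- yhat - y
  rmse <- sqrt(mean(res^2))
  mae <- mean(abs(res))
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sum(res^2) / sstot else {
    warning("r2 undefined: reference values are constant")
    NA_real_
  }
  structure(list(r2 = r2, rmse = rmse, mae = mae, n = length(y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report n=%d> R2 %.4f  RMSE %.4g  MAE %.4g\n",
              x$n, x$r2, x$rmse, x$mae))
  invisible(x)
}

#' Before/after-transfer metric comparison
#'
#' Tabulates metric deltas between two evaluations on the same test set
#' and flags the improvement direction per metric (`R2` improves upward,
#' errors improve downward).
#'
#' @param before,after [evaluate()] reports on the same test set.
#' @return A data frame with columns `metric`, `before`, `after`, `delta`
#'   and `improved`.
#' @export
paired_report <- function(before, after) {
  stopifnot(inherits(before, "eval_report"), inherits(after, "eval_report"))
  metric <- c("r2", "rmse", "mae")
  b <- unlist(before[metric]); a <- unlist(after[metric])
  data.frame(metric = metric, before = b, after = a, delta = a - b,
             improved = ifelse(metric == "r2", a > b, a < b),
             row.names = NULL)
}

#' Evaluate a fitted model on a spectra set
#'
#' Convenience wrapper: predicts the selected target and calls
#' [evaluate()].
#'
#' @param model an object with a [predict()] method over spectra matrices
#'   (e.g. a `bdser_net`, [pls_fit()] or [svr_fit()] result).
#' @param set a [spectra_set()].
#' @param target target column (index or name).
#' @return An `eval_report`.
#' @export
evaluate_model <- function(model, set, target = 1L) {
  validate_spectra_set(set)
  tcol <- resolve_target(set, target)
  evaluate(set$Y[, tcol], predict(model, set$X))
}

#' Before/after transfer scatter plot
#'
#' Base-graphics scatter of predicted versus reference values before and
#' after transfer on a common test set.
#'
#' @param y reference values.
#' @param yhat_before,yhat_after predictions before and after transfer.
#' @param main plot title.
#' @return Invisibly, `NULL`; called for the side effect.
#' @export
plot_transfer <- function(y, yhat_before, yhat_after,
                          main = "Calibration transfer") {
  rng <- range(y, yhat_before, yhat_after)
  graphics::plot(y, yhat_before, col = "darkgreen", pch = 1, xlim = rng,
                 ylim = rng, xlab = "reference", ylab = "predicted",
                 main = main)
  graphics::points(y, yhat_after, col = "orange", pch = 16)
  graphics::abline(0, 1, col = "blue")
  graphics::legend("topleft", legend = c("before", "after"),
                   col = c("darkgreen", "orange"), pch = c(1, 16), bty = "n")
  invisible(NULL)
}
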