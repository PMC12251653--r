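#' Training schedule
#'
#' Fixed-epoch Adam training with plateau learning-rate decay: if the
#' monitored (training) loss has not strictly improved on its running best
#' for `plateau_patience` consecutive epochs the learning rate is
#' multiplied by `lr_factor` and the counter resets. There is no early
#' stopping; training always runs the full number of epochs.
#'
#' @param batch_size minibatch size (128 for tablet-scale sets, 8 for
#'   corn-scale sets in the reference setup).
#' @param epochs number of epochs (>= 0).
#' @param lr initial learning rate (> 0); 0.001 is the reference value.
#' @param plateau_patience epochs without improvement before decay (>= 1);
#'   30 in the reference setup.
#' @param lr_factor decay multiplier in (0, 1); 0.5 halves the rate.
#' @param seed integer seed controlling initialization, batch order and
#'   dropout; training histories are reproducible for a fixed seed on one
#'   platform.
#' @return An object of class `train_schedule` (optimizer is Adam).
#' @export
train_schedule <- function(batch_size = 8L, epochs = 100L, lr = 0.001,
                           plateau_patience = 30L, lr_factor = 0.5,
                           seed = 1L) {
  if (!(lr > 0)) stop("lr must be > 0")
  if (lr_factor <= 0 || lr_factor >= 1) stop("lr_factor must lie in (0, 1)")
  if (plateau_patience < 1) stop("plateau_patience must be >= 1")
  if (epochs < 0) stop("epochs must be >= 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 plateau_patience = as.integer(plateau_patience),
                 lr_factor = lr_factor, optimizer = "Adam",
                 seed = as.integer(seed)),
            class = "train_schedule")
}

#' Plateau learning-rate rule
#'
#' Pure functional form of the decay rule used inside [pretrain()] and
#' [fine_tune()]: given a loss history, the learning rate is multiplied by
#' `factor` when the most recent `patience` epochs all failed to strictly
#' improve on the running best loss, and left unchanged otherwise.
#'
#' @param history numeric vector of per-epoch losses (oldest first).
#' @param patience epochs without improvement required before decay.
#' @param factor decay multiplier.
#' @param lr current learning rate.
#' @return The new learning rate.
#' @examples
#' plateau_scheduler(c(1, rep(1, 30)), 30, 0.5, 0.001)  # 5e-04
#' @export
plateau_scheduler <- function(history, patience, factor, lr) {
  if (length(history) == 0) stop("empty history")
  if (patience < 1) stop("patience must be >= 1")
  streak <- 0L
  best <- history[1]
  streaks <- numeric(length(history))
  for (i in seq_along(history)[-1]) {
    if (history[i] < best) {
      best <- history[i]
      streak <- 0L
    } else streak <- streak + 1L
    streaks[i] <- streak
  }
  if (length(history) > 1 && streaks[length(history)] >= patience)
    lr * factor else lr
}

#' Build a transfer plan for one of the six strategies
#'
#' Strategy semantics (freezing is by parameter group):
#' \enumerate{
#'   \item Freeze everything; no update steps (direct testing of the
#'     pre-trained model on the slave instrument).
#'   \item Freeze nothing; fine-tune the whole network.
#'   \item Freeze convolutions and the second fully connected layer;
#'     retrain only the first fully connected layer.
#'   \item Freeze convolutions and the first fully connected layer;
#'     retrain only the second.
#'   \item Freeze the convolutions; retrain both fully connected layers.
#'   \item As 5, but add the balanced distribution adaptation terms to the
#'     objective during retraining.
#' }
#'
#' @param strategy integer in 1..6.
#' @param weights a [loss_weights()]; only used by strategy 6.
#' @return An object of class `transfer_plan` with fields `strategy`,
#'   `freeze` (named logical over `stem`, `blocks`, `fc1`, `fc2`),
#'   `use_bda` and `weights`.
#' @export
make_plan <- function(strategy, weights = loss_weights()) {
  if (!(strategy %in% 1:6)) stop("strategy must be an integer in 1..6")
  strategy <- as.integer(strategy)
  fz <- c(stem = TRUE, blocks = TRUE, fc1 = TRUE, fc2 = TRUE)
  if (strategy == 2L) fz[] <- FALSE
  if (strategy == 3L) fz["fc1"] <- FALSE
  if (strategy == 4L) fz["fc2"] <- FALSE
  if (strategy %in% c(5L, 6L)) fz[c("fc1", "fc2")] <- FALSE
  structure(list(strategy = strategy, freeze = fz,
                 use_bda = strategy == 6L, weights = weights),
            class = "transfer_plan")
}

#' @export
print.transfer_plan <- function(x, ...) {
  cat(sprintf("<transfer_plan strategy %d> trainable: %s%s\n", x$strategy,
              if (any(!x$freeze)) paste(names(x$freeze)[!x$freeze],
                                        collapse = ", ") else "none",
              if (x$use_bda) sprintf(" + BDA (lambda1 %g, lambda2 %g)",
                                     x$weights$lambda1, x$weights$lambda2)
              else ""))
  invisible(x)
}

group_order <- c("stem", "blocks", "fc1", "fc2")

optimizer_new <- function(net, trainable) {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- lapply(trainable, function(g) ps_zeros_like(net$params[[g]]))
  e$v <- lapply(trainable, function(g) ps_zeros_like(net$params[[g]]))
  names(e$m) <- names(e$v) <- trainable
  e$trainable <- trainable
  e
}

optimizer_apply <- function(opt, net, grads, lr) {
  opt$t <- opt$t + 1L
  for (g in opt$trainable)
    net$params[[g]] <- adam_walk(net$params[[g]], grads[[g]],
                                 opt$m[[g]], opt$v[[g]], opt$t, lr)
  list(opt = opt, net = net)
}

# plateau bookkeeping shared by both training entry points
plateau_update <- function(ps, loss, sched) {
  if (loss < ps$best) {
    ps$best <- loss
    ps$counter <- 0L
  } else {
    ps$counter <- ps$counter + 1L
    if (ps$counter >= sched$plateau_patience) {
      ps$lr <- ps$lr * sched$lr_factor
      ps$counter <- 0L
    }
  }
  ps
}

#' Pre-train the network on the master instrument
#'
#' Builds the network from `cfg` and minimizes the mean squared error on
#' the selected target of the master training set with minibatch Adam and
#' plateau learning-rate decay. The target is standardized internally
#' (centered, unit variance) for optimizer conditioning; the scaling is
#' stored in the returned network and inverted automatically by
#' [predict.bdser_net()].
#'
#' @param cfg a [model_config()].
#' @param master_train a [spectra_set()] of master-instrument training
#'   samples.
#' @param sched a [train_schedule()]; its `seed` also seeds the parameter
#'   initialization.
#' @param target column of `master_train$Y` to model (index or name).
#' @param arch `"bdser"` or `"plain"` (see [build_model()]).
#' @return A list with `net` (the trained `bdser_net`) and `history`
#'   (data frame with per-epoch `loss` - training MSE on the standardized
#'   target - and the learning rate in force).
#' @export
pretrain <- function(cfg, master_train, sched, target = 1L,
                     arch = c("bdser", "plain")) {
  validate_spectra_set(master_train)
  stopifnot(inherits(sched, "train_schedule"))
  arch <- match.arg(arch)
  if (nrow(master_train$X) == 0) stop("training set is empty")
  tcol <- resolve_target(master_train, target)
  net <- build_model(cfg, seed = sched$seed, arch = arch)
  y <- master_train$Y[, tcol]
  net$y_center <- mean(y)
  net$y_scale <- if (sd(y) > 0) sd(y) else 1
  ys <- (y - net$y_center) / net$y_scale
  X <- master_train$X
  n <- nrow(X)
  if (sched$epochs == 0L)
    return(list(net = net,
                history = data.frame(epoch = integer(0), loss = numeric(0),
                                     lr = numeric(0))))
  set.seed(sched$seed)
  perms <- lapply(seq_len(sched$epochs), function(e) sample.int(n))
  set.seed(sched$seed + 2L)
  bs <- min(sched$batch_size, n)
  opt <- optimizer_new(net, group_order)
  ps <- list(lr = sched$lr, best = Inf, counter = 0L)
  hist_loss <- numeric(sched$epochs)
  hist_lr <- numeric(sched$epochs)
  p <- cfg$dropout_p
  D <- cfg$fc1_dims[1]
  for (e in seq_len(sched$epochs)) {
    perm <- perms[[e]]
    sse <- 0
    for (s in seq.int(1L, n, by = bs)) {
      idx <- perm[s:min(s + bs - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      cs <- conv_stack_fw(net, Xb, want_cache = TRUE)
      mask <- if (p > 0)
        matrix((runif(D * length(idx)) >= p) / (1 - p), D) else NULL
      hd <- head_fw(net$params, cs$f, mask)
      r <- hd$raw - ys[idx]
      sse <- sse + sum(r^2)
      dpred <- 2 * r / length(idx)
      hb <- head_bw(net$params, hd, dpred, NULL, mask)
      cg <- conv_stack_bw(net, cs$cache, hb$df)
      grads <- list(stem = cg$stem, blocks = cg$blocks,
                    fc1 = hb$gfc1, fc2 = hb$gfc2)
      up <- optimizer_apply(opt, net, grads, ps$lr)
      opt <- up$opt; net <- up$net
    }
    loss <- sse / n
    if (!is.finite(loss))
      stop("training diverged (non-finite loss) at epoch ", e)
    hist_loss[e] <- loss
    hist_lr[e] <- ps$lr
    ps <- plateau_update(ps, loss, sched)
  }
  list(net = net,
       history = data.frame(epoch = seq_len(sched$epochs), loss = hist_loss,
                            lr = hist_lr))
}

#' Fine-tune a pre-trained network on a slave instrument
#'
#' Runs the selected transfer strategy: frozen groups receive no updates
#' (and strategy 1 performs no steps at all). When the plan enables
#' balanced distribution adaptation (strategy 6), every step draws an
#' equal-size batch from the master training set, computes the marginal
#' MMD on the first fully connected layer features and the conditional MMD
#' on the raw outputs, and combines them with the slave-batch MSE via
#' [total_loss()]. Slave targets are standardized with the scaling learned
#' during [pretrain()] so master and slave outputs share one scale.
#'
#' When the convolutional groups are frozen, their activations are
#' precomputed once per dataset, so fine-tuning only iterates the head.
#' One dropout mask per step is shared between the slave and master
#' batches.
#'
#' @param net a pre-trained `bdser_net`.
#' @param plan a [make_plan()] transfer plan.
#' @param slave_train a [spectra_set()] of slave-instrument training
#'   samples.
#' @param master_train master-instrument training samples; required when
#'   the plan uses BDA (the source batches are drawn from it).
#' @param sched a [train_schedule()].
#' @param mmd_cfg an [mmd_config()] for the adaptation terms.
#' @param target column of `Y` to model, as in [pretrain()].
#' @return A list with `net` and `history` (per-epoch `loss`, `mse`,
#'   `mda`, `cda`, `lr`).
#' @export
fine_tune <- function(net, plan, slave_train, master_train = NULL,
                      sched = train_schedule(), mmd_cfg = mmd_config(),
                      target = 1L) {
  stopifnot(inherits(net, "bdser_net"), inherits(plan, "transfer_plan"),
            inherits(sched, "train_schedule"))
  validate_spectra_set(slave_train)
  empty_hist <- data.frame(epoch = integer(0), loss = numeric(0),
                           mse = numeric(0), mda = numeric(0),
                           cda = numeric(0), lr = numeric(0))
  if (plan$strategy == 1L)
    return(list(net = net, history = empty_hist))
  if (plan$use_bda && is.null(master_train))
    stop("this plan uses BDA: master_train (source domain) is required")
  trainable <- group_order[!plan$freeze[group_order]]
  conv_frozen <- plan$freeze[["stem"]] && plan$freeze[["blocks"]]
  tcol <- resolve_target(slave_train, target)
  ys <- (slave_train$Y[, tcol] - net$y_center) / net$y_scale
  n_s <- nrow(slave_train$X)
  if (sched$epochs == 0L) return(list(net = net, history = empty_hist))
  lam1 <- plan$weights$lambda1
  lam2 <- plan$weights$lambda2
  # precompute frozen convolutional features
  f_s_all <- f_m_all <- NULL
  if (conv_frozen) {
    f_s_all <- conv_stack_fw(net, slave_train$X)$f
    if (plan$use_bda) f_m_all <- conv_stack_fw(net, master_train$X)$f
  }
  set.seed(sched$seed)
  perms <- lapply(seq_len(sched$epochs), function(e) sample.int(n_s))
  m_stream <- NULL
  if (plan$use_bda) {
    n_m <- nrow(master_train$X)
    steps_total <- sched$epochs * ceiling(n_s / min(sched$batch_size, n_s))
    need <- steps_total * min(sched$batch_size, n_s, n_m)
    set.seed(sched$seed + 1L)
    m_stream <- unlist(lapply(seq_len(ceiling(need / n_m) + 1L),
                              function(i) sample.int(n_m)))
  }
  set.seed(sched$seed + 2L)
  opt <- optimizer_new(net, trainable)
  ps <- list(lr = sched$lr, best = Inf, counter = 0L)
  bs <- min(sched$batch_size, n_s)
  p <- net$cfg$dropout_p
  D <- net$cfg$fc1_dims[1]
  H <- matrix(0, sched$epochs, 5,
              dimnames = list(NULL, c("loss", "mse", "mda", "cda", "lr")))
  mptr <- 0L
  for (e in seq_len(sched$epochs)) {
    perm <- perms[[e]]
    acc <- c(loss = 0, mse = 0, mda = 0, cda = 0)
    nsteps <- 0L
    for (s in seq.int(1L, n_s, by = bs)) {
      idx <- perm[s:min(s + bs - 1L, n_s)]
      nb <- length(idx)
      cs_cache_s <- NULL
      if (conv_frozen) {
        f_s <- f_s_all[, idx, drop = FALSE]
      } else {
        cs <- conv_stack_fw(net, slave_train$X[idx, , drop = FALSE],
                            want_cache = TRUE)
        f_s <- cs$f
        cs_cache_s <- cs$cache
      }
      mask <- if (p > 0) matrix((runif(D * nb) >= p) / (1 - p), D) else NULL
      hd_s <- head_fw(net$params, f_s, mask)
      r <- hd_s$raw - ys[idx]
      mse <- mean(r^2)
      dpred_s <- 2 * r / nb
      dfeat_s <- NULL
      g_master <- NULL
      mda <- cda <- 0
      if (plan$use_bda) {
        midx <- m_stream[mptr + seq_len(min(nb, length(m_stream) - mptr))]
        if (length(midx) < nb) midx <- rep_len(midx, nb)
        mptr <- mptr + nb
        cs_cache_m <- NULL
        if (conv_frozen) {
          f_m <- f_m_all[, midx, drop = FALSE]
        } else {
          csm <- conv_stack_fw(net, master_train$X[midx, , drop = FALSE],
                               want_cache = TRUE)
          f_m <- csm$f
          cs_cache_m <- csm$cache
        }
        hd_m <- head_fw(net$params, f_m, mask)
        mg <- mmd2_full(t(hd_m$h1), t(hd_s$h1), mmd_cfg, want_grad = TRUE)
        cg <- mmd2_full(matrix(hd_m$raw), matrix(hd_s$raw), mmd_cfg,
                        want_grad = TRUE)
        mda <- mg$value; cda <- cg$value
        dfeat_s <- lam1 * t(mg$dXt)
        dpred_s <- dpred_s + lam1 * lam2 * as.numeric(cg$dXt)
        hb_m <- head_bw(net$params, hd_m, lam1 * lam2 * as.numeric(cg$dXs),
                        lam1 * t(mg$dXs), mask)
        g_master <- list(hb = hb_m, cache = cs_cache_m)
      }
      hb_s <- head_bw(net$params, hd_s, dpred_s, dfeat_s, mask)
      gfc1 <- hb_s$gfc1; gfc2 <- hb_s$gfc2
      if (!is.null(g_master)) {
        gfc1 <- list(W = gfc1$W + g_master$hb$gfc1$W,
                     b = gfc1$b + g_master$hb$gfc1$b)
        gfc2 <- list(W = gfc2$W + g_master$hb$gfc2$W,
                     b = gfc2$b + g_master$hb$gfc2$b)
      }
      grads <- list(fc1 = gfc1, fc2 = gfc2)
      if (!conv_frozen) {
        cgs <- conv_stack_bw(net, cs_cache_s, hb_s$df)
        if (!is.null(g_master)) {
          cgm <- conv_stack_bw(net, g_master$cache, g_master$hb$df)
          cgs <- list(stem = ps_axpy(cgs$stem, cgm$stem),
                      blocks = ps_axpy(cgs$blocks, cgm$blocks))
        }
        grads$stem <- cgs$stem
        grads$blocks <- cgs$blocks
      }
      tot <- total_loss(mse, mda, cda, plan$weights)
      acc <- acc + c(tot, mse, mda, cda)
      nsteps <- nsteps + 1L
      up <- optimizer_apply(opt, net, grads, ps$lr)
      opt <- up$opt; net <- up$net
    }
    em <- acc / nsteps
    if (!is.finite(em[["loss"]]))
      stop("training diverged (non-finite loss) at epoch ", e)
    H[e, ] <- c(em, ps$lr)
    ps <- plateau_update(ps, em[["loss"]], sched)
  }
  list(net = net,
       history = data.frame(epoch = seq_len(sched$epochs),
                            loss = H[, "loss"], mse = H[, "mse"],
                            mda = H[, "mda"], cda = H[, "cda"],
                            lr = H[, "lr"]))
}
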