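#' Architecture hyperparameters for the multi-scale spectral network
#'
#' Collects the tunable dimensions of the regression network: the four
#' branch kernel sizes of each multi-scale (RX-Inception) block, the stem
#' convolution width, the per-block output channels, the adaptive-pool
#' output length and the fully connected head.
#'
#' The reference architecture is: stem convolution (`in_c` ->
#' `stem_out_c`, ReLU), a stack of multi-scale blocks (four parallel
#' depthwise-separable branches with kernels `kernels[1:4]`, channel
#' concatenation, pointwise fusion, squeeze-and-excitation recalibration,
#' residual connection with pointwise projection where shapes differ,
#' ReLU), adaptive average pooling to `pool_len`, dropout, and a
#' two-layer fully connected head whose first layer produces the
#' 100-dimensional feature vector used for distribution alignment.
#'
#' @param kernels four odd branch kernel sizes (M1-M4).
#' @param in_c input channels; spectra enter as a single channel.
#' @param stem_out_c stem output channels.
#' @param stem_kernel stem kernel size (odd).
#' @param block_channels output channels per block; each must be divisible
#'   by 4 (one quarter per branch). The last entry fixes the width feeding
#'   the head.
#' @param block_strides per-block stride; a stride of 2 in the first block
#'   realizes convolutional downsampling of the raw grid. Use all-1 to
#'   disable downsampling.
#' @param se_reduction squeeze-and-excitation bottleneck ratio.
#' @param pool_len adaptive average-pool output length (25 for 650/530
#'   point spectra, 256 for 700-point spectra in the reference configs).
#' @param dropout_p dropout probability applied after pooling.
#' @param fc1_out width of the first fully connected layer (the feature
#'   dimension), 100 in the reference configs.
#' @param fc1_dims,fc2_dims optional explicit head dimensions; validated
#'   against the rest of the configuration (a mismatch is a config error).
#' @return An object of class `model_config`.
#' @seealso [model_config_corn()], [model_config_tablet()], [build_model()]
#' @export
model_config <- function(kernels = c(3, 5, 13, 3), in_c = 1L,
                         stem_out_c = 16L, stem_kernel = 7L,
                         block_channels = c(32L, 64L, 100L),
                         block_strides = c(2L, 1L, 1L),
                         se_reduction = 4L, pool_len = 25L,
                         dropout_p = 0, fc1_out = 100L,
                         fc1_dims = NULL, fc2_dims = NULL) {
  kernels <- as.integer(kernels)
  if (length(kernels) != 4 || any(kernels < 1) || any(kernels %% 2 == 0))
    stop("config error: kernels must be four odd integers >= 1")
  if (stem_kernel %% 2 == 0) stop("config error: stem_kernel must be odd")
  if (in_c != 1L) stop("config error: spectra enter as a single channel (in_c = 1)")
  block_channels <- as.integer(block_channels)
  if (any(block_channels %% 4L != 0L))
    stop("config error: block_channels must be divisible by 4 (four branches)")
  block_strides <- as.integer(block_strides)
  if (length(block_strides) != length(block_channels))
    stop("config error: block_strides length must match block_channels")
  if (any(block_strides < 1)) stop("config error: strides must be >= 1")
  if (dropout_p < 0 || dropout_p >= 1)
    stop("config error: dropout_p must lie in [0, 1)")
  if (pool_len < 1) stop("config error: pool_len must be >= 1")
  flat <- tail(block_channels, 1) * as.integer(pool_len)
  if (is.null(fc1_dims)) fc1_dims <- c(flat, as.integer(fc1_out))
  if (fc1_dims[1] != flat)
    stop("config error: fc1 input width (", fc1_dims[1],
         ") must equal last block channels x pool_len (", flat, ")")
  if (is.null(fc2_dims)) fc2_dims <- c(fc1_dims[2], 1L)
  if (fc2_dims[1] != fc1_dims[2])
    stop("config error: fc2 input width must equal fc1 output width")
  structure(list(kernels = kernels, in_c = as.integer(in_c),
                 stem_out_c = as.integer(stem_out_c),
                 stem_kernel = as.integer(stem_kernel),
                 block_channels = block_channels,
                 block_strides = block_strides,
                 se_reduction = as.integer(se_reduction),
                 pool_len = as.integer(pool_len),
                 dropout_p = dropout_p,
                 fc1_dims = as.integer(fc1_dims),
                 fc2_dims = as.integer(fc2_dims)),
            class = "model_config")
}

#' Reference configuration for 700-point (corn-style) spectra
#'
#' Branch kernels 3/5/13/3, single input channel, 16 stem channels, no
#' dropout, head `(100 x 256, 100)` then `(100, 1)`.
#' @return A [model_config()].
#' @export
model_config_corn <- function() {
  model_config(kernels = c(3, 5, 13, 3), pool_len = 256L, dropout_p = 0)
}

#' Reference configuration for 650/530-point (tablet-style) spectra
#'
#' Branch kernels 5/9/15/3, single input channel, 16 stem channels,
#' dropout 0.5, head `(100 x 25, 100)` then `(100, 1)`.
#' @return A [model_config()].
#' @export
model_config_tablet <- function() {
  model_config(kernels = c(5, 9, 15, 3), pool_len = 25L, dropout_p = 0.5)
}

#' Build the multi-scale spectral regression network
#'
#' Instantiates the network described in [model_config()] with
#' He-style random initialization. Parameters are organized into four
#' named groups - `stem`, `blocks`, `fc1`, `fc2` - which are the unit of
#' freezing for the transfer strategies.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed; initialization is bit-reproducible for a
#'   fixed seed.
#' @param arch `"bdser"` for the multi-scale blocks, `"plain"` for the
#'   ablation in which each block is replaced by a single standard
#'   convolution of kernel `kernels[1]` (no attention, no residual).
#' @return An object of class `bdser_net`: the parameter tree (`params`),
#'   the configuration, the architecture tag, and the target scaling
#'   (`y_center`, `y_scale`) learned during [pretrain()].
#' @export
build_model <- function(cfg, seed = 1L, arch = c("bdser", "plain")) {
  stopifnot(inherits(cfg, "model_config"))
  arch <- match.arg(arch)
  set.seed(as.integer(seed))
  he <- function(nr, nc, fan) matrix(rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)
  params <- list()
  params$stem <- list(W = he(cfg$stem_out_c, cfg$stem_kernel, cfg$stem_kernel),
                      b = numeric(cfg$stem_out_c))
  in_c <- cfg$stem_out_c
  params$blocks <- vector("list", length(cfg$block_channels))
  for (i in seq_along(cfg$block_channels)) {
    out_c <- cfg$block_channels[i]
    if (arch == "bdser") {
      bc <- out_c %/% 4L
      br <- lapply(cfg$kernels, function(k)
        list(dW = he(in_c, k, k), db = numeric(in_c),
             pW = he(bc, in_c, in_c), pb = numeric(bc)))
      cr <- max(1L, out_c %/% cfg$se_reduction)
      blk <- list(br = br,
                  fW = he(out_c, out_c, out_c), fb = numeric(out_c),
                  se = list(W1 = he(cr, out_c, out_c), b1 = numeric(cr),
                            W2 = he(out_c, cr, cr), b2 = numeric(out_c)))
      if (in_c != out_c || cfg$block_strides[i] > 1) {
        blk$prW <- he(out_c, in_c, in_c)
        blk$prb <- numeric(out_c)
      } else {
        blk$prW <- NULL; blk$prb <- NULL
      }
    } else {
      k <- cfg$kernels[1]
      blk <- list(W = array(rnorm(out_c * in_c * k, 0, sqrt(2 / (in_c * k))),
                            c(out_c, in_c, k)),
                  b = numeric(out_c))
    }
    params$blocks[[i]] <- blk
    in_c <- out_c
  }
  params$fc1 <- list(W = he(cfg$fc1_dims[2], cfg$fc1_dims[1], cfg$fc1_dims[1]),
                     b = numeric(cfg$fc1_dims[2]))
  params$fc2 <- list(W = matrix(rnorm(cfg$fc2_dims[1], 0,
                                      sqrt(1 / cfg$fc2_dims[1])),
                                1, cfg$fc2_dims[1]),
                     b = numeric(1))
  structure(list(params = params, cfg = cfg, arch = arch,
                 y_center = 0, y_scale = 1),
            class = "bdser_net")
}

#' Ablation network: multi-scale blocks replaced by standard convolutions
#'
#' Identical pipeline to [build_model()] except that every multi-scale
#' block is swapped for one standard convolution of kernel `kernels[1]`
#' and the block's output width; the attention and residual structure is
#' removed with the block. The parameter groups remain
#' `{stem, blocks, fc1, fc2}` so all six transfer strategies apply
#' unchanged.
#'
#' @inheritParams build_model
#' @return A `bdser_net` with `arch = "plain"`.
#' @export
plain_cnn <- function(cfg, seed = 1L) build_model(cfg, seed, arch = "plain")

#' @export
print.bdser_net <- function(x, ...) {
  cat(sprintf("<bdser_net arch=%s> %d parameters\n", x$arch,
              count_parameters(x)))
  for (g in c("stem", "blocks", "fc1", "fc2"))
    cat(sprintf("  %-6s %d\n", g, count_parameters(x, g)))
  invisible(x)
}

#' Count network parameters by group
#'
#' @param net a [build_model()] result.
#' @param groups subset of `c("stem", "blocks", "fc1", "fc2")`.
#' @return Integer parameter count over the union of the groups.
#' @examples
#' \donttest{
#' net <- build_model(model_config_corn())
#' count_parameters(net, c("fc1", "fc2"))  # 2560201
#' }
#' @export
count_parameters <- function(net, groups = c("stem", "blocks", "fc1", "fc2")) {
  stopifnot(inherits(net, "bdser_net"))
  if (length(groups) == 0) return(0L)
  bad <- setdiff(groups, c("stem", "blocks", "fc1", "fc2"))
  if (length(bad)) stop("unknown parameter group(s): ", paste(bad, collapse = ", "))
  sum(vapply(unique(groups), function(g) ps_count(net$params[[g]]), numeric(1)))
}

#' Parameter counts of depthwise-separable vs standard 1-D convolution
#'
#' A depthwise-separable convolution (`in_c` depthwise kernels of size `k`
#' plus an `in_c -> out_c` pointwise mix, biases on both stages) against a
#' standard convolution of the same shape. For example, `in = 16`,
#' `out = 32`, `k = 3` gives 608 separable parameters vs 1568 standard.
#'
#' @param in_c,out_c,k channel counts and kernel size.
#' @return Integer parameter count.
#' @export
dsc_param_count <- function(in_c, out_c, k) {
  in_c * k + in_c + in_c * out_c + out_c
}

#' @rdname dsc_param_count
#' @export
std_conv_param_count <- function(in_c, out_c, k) {
  in_c * out_c * k + out_c
}

# ---- forward/backward machinery --------------------------------------------

# multi-scale block forward; cur is (C_in, L, N)
block_fw <- function(cur, bp, kernels, stride) {
  d <- dim(cur)
  nb <- length(bp$br)
  Dl <- vector("list", nb); Pl <- vector("list", nb)
  bc <- nrow(bp$br[[1]]$pW)
  Lo <- conv_out_len(d[2], kernels[1], stride)
  Cc <- array(0, c(bc * nb, Lo, d[3]))
  for (j in seq_len(nb)) {
    Dl[[j]] <- .dwconv_fw(cur, bp$br[[j]]$dW, bp$br[[j]]$db, stride,
                          same_pad(kernels[j]))
    Pl[[j]] <- pw_fw(Dl[[j]], bp$br[[j]]$pW, bp$br[[j]]$pb)
    Cc[(j - 1L) * bc + seq_len(bc), , ] <- relu(Pl[[j]])
  }
  Fz <- pw_fw(Cc, bp$fW, bp$fb)
  sec <- se_fw(Fz, bp$se)
  idx <- seq.int(1L, d[2], by = stride)
  Rin <- cur[, idx, , drop = FALSE]
  Rp <- if (!is.null(bp$prW)) pw_fw(Rin, bp$prW, bp$prb) else Rin
  Zb <- sec$Y + Rp
  list(out = relu(Zb), Dl = Dl, Pl = Pl, Cc = Cc, Fz = Fz, sec = sec,
       Rin = Rin, idx = idx, Zb = Zb, cur = cur)
}

block_bw <- function(cache, bp, kernels, stride, dout) {
  dZb <- dout
  dZb[cache$Zb <= 0] <- 0
  g <- list()
  # residual path
  if (!is.null(bp$prW)) {
    pr <- pw_bw(cache$Rin, bp$prW, dZb)
    dRin <- pr$dX; g$prW <- pr$dW; g$prb <- pr$db
  } else {
    dRin <- dZb; g$prW <- NULL; g$prb <- NULL
  }
  dcur <- array(0, dim(cache$cur))
  dcur[, cache$idx, ] <- dRin
  # attention path
  sb <- se_bw(cache$Fz, bp$se, cache$sec, dZb)
  g$se <- list(W1 = sb$dW1, b1 = sb$db1, W2 = sb$dW2, b2 = sb$db2)
  fu <- pw_bw(cache$Cc, bp$fW, sb$dX)
  g$fW <- fu$dW; g$fb <- fu$db
  dCc <- fu$dX
  nb <- length(bp$br)
  bc <- nrow(bp$br[[1]]$pW)
  g$br <- vector("list", nb)
  for (j in seq_len(nb)) {
    dRj <- dCc[(j - 1L) * bc + seq_len(bc), , , drop = FALSE]
    dPj <- dRj
    dPj[cache$Pl[[j]] <= 0] <- 0
    pwg <- pw_bw(cache$Dl[[j]], bp$br[[j]]$pW, dPj)
    dwg <- .dwconv_bw(cache$cur, bp$br[[j]]$dW, pwg$dX, stride,
                      same_pad(kernels[j]))
    dcur <- dcur + dwg$dX
    g$br[[j]] <- list(dW = dwg$dW, db = dwg$db, pW = pwg$dW, pb = pwg$db)
  }
  # reorder to match the parameter tree layout (br, fW, fb, se, prW, prb)
  list(grad = list(br = g$br, fW = g$fW, fb = g$fb, se = g$se,
                   prW = g$prW, prb = g$prb),
       dcur = dcur)
}

# stem + blocks + adaptive pool; returns flattened features f (D x N)
conv_stack_fw <- function(net, Xmat, want_cache = FALSE) {
  cfg <- net$cfg
  N <- nrow(Xmat); L <- ncol(Xmat)
  if (L < max(cfg$kernels, cfg$stem_kernel))
    stop("input has fewer wavelengths (", L, ") than the largest kernel")
  A <- array(t(Xmat), c(1L, L, N))
  Xt <- A[rep(1L, cfg$stem_out_c), , , drop = FALSE]
  Z0 <- .dwconv_fw(Xt, net$params$stem$W, net$params$stem$b, 1L,
                   same_pad(cfg$stem_kernel))
  cur <- relu(Z0)
  bcaches <- vector("list", length(net$params$blocks))
  for (i in seq_along(net$params$blocks)) {
    if (net$arch == "bdser") {
      bcaches[[i]] <- block_fw(cur, net$params$blocks[[i]], cfg$kernels,
                               cfg$block_strides[i])
      cur <- bcaches[[i]]$out
    } else {
      Zi <- fullconv_fw(cur, net$params$blocks[[i]]$W,
                        net$params$blocks[[i]]$b, cfg$block_strides[i])
      bcaches[[i]] <- list(cur = cur, Z = Zi)
      cur <- relu(Zi)
    }
  }
  dpool <- dim(cur)
  A_pool <- pool_matrix(dpool[2], cfg$pool_len)
  pooled <- pool_fw(cur, A_pool)
  f <- matrix(pooled, dpool[1] * cfg$pool_len, N)
  cache <- if (want_cache)
    list(Xt = Xt, Z0 = Z0, bcaches = bcaches, A_pool = A_pool,
         L_last = dpool[2], C_last = dpool[1]) else NULL
  list(f = f, cache = cache)
}

conv_stack_bw <- function(net, cache, df) {
  cfg <- net$cfg
  N <- ncol(df)
  dpooled <- array(df, c(cache$C_last, cfg$pool_len, N))
  dcur <- pool_bw(dpooled, cache$A_pool, cache$L_last)
  gblocks <- vector("list", length(net$params$blocks))
  for (i in rev(seq_along(net$params$blocks))) {
    if (net$arch == "bdser") {
      bb <- block_bw(cache$bcaches[[i]], net$params$blocks[[i]],
                     cfg$kernels, cfg$block_strides[i], dcur)
      gblocks[[i]] <- bb$grad
      dcur <- bb$dcur
    } else {
      dZ <- dcur
      dZ[cache$bcaches[[i]]$Z <= 0] <- 0
      fb <- fullconv_bw(cache$bcaches[[i]]$cur, net$params$blocks[[i]]$W,
                        dZ, cfg$block_strides[i])
      gblocks[[i]] <- list(W = fb$dW, b = fb$db)
      dcur <- fb$dX
    }
  }
  dZ0 <- dcur
  dZ0[cache$Z0 <= 0] <- 0
  sg <- .dwconv_bw(cache$Xt, net$params$stem$W, dZ0, 1L,
                   same_pad(net$cfg$stem_kernel))
  list(stem = list(W = sg$dW, b = sg$db), blocks = gblocks)
}

head_fw <- function(params, f, mask = NULL) {
  fd <- if (is.null(mask)) f else f * mask
  a1 <- params$fc1$W %*% fd + params$fc1$b
  h1 <- relu(a1)
  raw <- as.numeric(params$fc2$W %*% h1 + params$fc2$b)
  list(h1 = h1, raw = raw, a1 = a1, fd = fd)
}

head_bw <- function(params, hc, dpred, dfeat = NULL, mask = NULL) {
  dpred <- matrix(dpred, 1)
  gfc2 <- list(W = tcrossprod(dpred, hc$h1), b = sum(dpred))
  dh1 <- crossprod(params$fc2$W, dpred)
  if (!is.null(dfeat)) dh1 <- dh1 + dfeat
  da1 <- dh1
  da1[hc$a1 <= 0] <- 0
  gfc1 <- list(W = tcrossprod(da1, hc$fd), b = rowSums(da1))
  df <- crossprod(params$fc1$W, da1)
  if (!is.null(mask)) df <- df * mask
  list(gfc1 = gfc1, gfc2 = gfc2, df = df)
}

#' Run the network forward and expose features and predictions
#'
#' Evaluates the network in deterministic (eval) mode on a batch of
#' spectra. The returned `features` are the activations of the first fully
#' connected layer - the representation used for marginal distribution
#' alignment during transfer - and `predictions` are the scalar outputs on
#' the original target scale.
#'
#' @param net a [build_model()] (or [pretrain()]) network.
#' @param X numeric matrix of spectra (samples by wavelengths) or a
#'   [spectra_set()].
#' @return A list with `features` (n x fc1 width) and `predictions`
#'   (n x 1).
#' @export
net_forward <- function(net, X) {
  stopifnot(inherits(net, "bdser_net"))
  if (inherits(X, "spectra_set")) X <- X$X
  X <- as.matrix(X)
  cs <- conv_stack_fw(net, X)
  hd <- head_fw(net$params, cs$f)
  list(features = t(hd$h1),
       predictions = matrix(hd$raw * net$y_scale + net$y_center, ncol = 1))
}

#' Predict reference values from spectra
#'
#' @param object a `bdser_net`.
#' @param newdata spectra matrix or [spectra_set()].
#' @param ... unused.
#' @return Numeric vector of predictions on the original target scale.
#' @export
predict.bdser_net <- function(object, newdata, ...) {
  as.numeric(net_forward(object, newdata)$predictions)
}

#' Extract squeeze-and-excitation channel gates
#'
#' Returns, per multi-scale block, the sigmoid channel gates computed for
#' each sample; all values lie strictly in (0, 1).
#'
#' @param net a `bdser_net` with `arch = "bdser"`.
#' @param X spectra matrix or [spectra_set()].
#' @return A list (one element per block) of channels-by-samples matrices.
#' @export
se_gates <- function(net, X) {
  stopifnot(inherits(net, "bdser_net"))
  if (net$arch != "bdser") stop("the plain ablation has no attention gates")
  if (inherits(X, "spectra_set")) X <- X$X
  cs <- conv_stack_fw(net, as.matrix(X), want_cache = TRUE)
  lapply(cs$cache$bcaches, function(bc) bc$sec$g)
}
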