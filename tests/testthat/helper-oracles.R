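# Independent oracles and tiny fixtures used across the suite.

# Exhaustive max-min Kennard-Stone re-implementation: at every step scan
# all candidates and all selected samples directly.
ks_brute_force <- function(D, n_train) {
  n <- nrow(D)
  best_pair <- c(1L, 2L)
  best_d <- -Inf
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1L, n)) {
    if (D[i, j] > best_d) {
      best_d <- D[i, j]
      best_pair <- c(i, j)
    }
  }
  sel <- best_pair
  while (length(sel) < n_train) {
    cand <- setdiff(seq_len(n), sel)
    scores <- vapply(cand, function(i) min(D[i, sel]), numeric(1))
    sel <- c(sel, cand[which.max(scores)])
  }
  sel
}

# Explicit double-sum MMD^2 with a Gaussian kernel of bandwidth s.
mmd2_double_sum <- function(Xs, Xt, s) {
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * s^2))
  n <- nrow(Xs); m <- nrow(Xt)
  kss <- ktt <- kst <- 0
  for (a in seq_len(n)) for (b in seq_len(n))
    kss <- kss + k(Xs[a, ], Xs[b, ])
  for (a in seq_len(m)) for (b in seq_len(m))
    ktt <- ktt + k(Xt[a, ], Xt[b, ])
  for (a in seq_len(n)) for (b in seq_len(m))
    kst <- kst + k(Xs[a, ], Xt[b, ])
  kss / n^2 + ktt / m^2 - 2 * kst / (n * m)
}

# small network configuration for fast training tests
tiny_cfg <- function(dropout_p = 0) {
  model_config(kernels = c(3, 5, 7, 3), stem_out_c = 4L, stem_kernel = 3L,
               block_channels = c(8L, 8L), block_strides = c(1L, 1L),
               pool_len = 4L, dropout_p = dropout_p, fc1_out = 8L)
}

# small paired-instrument scenario on a short grid
tiny_scenario <- function(seed = 1, n = 24, noise_sd = 0.001) {
  wl <- seq(1100, by = 2, length.out = 40)
  prof <- generate_component_profiles(2, wl, peaks_per_component = 3,
                                      peak_width_range = c(10, 40),
                                      seed = seed)
  master <- generate_master_spectra(prof, n, list(c(0, 1), c(0, 1)),
                                    baseline_amp = 0, noise_sd = noise_sd,
                                    seed = seed + 1)
  tr <- instrument_transform(shift_nm = 4, broaden_sigma_nm = 4, gain = 1.3,
                             offset = 0.1, scatter_sd = 0.02,
                             noise_sd = noise_sd, seed = seed + 2)
  list(master = master, slave = apply_instrument_transform(master, tr))
}

flatten_group <- function(net, g) specshift:::ps_flatten(net$params[[g]])
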