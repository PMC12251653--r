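#' Benchmark run configuration
#'
#' Assembles and validates the configuration of the end-to-end benchmark:
#' simulation preset (or externally loaded data), target, split, optional
#' outlier screen, model architecture, training schedule, transfer
#' settings and output directory. Unknown fields are rejected.
#'
#' Default epochs are desk scale (200 for `corn-like`, 60 for
#' `tablet-like`); set `paper_epochs = TRUE` for the full reference
#' schedule (1000 / 300).
#'
#' @param preset `"corn-like"` or `"tablet-like"` (simulated data), or
#'   `"none"` when `data` supplies spectra sets directly.
#' @param data optional list with elements `master` and `slaves` (a named
#'   list), each a [spectra_set()]; used when `preset = "none"`.
#' @param target target column (index or name).
#' @param split list with `method` (`"ks"`, `"spxy"` or `"random"`) and
#'   `ratio`.
#' @param screen list with `enabled`, `threshold`, `components`; the
#'   leave-one-out screen runs on the master set before splitting.
#' @param model a [model_config()]; `NULL` picks the preset-matched
#'   reference config.
#' @param epochs pre-training epochs; `transfer_epochs` defaults to the
#'   same value.
#' @param transfer_epochs fine-tuning epochs.
#' @param batch_size minibatch size; `NULL` picks the preset default
#'   (8 corn-like, 128 tablet-like).
#' @param strategies integer vector of transfer strategies to run.
#' @param weights a [loss_weights()].
#' @param mmd an [mmd_config()].
#' @param baselines logical; also fit PLS/SVR and the classical transfer
#'   trio (DS, PDS, SBC with a PLS master model).
#' @param paper_epochs logical; restore the full-length reference
#'   schedule.
#' @param out_dir optional output directory for CSV/JSON results.
#' @param seed integer seed for simulation and training.
#' @return A validated list of class `run_config`.
#' @export
benchmark_config <- function(preset = "corn-like", data = NULL,
                             target = 1L,
                             split = list(method = "ks", ratio = 0.8),
                             screen = list(enabled = FALSE, threshold = 30,
                                           components = 5L),
                             model = NULL, epochs = NULL,
                             transfer_epochs = NULL, batch_size = NULL,
                             strategies = 1:6,
                             weights = loss_weights(),
                             mmd = mmd_config(),
                             baselines = TRUE, paper_epochs = FALSE,
                             out_dir = NULL, seed = 1L) {
  if (!preset %in% c("corn-like", "tablet-like", "none"))
    stop("unknown preset: ", preset)
  if (preset == "none" && is.null(data))
    stop("preset 'none' requires data = list(master = ..., slaves = ...)")
  stopifnot(split$method %in% c("ks", "spxy", "random"),
            split$ratio > 0, split$ratio < 1,
            all(strategies %in% 1:6))
  cornish <- !identical(preset, "tablet-like")
  if (is.null(epochs))
    epochs <- if (paper_epochs) (if (cornish) 1000L else 300L)
              else (if (cornish) 200L else 60L)
  if (is.null(transfer_epochs)) transfer_epochs <- epochs
  if (is.null(batch_size)) batch_size <- if (cornish) 8L else 128L
  if (is.null(model))
    model <- if (cornish) model_config_corn() else model_config_tablet()
  structure(list(preset = preset, data = data, target = target,
                 split = split, screen = screen, model = model,
                 epochs = as.integer(epochs),
                 transfer_epochs = as.integer(transfer_epochs),
                 batch_size = as.integer(batch_size),
                 strategies = as.integer(strategies), weights = weights,
                 mmd = mmd, baselines = baselines,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a benchmark configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [benchmark_config()]; unknown keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @param overrides named list of values overriding the file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(benchmark_config)), c("data", "model",
                                                       "weights", "mmd"))
  extra <- c("lambda1", "lambda2", "kernel", "bandwidth", "model")
  bad <- setdiff(names(raw), c(known, extra))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(overrides)) raw[[nm]] <- overrides[[nm]]
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$lambda1) || !is.null(raw$lambda2))
    args$weights <- loss_weights(raw$lambda1 %||% 1, raw$lambda2 %||% 1)
  if (!is.null(raw$kernel) || !is.null(raw$bandwidth))
    args$mmd <- if (!is.null(raw$bandwidth))
      mmd_config(raw$kernel %||% "rbf", "fixed", raw$bandwidth)
    else mmd_config(raw$kernel %||% "rbf")
  if (!is.null(raw$model)) args$model <- do.call(model_config, raw$model)
  do.call(benchmark_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end calibration-transfer benchmark
#'
#' Executes the full experimental grid on simulated (or supplied)
#' paired-instrument data: optional outlier screen, calibration/test
#' split per instrument, pre-training on the master, every requested
#' transfer strategy on every slave, and the baselines (PLS and SVR
#' trained on the master; DS, PDS and SBC built around a PLS master model
#' with the slave training samples as transfer standards). Per-strategy
#' and per-model metric tables are returned and, when `out_dir` is set,
#' written as CSV along with the resolved configuration as JSON.
#'
#' @param cfg a [benchmark_config()].
#' @return A list with `transfer` (per strategy x slave metrics),
#'   `models` (direct-prediction metrics of the network and the
#'   baselines on master and slaves), `classical` (DS/PDS/SBC transfer
#'   metrics), `master_eval`, the fitted `net`, and the `splits` used.
#' @export
run_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$preset == "none") {
    master <- cfg$data$master
    slaves <- cfg$data$slaves
  } else {
    sim <- simulate_transfer_scenario(cfg$preset, seed = cfg$seed)
    master <- sim$master
    slaves <- sim$slaves
  }
  tcol <- resolve_target(master, cfg$target)
  target_name <- master$target_names[tcol]
  # outlier screen on the master set (before splitting)
  screen_report <- NULL
  if (isTRUE(cfg$screen$enabled)) {
    screen_report <- loo_pls_outlier_screen(master$X, master$Y[, tcol],
                                            cfg$screen$components,
                                            cfg$screen$threshold)
    keep <- setdiff(seq_len(nrow(master$X)), screen_report$removed_indices)
    master <- subset_samples(master, keep)
    slaves <- lapply(slaves, subset_samples, i = keep)
  }
  do_split <- function(set) {
    switch(cfg$split$method,
           ks = kennard_stone_split(set$X, cfg$split$ratio),
           spxy = spxy_split(set$X, set$Y, cfg$split$ratio),
           random = random_split(nrow(set$X), cfg$split$ratio,
                                 seed = cfg$seed))
  }
  splits <- c(list(master = do_split(master)), lapply(slaves, do_split))
  m_tr <- subset_samples(master, splits$master$train_indices)
  m_te <- subset_samples(master, splits$master$test_indices)
  sched <- train_schedule(batch_size = cfg$batch_size, epochs = cfg$epochs,
                          seed = cfg$seed)
  pt <- pretrain(cfg$model, m_tr, sched, target = tcol)
  master_eval <- evaluate_model(pt$net, m_te, tcol)
  ft_sched <- train_schedule(batch_size = cfg$batch_size,
                             epochs = cfg$transfer_epochs, seed = cfg$seed)
  transfer_rows <- list()
  for (sl_name in names(slaves)) {
    sl <- slaves[[sl_name]]
    sp <- splits[[sl_name]]
    sl_tr <- subset_samples(sl, sp$train_indices)
    sl_te <- subset_samples(sl, sp$test_indices)
    for (st in cfg$strategies) {
      plan <- make_plan(st, cfg$weights)
      ft <- fine_tune(pt$net, plan, sl_tr,
                      master_train = if (plan$use_bda) m_tr else NULL,
                      sched = ft_sched, mmd_cfg = cfg$mmd, target = tcol)
      ev <- evaluate_model(ft$net, sl_te, tcol)
      transfer_rows[[length(transfer_rows) + 1L]] <-
        data.frame(slave = sl_name, strategy = st, target = target_name,
                   r2 = ev$r2, rmse = ev$rmse, mae = ev$mae, n = ev$n)
    }
  }
  transfer_tab <- do.call(rbind, transfer_rows)
  models_tab <- NULL
  classical_tab <- NULL
  if (isTRUE(cfg$baselines)) {
    pls <- pls_fit(m_tr$X, m_tr$Y[, tcol])
    svr <- svr_fit(m_tr$X, m_tr$Y[, tcol])
    mrows <- list()
    eval_on <- function(model, name, set, inst) {
      sp <- splits[[inst]]
      te <- subset_samples(set, sp$test_indices)
      ev <- evaluate_model(model, te, tcol)
      data.frame(model = name, instrument = inst, target = target_name,
                 r2 = ev$r2, rmse = ev$rmse, mae = ev$mae, n = ev$n)
    }
    for (mdl in list(list(pls, "pls"), list(svr, "svr"),
                     list(pt$net, "network"))) {
      mrows[[length(mrows) + 1L]] <- eval_on(mdl[[1]], mdl[[2]], master,
                                             "master")
      for (sl_name in names(slaves))
        mrows[[length(mrows) + 1L]] <- eval_on(mdl[[1]], mdl[[2]],
                                               slaves[[sl_name]], sl_name)
    }
    models_tab <- do.call(rbind, mrows)
    crows <- list()
    for (sl_name in names(slaves)) {
      sl <- slaves[[sl_name]]
      sp <- splits[[sl_name]]
      std_idx <- sp$train_indices
      sl_te <- subset_samples(sl, sp$test_indices)
      y_te <- sl_te$Y[, tcol]
      ds <- ds_fit(master$X[std_idx, , drop = FALSE],
                   sl$X[std_idx, , drop = FALSE])
      pds <- pds_fit(master$X[std_idx, , drop = FALSE],
                     sl$X[std_idx, , drop = FALSE], window = 5L)
      sbc <- sbc_fit(sl$Y[std_idx, tcol],
                     predict(pls, sl$X[std_idx, , drop = FALSE]))
      preds <- list(
        ds = predict(pls, ds_apply(ds, sl_te$X)),
        pds = predict(pls, pds_apply(pds, sl_te$X)),
        sbc = sbc_apply(sbc, predict(pls, sl_te$X)))
      for (nm in names(preds)) {
        ev <- evaluate(y_te, preds[[nm]])
        crows[[length(crows) + 1L]] <-
          data.frame(method = nm, slave = sl_name, target = target_name,
                     r2 = ev$r2, rmse = ev$rmse, mae = ev$mae, n = ev$n)
      }
    }
    classical_tab <- do.call(rbind, crows)
  }
  out <- list(transfer = transfer_tab, models = models_tab,
              classical = classical_tab, master_eval = master_eval,
              net = pt$net, splits = splits, screen = screen_report,
              config = cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(transfer_tab,
                     file.path(cfg$out_dir, "transfer_results.csv"),
                     row.names = FALSE)
    if (!is.null(models_tab))
      utils::write.csv(models_tab,
                       file.path(cfg$out_dir, "model_results.csv"),
                       row.names = FALSE)
    if (!is.null(classical_tab))
      utils::write.csv(classical_tab,
                       file.path(cfg$out_dir, "classical_results.csv"),
                       row.names = FALSE)
    resolved <- cfg
    resolved$data <- NULL
    jsonlite::write_json(resolved,
                         file.path(cfg$out_dir, "resolved_config.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA)
  }
  out
}
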