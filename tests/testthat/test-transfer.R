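tiny_sets <- function(seed = 1) {
  sc <- tiny_scenario(seed = seed)
  sp <- kennard_stone_split(sc$master$X, 0.75)
  list(m_tr = subset_samples(sc$master, sp$train_indices),
       m_te = subset_samples(sc$master, sp$test_indices),
       s_tr = subset_samples(sc$slave, sp$train_indices),
       s_te = subset_samples(sc$slave, sp$test_indices))
}

test_that("transfer plans encode the six strategies", {
  p1 <- make_plan(1)
  expect_true(all(p1$freeze))
  expect_false(p1$use_bda)
  expect_true(all(!make_plan(2)$freeze))
  p3 <- make_plan(3)
  expect_equal(unname(p3$freeze), c(TRUE, TRUE, FALSE, TRUE))
  p4 <- make_plan(4)
  expect_equal(unname(p4$freeze), c(TRUE, TRUE, TRUE, FALSE))
  p5 <- make_plan(5)
  expect_equal(unname(p5$freeze), c(TRUE, TRUE, FALSE, FALSE))
  expect_false(p5$use_bda)
  p6 <- make_plan(6)
  expect_identical(p6$freeze, p5$freeze)
  expect_true(p6$use_bda)
  expect_error(make_plan(7), "1..6")
})

test_that("plateau rule halves after patience epochs without improvement", {
  expect_equal(plateau_scheduler(c(1, rep(1, 30)), 30, 0.5, 0.001), 5e-4)
  expect_equal(plateau_scheduler(seq(2, 1, length.out = 50), 30, 0.5, 0.01),
               0.01)
  expect_equal(plateau_scheduler(c(1, rep(1, 29), 0.5), 30, 0.5, 0.001),
               0.001)
  expect_error(plateau_scheduler(numeric(0), 30, 0.5, 1e-3), "empty")
})

test_that("zero-epoch pretraining returns the initial parameters", {
  ts <- tiny_sets(2)
  pt <- pretrain(tiny_cfg(), ts$m_tr, train_schedule(epochs = 0, seed = 5))
  expect_identical(pt$net$params, build_model(tiny_cfg(), seed = 5)$params)
  expect_equal(nrow(pt$history), 0L)
})

test_that("training history has one row per epoch and is seed-reproducible", {
  ts <- tiny_sets(3)
  sch <- train_schedule(batch_size = 6, epochs = 12, seed = 21)
  pt1 <- pretrain(tiny_cfg(0.3), ts$m_tr, sch)
  pt2 <- pretrain(tiny_cfg(0.3), ts$m_tr, sch)
  expect_equal(nrow(pt1$history), 12L)
  expect_identical(pt1$history, pt2$history)
  expect_identical(pt1$net$params, pt2$net$params)
  ft1 <- fine_tune(pt1$net, make_plan(6), ts$s_tr, ts$m_tr,
                   train_schedule(batch_size = 6, epochs = 8, seed = 4))
  ft2 <- fine_tune(pt1$net, make_plan(6), ts$s_tr, ts$m_tr,
                   train_schedule(batch_size = 6, epochs = 8, seed = 4))
  expect_identical(ft1$history, ft2$history)
})

test_that("pretraining fits noiseless linear spectra to high accuracy", {
  wl <- seq(1100, by = 2, length.out = 40)
  prof <- generate_component_profiles(2, wl, seed = 8)
  m <- generate_master_spectra(prof, 32, list(c(0, 1), c(0, 1)),
                               baseline_amp = 0, noise_sd = 0, seed = 9)
  cfg <- model_config(kernels = c(3, 5, 7, 3), stem_out_c = 4L,
                      stem_kernel = 3L, block_channels = c(8L, 8L),
                      block_strides = c(1L, 1L), pool_len = 4L,
                      dropout_p = 0, fc1_out = 16L)
  pt <- pretrain(cfg, m, train_schedule(batch_size = 8, epochs = 400,
                                        seed = 1))
  expect_gte(evaluate_model(pt$net, m, 1)$r2, 0.99)
  # the loss history is monotone-ish: final loss far below the initial one
  expect_lt(tail(pt$history$loss, 1), 0.05 * pt$history$loss[1])
})

test_that("frozen groups are bit-identical after fine-tuning; strategy 1 is inert", {
  ts <- tiny_sets(4)
  pt <- pretrain(tiny_cfg(0.2), ts$m_tr,
                 train_schedule(batch_size = 6, epochs = 4, seed = 2))
  sch <- train_schedule(batch_size = 6, epochs = 2, seed = 3)  # ~20 steps
  for (st in 1:6) {
    plan <- make_plan(st)
    ft <- fine_tune(pt$net, plan, ts$s_tr,
                    master_train = if (plan$use_bda) ts$m_tr else NULL,
                    sched = sch)
    for (g in names(plan$freeze)) {
      if (plan$freeze[[g]]) {
        expect_identical(ft$net$params[[g]], pt$net$params[[g]],
                         label = sprintf("strategy %d group %s", st, g))
      } else {
        expect_false(identical(ft$net$params[[g]], pt$net$params[[g]]),
                     label = sprintf("strategy %d group %s changed", st, g))
      }
    }
    if (st == 1) {
      expect_identical(ft$net$params, pt$net$params)
      expect_identical(predict(ft$net, ts$s_te$X), predict(pt$net, ts$s_te$X))
      expect_equal(nrow(ft$history), 0L)
    }
  }
})

test_that("strategy 6 with lambda1 = 0 follows the strategy-5 trajectory", {
  ts <- tiny_sets(5)
  pt <- pretrain(tiny_cfg(0.3), ts$m_tr,
                 train_schedule(batch_size = 6, epochs = 4, seed = 7))
  sch <- train_schedule(batch_size = 6, epochs = 6, seed = 11)
  ft5 <- fine_tune(pt$net, make_plan(5), ts$s_tr, sched = sch)
  ft6 <- fine_tune(pt$net, make_plan(6, loss_weights(0, 1)), ts$s_tr,
                   master_train = ts$m_tr, sched = sch)
  expect_equal(ft6$net$params, ft5$net$params, tolerance = 1e-12)
  expect_equal(ft6$history$mse, ft5$history$mse, tolerance = 1e-12)
  expect_equal(ft6$history$loss, ft5$history$loss, tolerance = 1e-12)
})

test_that("BDA requires source-domain data and lowers feature discrepancy", {
  ts <- tiny_sets(6)
  pt <- pretrain(tiny_cfg(), ts$m_tr,
                 train_schedule(batch_size = 6, epochs = 4, seed = 1))
  expect_error(fine_tune(pt$net, make_plan(6), ts$s_tr, sched =
                           train_schedule(epochs = 2, seed = 1)),
               "master_train")
  ft <- fine_tune(pt$net, make_plan(6), ts$s_tr, ts$m_tr,
                  train_schedule(batch_size = 6, epochs = 30, seed = 2))
  h <- ft$history
  expect_true(all(is.finite(h$mda)) && all(is.finite(h$cda)))
  # the alignment terms are driven down over training
  expect_lt(mean(tail(h$mda, 5)), mean(head(h$mda, 5)))
})
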