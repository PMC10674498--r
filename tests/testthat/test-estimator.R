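test_that("training on a learnable toy set decreases the loss", {
  trips <- toy_triplets(200, size = 16L, seed = 41)
  cfg <- estimator_config(epochs = 5, input_size = 16L, seed = 2, lr = 2e-3)
  fit <- fit_zernike_estimator(trips, cfg, split = 0.8)
  expect_s3_class(fit, "zernike_estimator")
  expect_equal(fit$n_train, 160)
  expect_equal(fit$n_val, 40)
  expect_equal(nrow(fit$history), 6)              # epoch 0 baseline + 5
  tr <- fit$history$train_loss[-1]
  expect_gte(sum(diff(tr) < 0), 4 - 1)            # monotone trend, >= 4 of 5 ok
  expect_lt(tr[5], tr[1])
})

test_that("training is deterministic under a fixed seed", {
  trips <- toy_triplets(60, size = 16L, seed = 42)
  cfg <- estimator_config(epochs = 1, input_size = 16L, seed = 3)
  f1 <- fit_zernike_estimator(trips, cfg, split = 0.8)
  f2 <- fit_zernike_estimator(trips, cfg, split = 0.8)
  expect_identical(f1$history$train_loss[2], f2$history$train_loss[2])
  expect_identical(f1$history$val_loss, f2$history$val_loss)
})

test_that("prediction rescales by the divisors and preserves order", {
  trips <- toy_triplets(40, size = 16L, seed = 43)
  cfg <- estimator_config(epochs = 1, input_size = 16L, seed = 4)
  fit <- fit_zernike_estimator(trips, cfg, split = 0.8)
  expect_equal(fit$divisors, c(pi, 1200, 1200, rep(48, 7)))
  p_all <- predict(fit, trips[1:8])
  expect_equal(dim(p_all), c(8L, 10L))
  # batch order preserved: predicting a subset matches the batch rows
  p_sub <- predict(fit, trips[c(3, 6)])
  expect_equal(p_sub[1, ], p_all[3, ], tolerance = 1e-10)
  expect_equal(p_sub[2, ], p_all[6, ], tolerance = 1e-10)
  # single-triplet convenience form
  p1 <- predict(fit, trips[[5]])
  expect_equal(unname(p1), unname(p_all[5, ]), tolerance = 1e-10)
  # divisor pathway: scaled outputs times divisors equal predictions
  X <- sadhm:::apply_input_transform(sadhm:::triplets_to_array(trips[5], 16L),
                                     fit$config$fourier_log)
  raw <- sadhm:::net_forward(fit$ops, X, training = FALSE)$out
  expect_equal(unname(p1), as.numeric(raw * fit$divisors), tolerance = 1e-10)
})

test_that("the error table has the documented shape and aggregates", {
  trips <- toy_triplets(30, size = 16L, seed = 44)
  cfg <- estimator_config(epochs = 1, input_size = 16L, seed = 5)
  fit <- fit_zernike_estimator(trips, cfg, split = 0.8)
  f <- tempfile(fileext = ".csv")
  tab <- evaluate_estimator(fit, trips, out_csv = f)
  expect_equal(nrow(tab), 30 * 10)
  expect_named(tab, c("sample_id", "n", "true", "predicted",
                      "abs_err", "rel_err"))
  expect_equal(tab$abs_err, abs(tab$predicted - tab$true))
  agg <- attr(tab, "aggregates")
  expect_equal(nrow(agg), 10)
  expect_true(all(agg$max_abs_err >= agg$mean_abs_err))
  expect_true(file.exists(f)); unlink(f)
})

test_that("model artifacts reload to identical predictions", {
  trips <- toy_triplets(30, size = 16L, seed = 45)
  cfg <- estimator_config(epochs = 2, input_size = 16L, seed = 6)
  fit <- fit_zernike_estimator(trips, cfg, split = 0.8)
  d <- withr::local_tempdir()
  save_estimator(fit, d)
  back <- load_estimator(d)
  expect_equal(predict(back, trips[1:4]), predict(fit, trips[1:4]),
               tolerance = 1e-12)
})

test_that("the resnet50-style architecture builds and runs forward", {
  ops <- sadhm:::init_params(sadhm:::build_arch("resnet50"))
  types <- vapply(ops, function(o) o$type, "")
  expect_equal(sum(types == "add"), 16)           # 3+4+6+3 bottleneck blocks
  expect_equal(ops[[length(ops)]]$out_ch, 10L)
  # forward pass on a small batch at reduced input size (size-agnostic ops)
  X <- array(stats::rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  out <- sadhm:::net_forward(ops, X, training = FALSE)$out
  expect_equal(dim(out), c(10L, 2L))
  expect_true(all(is.finite(out)))
})
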