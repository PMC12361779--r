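test_that("learning-rate schedules match their closed forms", {
  cfg <- train_config(schedule = "cosine", lr0 = 0.001, epochs = 100,
                      eta_min = 0)
  expect_equal(lr_schedule(0, cfg), 0.001)
  expect_equal(lr_schedule(100, cfg), 0)
  expect_equal(lr_schedule(50, cfg), 0.0005)   # cos(pi/2) = 0
  cfg2 <- train_config(schedule = "cosine", lr0 = 0.01, eta_min = 0.002,
                       epochs = 10)
  for (e in 0:10)
    expect_equal(lr_schedule(e, cfg2),
                 0.002 + 0.008 * (1 + cos(pi * e / 10)) / 2)
  cfgl <- train_config(schedule = "lambda_decay", lr0 = 0.001,
                       lambda_gamma = 0.9, epochs = 10)
  expect_equal(lr_schedule(3, cfgl), 0.001 * 0.9^3)
  expect_error(lr_schedule(11, cfgl), "epoch")
  expect_error(lr_schedule(-1, cfgl), "epoch")
})

test_that("fit reduces loss, logs the lr trace and is seed-reproducible", {
  ds <- two_class_tensor()
  set.seed(71)
  m <- tiny_model(2)
  cfg <- train_config(optimizer = "sgd", lr0 = 0.05, epochs = 5, batch = 8,
                      schedule = "lambda_decay", lambda_gamma = 0.9,
                      seed = 7)
  log <- fit(m, ds, ds, cfg)
  expect_lt(log$log$train_loss[5], log$log$train_loss[1])
  expect_equal(log$log$lr, 0.05 * 0.9^(0:4), tolerance = 1e-9)
  # same seed, fresh model: identical epoch-1 loss
  set.seed(71)
  m2 <- tiny_model(2)
  log2 <- fit(m2, ds, ds, cfg)
  expect_equal(log$log$train_loss[1], log2$log$train_loss[1],
               tolerance = 1e-6)
  # both optimizers descend
  set.seed(71)
  m3 <- tiny_model(2)
  cfga <- train_config(optimizer = "adam", lr0 = 0.005, epochs = 3,
                       batch = 8, schedule = "none", seed = 7)
  loga <- fit(m3, ds, ds, cfga)
  expect_lt(loga$log$train_loss[3], loga$log$train_loss[1])
})

test_that("fully frozen models are bit-identical after an epoch", {
  ds <- two_class_tensor(n_per = 8)
  set.seed(72)
  m <- tiny_model(2)
  before <- cgenet:::collect_weights(m)
  cfg <- train_config(epochs = 1, batch = 8, seed = 1, freeze = "net")
  fit(m, ds, ds, cfg)
  after <- cgenet:::collect_weights(m)
  for (id in names(before))
    for (wn in setdiff(names(before[[id]]), c("run_mean", "run_var")))
      expect_identical(before[[id]][[wn]], after[[id]][[wn]])
})

test_that("mean loss is batch-size invariant on a frozen forward", {
  ds <- two_class_tensor(n_per = 8)
  set.seed(73)
  m <- tiny_model(2)
  e1 <- cgenet:::eval_dataset(m, ds, batch = 4)
  e2 <- cgenet:::eval_dataset(m, ds, batch = 16)
  expect_equal(e1$loss, e2$loss, tolerance = 1e-10)
  expect_identical(e1$pred, e2$pred)
})

test_that("checkpoints round-trip weights and BN statistics", {
  dir <- withr::local_tempdir()
  ds <- two_class_tensor(n_per = 8)
  set.seed(74)
  m <- tiny_model(2)
  fit(m, ds, ds, train_config(epochs = 1, batch = 8, seed = 1))
  p <- save_checkpoint(m, file.path(dir, "ck.rds"))
  set.seed(99)
  m2 <- tiny_model(2)
  load_checkpoint(m2, p)
  fm <- random_fm(2, 16, 16)
  expect_equal(cgenet:::layer_fwd(m, fm)$x, cgenet:::layer_fwd(m2, fm)$x,
               tolerance = 1e-12)
})

test_that("transfer loading reinitializes exactly the classifier head", {
  dir <- withr::local_tempdir()
  ds <- two_class_tensor(n_per = 8)
  set.seed(75)
  src <- tiny_model(5)
  ck <- save_checkpoint(src, file.path(dir, "src.rds"))
  # equal class counts: full load, nothing reinitialized
  set.seed(76)
  tgt_same <- tiny_model(5)
  log_same <- transfer_finetune(tgt_same, ck, ds, ds,
                                train_config(epochs = 1, batch = 8,
                                             seed = 1))
  expect_length(attr(log_same, "reinitialized"), 0)
  # 5 -> 2 classes: only the head stays fresh
  set.seed(77)
  tgt <- tiny_model(2)
  fresh_head <- tgt$children[[3]]$w$W
  log <- transfer_finetune(tgt, ck, ds, ds,
                           train_config(epochs = 1, batch = 8, seed = 1,
                                        freeze = "net"))
  expect_identical(attr(log, "reinitialized"), "net.classifier")
  expect_identical(tgt$children[[3]]$w$W, fresh_head)  # frozen + fresh
  expect_equal(tgt$children[[1]]$children[[1]]$w$W,
               src$children[[1]]$children[[1]]$w$W)
  # architecture mismatch outside the head is an explicit error
  set.seed(78)
  other <- build_cgenet(2)
  expect_error(transfer_finetune(other, ck, ds, ds), "incompatible")
})

test_that("non-finite loss aborts with the batch position", {
  ds <- two_class_tensor(n_per = 8)
  set.seed(79)
  m <- tiny_model(2)
  m$children[[3]]$w$W[] <- 1e308   # classifier weights force overflow
  expect_error(fit(m, ds, ds, train_config(epochs = 1, batch = 8, seed = 1)),
               "batch")
})

test_that("schedule comparison shares the epoch-1 trajectory exactly", {
  ds <- two_class_tensor(n_per = 12)
  cfg <- train_config(optimizer = "adam", lr0 = 0.01, epochs = 4, batch = 8,
                      seed = 5)
  res <- compare_schedules(function() tiny_model(2), ds, ds, cfg,
                           threshold = 0.9, init_seed = 11)
  expect_named(res, c("cosine", "none"))
  # cosine and constant agree at epoch 0 only
  ca <- cfg; ca$schedule <- "cosine"
  cn <- cfg; cn$schedule <- "none"
  expect_equal(lr_schedule(0, ca), lr_schedule(0, cn))
  expect_false(isTRUE(all.equal(lr_schedule(1, ca), lr_schedule(1, cn))))
})
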