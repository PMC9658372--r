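test_that("the step-decay schedule matches its closed form and an iterative oracle", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 0), 0.005)
  expect_equal(lr_at_epoch(cfg, 6), 0.005)
  expect_equal(lr_at_epoch(cfg, 7), 0.0005)
  expect_equal(lr_at_epoch(cfg, 14), 5e-5)

  flat <- train_config(decay_factor = 1)
  expect_equal(lr_at_epoch(flat, 0:49), rep(0.005, 50))

  # iterative "multiply every decay_step epochs" simulation
  lr <- cfg$initial_lr
  for (ep in 0:200) {
    if (ep > 0 && ep %% cfg$decay_step == 0) lr <- lr * cfg$decay_factor
    expect_equal(lr_at_epoch(cfg, ep), lr)
  }
  expect_error(lr_at_epoch(cfg, -1), "epoch")
})

test_that("train_config validates its fields", {
  expect_error(train_config(decay_factor = 0), "decay_factor")
  expect_error(train_config(decay_factor = 1.5), "decay_factor")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(omega = -1), "omega")
  expect_error(train_config(optimizer = "adam"))
  cfg <- train_config(epochs = 5, seed = 3)
  expect_s3_class(cfg, "amcnn_train_config")
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$batch_size, 32L)
})

test_that("a toy run keeps faithful per-epoch books and selects the best epoch", {
  ds <- toy_dataset(2L, 1L, 2L, 10L, seed = 1L)
  split <- split_manifest(ds$manifest, seed = 0L)
  cfg <- train_config(epochs = 2L, batch_size = 8L, seed = 0L, omega = 1)
  fit <- amcnn_fit(ds$manifest, split, cfg, image_root = ds$dir)
  expect_s3_class(fit, "amcnn_fit")
  h <- fit$history
  expect_equal(nrow(h), 2L)
  expect_equal(h$epoch, 1:2)
  expect_equal(h$lr, c(0.005, 0.005))
  expect_true(all(is.finite(h$train_loss)))
  expect_true(all(h$val_accuracy >= 0 & h$val_accuracy <= 1))
  best <- which(h$val_accuracy == max(h$val_accuracy))[1]  # ties -> earlier
  expect_equal(fit$best_epoch, best)
  expect_gt(fit$wall_time, 0)

  # same seed, same data: reproducible loss trajectory
  fit2 <- amcnn_fit(ds$manifest, split, cfg, image_root = ds$dir)
  expect_identical(fit2$history$train_loss, h$train_loss)

  expect_error(
    amcnn_fit(ds$manifest,
              structure(list(assignment = stats::setNames(
                rep("test", nrow(ds$manifest$records)),
                ds$manifest$records$record_id),
                seed = 0L, fractions = c(train = .8, val = .1, test = .1),
                stratified = TRUE), class = "amcnn_split"),
              cfg, image_root = ds$dir),
    "empty train split")
})

test_that("checkpoints round-trip bitwise", {
  ds <- toy_dataset(2L, 1L, 2L, 10L, seed = 1L)
  split <- split_manifest(ds$manifest, seed = 0L)
  cfg <- train_config(epochs = 1L, batch_size = 8L, seed = 1L, omega = 1.2)
  fit <- amcnn_fit(ds$manifest, split, cfg,
                   mask_provider = mask_provider_oracle(ds$dir),
                   image_root = ds$dir)
  path <- file.path(tempdir(), "roundtrip.rds")
  amcnn_save(fit, path)
  fit2 <- amcnn_load(path)
  te <- split_records(ds$manifest, split, "test")
  p1 <- predict(fit, te, type = "prob", image_root = ds$dir,
                mask_provider = mask_provider_oracle(ds$dir))
  p2 <- predict(fit2, te, type = "prob", image_root = ds$dir,
                mask_provider = mask_provider_oracle(ds$dir))
  expect_identical(p1, p2)

  corrupt <- file.path(tempdir(), "corrupt.rds")
  obj <- readRDS(path); obj$format_version <- 99L; saveRDS(obj, corrupt)
  expect_error(amcnn_load(corrupt), "format version")
})

test_that("predict returns classes, probabilities and ranked lists", {
  ds <- toy_dataset(2L, 1L, 2L, 10L, seed = 1L)
  split <- split_manifest(ds$manifest, seed = 0L)
  cfg <- train_config(epochs = 1L, batch_size = 8L, seed = 0L, omega = 1)
  fit <- amcnn_fit(ds$manifest, split, cfg, image_root = ds$dir)
  te <- split_records(ds$manifest, split, "test")

  pr <- predict(fit, te, type = "prob", image_root = ds$dir)
  expect_equal(dim(pr), c(nrow(te), 4L))
  expect_equal(rowSums(pr), rep(1, nrow(te)), tolerance = 1e-6)

  cl <- predict(fit, te, type = "class", image_root = ds$dir)
  expect_true(all(cl %in% 0:3))

  tk <- predict(fit, te, type = "topk", k = 3L, image_root = ds$dir)
  expect_length(tk, nrow(te))
  expect_equal(nrow(tk[[1]]), 3L)
  expect_true(all(diff(tk[[1]]$confidence) <= 0))

  # a single image path also works
  one <- predict(fit, file.path(ds$dir, te$path[1]), type = "prob")
  expect_equal(dim(one), c(1L, 4L))
})
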