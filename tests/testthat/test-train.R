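test_that("training keeps per-epoch records and writes a checkpoint", {
  pairs <- make_pairs(8, 100)
  val <- make_pairs(4, 900)
  m <- dks_model(tiny_model_config())
  ckpt <- tempfile("ckpt")
  fit <- train_model(m, pairs, val, train_config(
    learning_rate = 1e-3, batch_size = 4L, epochs = 2L, seed = 3L,
    checkpoint_dir = ckpt, verbose = FALSE))
  expect_s3_class(fit, "dks_fit")
  expect_equal(fit$history$epoch, 1:2)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(fit$history$val_dice >= 0 & fit$history$val_dice <= 1))
  expect_true(file.exists(file.path(ckpt, "best.rds")))
  expect_true(file.exists(file.path(ckpt, "history.json")))
  # the input model is left untouched
  expect_identical(m$store$params[["b1.head.b"]],
                   dks_model(tiny_model_config())$store$params[["b1.head.b"]])
  unlink(ckpt, recursive = TRUE)
})

test_that("training on all-empty masks completes under the empty-mask convention", {
  pairs <- lapply(1:4, function(i) {
    list(image = array(runif(32 * 32 * 3), c(32, 32, 3)),
         mask = matrix(0, 32, 32))
  })
  m <- dks_model(tiny_model_config())
  fit <- train_model(m, pairs, pairs, train_config(
    learning_rate = 1e-3, batch_size = 4L, epochs = 1L, seed = 1L,
    verbose = FALSE))
  expect_true(is.finite(fit$history$train_loss))
  expect_true(is.finite(fit$history$val_dice))
})

test_that("identical seeds reproduce identical histories", {
  pairs <- make_pairs(6, 40)
  m <- dks_model(tiny_model_config())
  cfg <- train_config(learning_rate = 5e-4, batch_size = 2L, epochs = 2L,
                      seed = 8L, verbose = FALSE)
  f1 <- train_model(m, pairs, config = cfg)
  f2 <- train_model(m, pairs, config = cfg)
  expect_identical(f1$history, f2$history)
})

test_that("repeated steps on one fixed batch drive the loss down", {
  pairs <- make_pairs(4, 77)
  m <- dks_model(tiny_model_config())
  fit <- train_model(m, pairs, config = train_config(
    learning_rate = 3e-3, batch_size = 4L, epochs = 12L, seed = 2L,
    verbose = FALSE))
  l <- fit$history$train_loss
  expect_lt(l[12], l[1])
  expect_lt(l[12], 0.8 * l[1])
})

test_that("early stopping halts after the configured patience", {
  pairs <- make_pairs(4, 55)
  m <- dks_model(tiny_model_config())
  fit <- train_model(m, pairs, pairs, train_config(
    learning_rate = 1e-9, batch_size = 4L, epochs = 30L, seed = 2L,
    early_stop_patience = 2L, verbose = FALSE))
  expect_lt(nrow(fit$history), 30)
})

test_that("evaluation reports the five table columns plus audit fields", {
  pairs <- make_pairs(3, 70)
  m <- dks_model(tiny_model_config())
  jp <- tempfile(fileext = ".json")
  ev <- evaluate_model(m, pairs, json_path = jp)
  expect_s3_class(ev, "dks_eval")
  expect_named(ev$per_image, c("id", "Dice", "mIou", "Recall", "Precision",
                               "F1-Score", "iou_mean2class"))
  expect_equal(nrow(ev$per_image), 3)
  j <- jsonlite::read_json(jp)
  expect_equal(unlist(j$columns),
               c("Dice", "mIou", "Recall", "Precision", "F1-Score"))
  expect_true(all(c("mean", "pooled") %in% names(j)))

  # per-image metrics agree with direct computation
  pred <- predict_mask(m, pairs[[1]]$image)
  want <- compute_metrics(confusion_counts(pred, pairs[[1]]$mask))
  expect_equal(ev$per_image$Dice[1], want$dice)
  expect_equal(ev$per_image$mIou[1], want$miou_paper)
  unlink(jp)
})

test_that("file prediction is deterministic and binary", {
  m <- dks_model(tiny_model_config())
  img <- tempfile(fileext = ".png")
  png::writePNG(generate_sample(tiny_synth_params(), 3)$image, img)
  out1 <- tempfile(fileext = ".png"); out2 <- tempfile(fileext = ".png")
  prob <- tempfile(fileext = ".png")
  predict_to_file(m, img, out1, prob_path = prob)
  predict_to_file(m, img, out2)
  expect_identical(readBin(out1, "raw", 1e6), readBin(out2, "raw", 1e6))
  expect_true(all(read_mask(out1) %in% c(0, 1)))
  expect_true(file.exists(prob))
  # checkpoint round trip gives the same file
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  out3 <- tempfile(fileext = ".png")
  predict_to_file(ck, img, out3)
  expect_identical(readBin(out1, "raw", 1e6), readBin(out3, "raw", 1e6))
  unlink(c(img, out1, out2, out3, prob, ck))
})

test_that("odd-sized inputs are resized with a warning before prediction", {
  m <- dks_model(tiny_model_config())
  img <- tempfile(fileext = ".png")
  png::writePNG(array(runif(30 * 30 * 3), c(30, 30, 3)), img)
  out <- tempfile(fileext = ".png")
  expect_warning(predict_to_file(m, img, out), "divisible-by-16")
  expect_equal(dim(read_mask(out)), c(32L, 32L))
  unlink(c(img, out))
})

test_that("configuration files round-trip through YAML", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "model:",
    "  input_size: 64",
    "  width_multiplier: 0.25",
    "  decoder_widths: [64, 32, 16, 8]",
    "  seed: 11",
    "train:",
    "  learning_rate: 0.001",
    "  batch_size: 2",
    "  epochs: 3",
    "  loss_weights: [0.7, 0.3]"), yml)
  cfg <- load_config(yml)
  expect_equal(cfg$model$input_size, 64L)
  expect_equal(cfg$model$width_multiplier, 0.25)
  expect_equal(cfg$model$decoder_widths, c(64L, 32L, 16L, 8L))
  expect_equal(cfg$train$loss_weights, c(0.7, 0.3))
  expect_equal(cfg$train$epochs, 3L)
  # invalid values are rejected by the constructors
  writeLines(c("model:", "  input_size: 100"), yml)
  expect_error(load_config(yml), "divisible by 16")
  unlink(yml)
})

test_that("training rejects empty or mismatched data", {
  m <- dks_model(tiny_model_config())
  expect_error(train_model(m, list(), config = train_config(epochs = 1L)),
               "non-empty")
  bad <- list(list(image = array(0, c(32, 32, 3)), mask = matrix(0, 16, 16)))
  expect_error(train_model(m, bad, config = train_config(
    epochs = 1L, verbose = FALSE)), "mismatch")
})
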