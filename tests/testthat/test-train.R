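test_that("dataset splitting: sizes, disjointness, determinism, val re-sampling", {
  sp <- split_dataset(10, 0.8, 0.2, seed = 1)
  expect_length(sp$test, 2)
  expect_length(sp$val, 2)    # 20% of the 8-item training pool
  expect_length(sp$train, 6)
  expect_setequal(c(sp$train, sp$val, sp$test), 1:10)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_dataset(10, 0.8, 0.2, seed = 1))
  # re-sampling validation keeps the train/test boundary fixed
  sp2 <- split_dataset(10, 0.8, 0.2, seed = 1, val_seed = 99)
  expect_identical(sp2$test, sp$test)
  expect_setequal(c(sp2$train, sp2$val), c(sp$train, sp$val))
  expect_false(identical(sp2$val, sp$val))
  expect_error(split_dataset(2), "at least 3")
  expect_error(split_dataset(4, train_fraction = 0.99, val_fraction = 0.01),
               "empty split")
})

test_that("one-epoch smoke fit: history contract and finite losses", {
  data <- tiny_phantom_data(n = 6, seed = 2)
  cfg <- train_config(model = tiny_unet_config(), loss_name = "bce_dice",
                      learning_rate = 1e-3, batch_size = 2L, epochs = 1L,
                      seed = 4L)
  fit <- train_unet(data, cfg)
  expect_s3_class(fit, "spine_unet_fit")
  expect_equal(nrow(fit$history), 1L)
  expect_true(all(is.finite(unlist(fit$history))))
  # mismatched class count fails before training starts
  bad <- train_config(model = tiny_unet_config(n_classes = 4L), epochs = 1L)
  expect_error(train_unet(data, bad), "n_classes")
})

test_that("training is reproducible end-to-end under a fixed seed", {
  data <- tiny_phantom_data(n = 6, seed = 2)
  cfg <- train_config(model = tiny_unet_config(), loss_name = "dice",
                      learning_rate = 1e-3, batch_size = 2L, epochs = 2L,
                      seed = 8L)
  f1 <- train_unet(data, cfg)
  f2 <- train_unet(data, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("with head weights (1, 0) the trajectory ignores the bottleneck target", {
  data <- tiny_phantom_data(n = 6, seed = 3)
  scrambled <- lapply(data, function(p) {
    p$bottleneck_onehot <- p$bottleneck_onehot[, , 2:1]  # nonsense target
    p
  })
  cfg <- train_config(model = tiny_unet_config(), loss_name = "dice",
                      learning_rate = 1e-3, batch_size = 2L, epochs = 2L,
                      output_loss_weights = c(1, 0), seed = 6L)
  f1 <- train_unet(data, cfg)
  f2 <- train_unet(scrambled, cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
})

test_that("single-head model trains on the final loss alone", {
  data <- tiny_phantom_data(n = 6, seed = 4)
  cfg <- train_config(model = tiny_unet_config(use_dual_output = FALSE),
                      loss_name = "dice", learning_rate = 1e-3,
                      batch_size = 2L, epochs = 1L, seed = 2L)
  fit <- train_unet(data, cfg)
  expect_identical(fit$model$outputs, "out_final")
  expect_true(is.finite(fit$history$train_loss))
})

test_that("evaluation agrees with brute-force metric oracles on the same predictions", {
  toy <- get_toy_fit()
  test_idx <- toy$fit$split$test
  ev <- evaluate_unet(toy$fit, toy$data[test_idx], with_boundary = TRUE)
  # recompute from scratch: argmax labels, loop confusion, set-based metrics
  pooled <- NULL
  for (p in toy$data[test_idx]) {
    prob <- predict(toy$fit$model, p$image)$out_final
    pred <- apply(prob[, , , 1], c(1, 2), which.max) - 1L
    o <- oracle_confusion(as.vector(pred), as.vector(p$class_map), 2)
    pooled <- if (is.null(pooled)) o else Map(`+`, pooled, o)
  }
  cc <- structure(c(pooled, list(n_classes = 2L)), class = "confusion_counts")
  want <- scalar_metrics(cc)
  expect_equal(ev$metrics, want, tolerance = 1e-12)
  expect_true(is.finite(ev$hd) && is.finite(ev$assd))
  expect_lte(ev$assd, ev$hd)
  # a model predicting all-background has zero foreground recall
  zero <- toy$fit$model
  for (nm in names(zero$params)) for (f in names(zero$params[[nm]]))
    zero$params[[nm]][[f]][] <- 0
  zero$params[["final.head.conv"]]$b <- c(10, 0)   # bias forces class 0
  ev0 <- evaluate_unet(zero, toy$data[test_idx])
  expect_equal(ev0$metrics$recall, 0)
})

test_that("multiclass training runs and its metrics are macro-averaged", {
  data <- tiny_phantom_data(n = 6, seed = 5, n_classes = 4L)
  cfg <- train_config(model = tiny_unet_config(n_classes = 4L),
                      loss_name = "cce_dice", learning_rate = 1e-3,
                      batch_size = 2L, epochs = 1L, seed = 3L)
  fit <- train_unet(data, cfg)
  ev <- evaluate_unet(fit, data[fit$split$test])
  expect_true(all(unlist(ev$metrics) >= 0 & unlist(ev$metrics) <= 1))
  expect_equal(ev$confusion$n_classes, 4L)
})

test_that("stability harness: aggregation arithmetic and reproducible runs", {
  # sample sd arithmetic on a two-run table
  s <- stability_summary(data.frame(miou = c(0.8, 0.9)))
  expect_equal(s["mean", "miou"], 0.85)
  expect_equal(s["sd", "miou"], sd(c(0.8, 0.9)), tolerance = 1e-12)
  expect_equal(s["sd", "miou"], 0.0707, tolerance = 1e-3)
  # identical seeds give identical per-run rows
  data <- tiny_phantom_data(n = 8, seed = 6)
  cfg <- train_config(model = tiny_unet_config(), loss_name = "dice",
                      learning_rate = 1e-3, batch_size = 2L, epochs = 1L,
                      seed = 2L)
  rep <- stability_runs(data, cfg, seeds = c(5L, 5L))
  expect_equal(rep$runs[1, -1], rep$runs[2, -1], ignore_attr = TRUE)
  expect_equal(unlist(rep$summary["mean", ]),
               colMeans(rep$runs[, -1]), tolerance = 1e-12)
})
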