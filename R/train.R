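#' Training configuration
#'
#' Protocol settings for fitting the dual-output network: Adam with a low
#' learning rate (1e-4), batch size 2 and 50 epochs is the reference protocol
#' for real MRI data; the reduced phantom protocol in
#' [run_phantom_benchmark()] raises the rate.  The same loss is applied at the
#' final head (against the full-resolution one-hot mask) and, when the model
#' has a dual output, at the bottleneck head (against the downsampled
#' bottleneck target), combined with `output_loss_weights`.
#'
#' @param model A [unet_config()].
#' @param loss A [loss_config()].
#' @param loss_name One of the [get_loss()] names.
#' @param learning_rate Adam step size.
#' @param batch_size Samples per gradient step.
#' @param epochs Training epochs (fixed; no early stopping).
#' @param output_loss_weights Numeric `(final, bottleneck)` head weights.
#' @param train_fraction Fraction of the data used for training+validation;
#'   the remainder is the test split.
#' @param val_fraction Fraction of the training pool reserved for validation.
#' @param seed Seed governing weight init, shuffling, dropout and splits.
#' @return An object of class `train_config`.
#' @export
train_config <- function(model = unet_config(), loss = loss_config(),
                         loss_name = "dice", learning_rate = 1e-4,
                         batch_size = 2L, epochs = 50L,
                         output_loss_weights = c(final = 1, bottleneck = 1),
                         train_fraction = 0.8, val_fraction = 0.2,
                         seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 1,
            train_fraction > 0, train_fraction < 1,
            val_fraction > 0, val_fraction < 1,
            length(output_loss_weights) == 2, all(output_loss_weights >= 0))
  get_loss(loss_name)  # validates the name
  structure(list(model = model, loss = loss, loss_name = loss_name,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 output_loss_weights = unname(output_loss_weights),
                 train_fraction = train_fraction, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Deterministic train/validation/test split
#'
#' The test set holds `round((1 - train_fraction) * n)` indices drawn under
#' `seed`; the validation set is carved from the remaining training pool under
#' `val_seed` (defaults to `seed`).  Keeping `seed` fixed while varying
#' `val_seed` re-samples validation from the training data without touching
#' the train/test boundary, which is how multi-seed stability runs are set up.
#'
#' @param n_items Number of samples (>= 3).
#' @param train_fraction,val_fraction See [train_config()].
#' @param seed Seed of the train/test boundary.
#' @param val_seed Seed of the validation draw.
#' @return List of disjoint, exhaustive index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n_items, train_fraction = 0.8, val_fraction = 0.2,
                          seed = 1L, val_seed = seed) {
  if (n_items < 3) stop("split_dataset: need at least 3 items")
  n_test <- round((1 - train_fraction) * n_items)
  test <- withr::with_seed(seed, sort(sample.int(n_items, n_test)))
  pool <- setdiff(seq_len(n_items), test)
  n_val <- round(val_fraction * length(pool))
  val <- withr::with_seed(val_seed, sort(sample(pool, n_val)))
  train <- setdiff(pool, val)
  if (!length(train) || !length(val) || !length(test))
    stop("split_dataset: fractions produce an empty split")
  list(train = train, val = val, test = test)
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zl <- zeros_like_params(params)
  list(m = zl, v = zl, t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    for (f in names(params[[nm]])) {
      g <- grads[[nm]][[f]]
      st$m[[nm]][[f]] <- beta1 * st$m[[nm]][[f]] + (1 - beta1) * g
      st$v[[nm]][[f]] <- beta2 * st$v[[nm]][[f]] + (1 - beta2) * g * g
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (st$m[[nm]][[f]] / bc1) / (sqrt(st$v[[nm]][[f]] / bc2) + eps)
    }
  }
  list(params = params, st = st)
}

## ---- batching --------------------------------------------------------------

pairs_to_tensors <- function(pairs, idx) {
  p1 <- pairs[[idx[1]]]
  S <- nrow(p1$image); C <- p1$n_classes
  sb <- dim(p1$bottleneck_onehot)[1]
  B <- length(idx)
  x <- array(0, dim = c(S, S, 1L, B))
  yf <- array(0, dim = c(S, S, C, B))
  yb <- array(0, dim = c(sb, sb, C, B))
  for (i in seq_len(B)) {
    p <- pairs[[idx[i]]]
    x[, , 1L, i] <- p$image
    yf[, , , i] <- p$mask_onehot
    yb[, , , i] <- p$bottleneck_onehot
  }
  list(x = x, y_final = yf, y_bottleneck = yb)
}

#' Fit the network
#'
#' Dual-output training: each gradient step minimises
#' `w_final * L(final head, full mask) + w_bottleneck * L(bottleneck head,
#' bottleneck mask)` with the configured loss at both heads, optimised by
#' Adam.  All randomness (weight initialisation, epoch shuffling, dropout
#' masks) runs under `config$seed`, so a fit is reproducible end-to-end.
#'
#' @param data List of slice pairs ([build_dataset()] /
#'   [generate_phantom_dataset()]).
#' @param config A [train_config()].
#' @param split Optional index list from [split_dataset()]; computed from the
#'   config fractions and seed when omitted.
#' @param verbose Print per-epoch losses.
#' @return An object of class `spine_unet_fit`: the trained `model`, the
#'   per-epoch `history` (train/validation loss), the `split` and the
#'   `config`.
#' @export
train_unet <- function(data, config, split = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (!length(data)) stop("train_unet: no data")
  mcfg <- config$model
  if (data[[1]]$n_classes != mcfg$n_classes)
    stop("train_unet: model n_classes (", mcfg$n_classes,
         ") does not match data (", data[[1]]$n_classes, ")")
  if (nrow(data[[1]]$image) != mcfg$input_size)
    stop("train_unet: model input_size does not match data")
  if (is.null(split))
    split <- split_dataset(length(data), config$train_fraction,
                           config$val_fraction, config$seed)
  model <- build_unet(mcfg, seed = config$seed)
  lf <- get_loss(config$loss_name)
  w <- config$output_loss_weights
  dual <- mcfg$use_dual_output
  opt <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))

  batch_loss <- function(pairs_idx, training) {
    bt <- pairs_to_tensors(data, pairs_idx)
    fwd <- nn_forward(model, bt$x, training = training, keep = training)
    pf <- fwd$outputs$out_final
    lo <- w[1] * lf$fn(bt$y_final, pf, config$loss)
    if (dual)
      lo <- lo + w[2] * lf$fn(bt$y_bottleneck, fwd$outputs$out_bottleneck,
                              config$loss)
    list(fwd = fwd, bt = bt, loss = lo)
  }

  withr::with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(split$train)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tl <- 0; tn <- 0
      for (b in batches) {
        r <- batch_loss(b, training = TRUE)
        douts <- list(out_final = w[1] *
                        lf$grad(r$bt$y_final, r$fwd$outputs$out_final,
                                config$loss))
        if (dual)
          douts$out_bottleneck <- w[2] *
            lf$grad(r$bt$y_bottleneck, r$fwd$outputs$out_bottleneck,
                    config$loss)
        bw <- nn_backward(model, r$fwd, douts)
        up <- adam_step(model$params, bw$pgrads, opt, config$learning_rate)
        model$params <- up$params
        opt <- up$st
        model$state <- r$fwd$state
        tl <- tl + r$loss * length(b); tn <- tn + length(b)
      }
      vbatches <- split(split$val,
                        ceiling(seq_along(split$val) / max(4L, config$batch_size)))
      vl <- 0
      for (b in vbatches) vl <- vl + batch_loss(b, training = FALSE)$loss * length(b)
      history[ep, ] <- list(ep, tl / tn, vl / length(split$val))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                        history$train_loss[ep], history$val_loss[ep]))
    }
  })
  structure(list(model = model, history = history, split = split,
                 config = config),
            class = "spine_unet_fit")
}

#' Evaluate a trained model
#'
#' Inference uses the final head only (the bottleneck head is a training-time
#' supervision signal): per-pixel argmax of the final softmax, pooled
#' confusion counts over all evaluated images, scalar metrics from the pooled
#' counts.  With `with_boundary = TRUE`, per-image Hausdorff and average
#' symmetric surface distances of the binary foreground boundaries are
#' averaged over images; images whose prediction or truth has no boundary are
#' skipped with a warning.
#'
#' @param model A `spine_unet` or `spine_unet_fit`.
#' @param test List of slice pairs to evaluate.
#' @param with_boundary Also compute mean HD and ASSD (pixel units).
#' @param per_image Additionally return a per-image metric table.
#' @return List with `metrics`, the pooled `confusion`, and optionally
#'   `hd`/`assd` and `per_image`.
#' @export
evaluate_unet <- function(model, test, with_boundary = FALSE,
                          per_image = FALSE) {
  if (inherits(model, "spine_unet_fit")) model <- model$model
  stopifnot(inherits(model, "spine_unet"))
  if (!length(test)) stop("evaluate_unet: empty test set")
  nc <- model$config$n_classes
  pooled <- NULL
  rows <- list()
  hds <- c(); assds <- c(); skipped <- 0L
  chunks <- split(seq_along(test), ceiling(seq_along(test) / 8L))
  for (ch in chunks) {
    bt <- pairs_to_tensors(test, ch)
    pf <- nn_forward(model, bt$x, training = FALSE)$outputs$out_final
    for (i in seq_along(ch)) {
      pred <- argmax_labels(pf[, , , i])
      truth <- test[[ch[i]]]$class_map
      cc <- confusion_counts(pred, truth, nc)
      pooled <- if (is.null(pooled)) cc else pooled + cc
      if (per_image)
        rows[[length(rows) + 1L]] <-
          as.data.frame(scalar_metrics(cc))
      if (with_boundary) {
        bp <- extract_boundary(pred > 0)
        btr <- extract_boundary(truth > 0)
        if (nrow(bp) && nrow(btr)) {
          hds <- c(hds, hausdorff(bp, btr))
          assds <- c(assds, assd(bp, btr))
        } else skipped <- skipped + 1L
      }
    }
  }
  out <- list(metrics = scalar_metrics(pooled), confusion = pooled)
  if (with_boundary) {
    if (skipped)
      warning(skipped, " image(s) without a boundary skipped in HD/ASSD")
    out$hd <- if (length(hds)) mean(hds) else NA_real_
    out$assd <- if (length(assds)) mean(assds) else NA_real_
  }
  if (per_image) out$per_image <- do.call(rbind, rows)
  out
}

argmax_labels <- function(prob) {
  d <- dim(prob)
  M <- matrix(prob, d[1] * d[2], d[3])
  matrix(max.col(M, ties.method = "first") - 1L, d[1], d[2])
}

#' Multi-seed stability harness
#'
#' Repeats fit + evaluate over a set of seeds with the train/test boundary
#' held fixed (drawn under `config$seed`) while weight initialisation,
#' shuffling, dropout and the validation draw follow each run's seed.  Reports
#' the per-run metric table with mean and sample (n-1) standard deviation per
#' metric.
#'
#' @param data List of slice pairs.
#' @param config A [train_config()].
#' @param seeds Integer vector, one entry per run.
#' @return An object of class `stability_report` with `runs` (data.frame) and
#'   `summary` (mean/sd rows).
#' @export
stability_runs <- function(data, config, seeds) {
  runs <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    sp <- split_dataset(length(data), config$train_fraction,
                        config$val_fraction, seed = config$seed, val_seed = s)
    fit <- train_unet(data, cfg, split = sp)
    m <- evaluate_unet(fit, data[sp$test])$metrics
    cbind(data.frame(seed = s), as.data.frame(m))
  })
  tab <- do.call(rbind, runs)
  structure(list(runs = tab, summary = stability_summary(tab[, -1])),
            class = "stability_report")
}

#' Mean and sample standard deviation of per-run metrics
#'
#' @param tab Data frame of per-run metric columns.
#' @return Data frame with rows `mean` and `sd`.
#' @export
stability_summary <- function(tab) {
  data.frame(rbind(mean = colMeans(tab), sd = apply(tab, 2, sd)))
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>", nrow(x$runs), "runs\n")
  print(x$runs, row.names = FALSE)
  cat("\n")
  print(round(x$summary, 5))
  invisible(x)
}

#' @export
print.spine_unet_fit <- function(x, ...) {
  cat("<spine_unet_fit>\n")
  cat(sprintf("  loss    : %s (lr %g, batch %d, %d epochs)\n", x$config$loss_name,
              x$config$learning_rate, x$config$batch_size, x$config$epochs))
  h <- x$history
  cat(sprintf("  split   : %d train / %d val / %d test\n",
              length(x$split$train), length(x$split$val), length(x$split$test)))
  cat(sprintf("  loss    : first epoch %.4f -> final %.4f (val %.4f)\n",
              h$train_loss[1], h$train_loss[nrow(h)], h$val_loss[nrow(h)]))
  invisible(x)
}

#' @export
summary.spine_unet_fit <- function(object, ...) {
  print(object)
  invisible(object$history)
}

#' Loss curves of a fit
#'
#' @param x A `spine_unet_fit`.
#' @param ... Passed to `plot`.
#' @export
plot.spine_unet_fit <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       ylim = range(c(h$train_loss, h$val_loss)), ...)
  lines(h$epoch, h$val_loss, lty = 2)
  legend("topright", legend = c("training", "validation"), lty = c(1, 2),
         bty = "n")
  invisible(h)
}

#' @export
predict.spine_unet_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' Reduced network configuration for the phantom benchmark
#'
#' A quarter-scale variant of the architecture used for CPU-scale end-to-end
#' checks: 64-pixel input, encoder 32/64/128, bottleneck 256, decoder
#' 128/64/32/16, Inception branches scaled to a 64-channel concatenation.
#' Structure (Inception first block, dual output, skip wiring) is identical to
#' the full model.
#'
#' @param n_classes 2 or 4.
#' @param use_inception,use_dual_output Ablation toggles.
#' @return A [unet_config()].
#' @export
reduced_unet_config <- function(n_classes = 2L, use_inception = TRUE,
                                use_dual_output = TRUE) {
  unet_config(input_size = 64L, n_classes = n_classes,
              encoder_filters = c(32L, 64L, 128L),
              bottleneck_filters = 256L,
              decoder_filters = c(128L, 64L, 32L, 16L),
              inception = inception_config(16L, 24L, 32L, 4L, 8L, 8L),
              use_inception = use_inception,
              use_dual_output = use_dual_output)
}

#' End-to-end phantom benchmark
#'
#' The package's CPU-scale convergence protocol: 80 spine phantoms at 64
#' pixels, the [reduced_unet_config()] network, Dice loss at both heads, Adam
#' at 1e-3, batch 2, 30 epochs.  Returns the fit together with validation and
#' test metrics.
#'
#' @param seed Master seed for phantom generation and training.
#' @param n Number of phantoms.
#' @param epochs Training epochs.
#' @param loss_name Loss to train with.
#' @param use_dual_output Train with the auxiliary bottleneck head.
#' @param verbose Print per-epoch losses.
#' @return List with `fit`, `val_metrics`, `test_metrics`.
#' @export
run_phantom_benchmark <- function(seed = 1L, n = 80L, epochs = 30L,
                                  loss_name = "dice", use_dual_output = TRUE,
                                  verbose = FALSE) {
  data <- generate_phantom_dataset(phantom_config(size = 64L), n = n,
                                   seed = seed, n_classes = 2L)
  cfg <- train_config(model = reduced_unet_config(use_dual_output = use_dual_output),
                      loss_name = loss_name, learning_rate = 1e-3,
                      batch_size = 2L, epochs = epochs, seed = seed)
  fit <- train_unet(data, cfg, verbose = verbose)
  val <- evaluate_unet(fit, data[fit$split$val])
  test <- evaluate_unet(fit, data[fit$split$test], with_boundary = TRUE)
  list(fit = fit, val_metrics = val$metrics, test_metrics = test$metrics,
       test_hd = test$hd, test_assd = test$assd)
}
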