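# Independent brute-force oracles.  Everything here is deliberately written as
# plain scalar loops (or set arithmetic), sharing no code with the package
# implementations it checks.

oracle_bce <- function(y, p, eps = 1e-7) {
  tot <- 0
  for (i in seq_along(y)) {
    pi <- min(max(p[i], eps), 1 - eps)
    tot <- tot + y[i] * log(pi) + (1 - y[i]) * log(1 - pi)
  }
  -tot / length(y)
}

oracle_focal <- function(y, p, alpha = 0.5, gamma = 2, eps = 1e-7) {
  tot <- 0
  for (i in seq_along(y)) {
    pi <- min(max(p[i], eps), 1 - eps)
    pt <- if (y[i] == 1) pi else 1 - pi
    tot <- tot + alpha * (1 - pt)^gamma * (-log(pt))
  }
  tot / length(y)
}

oracle_dice <- function(y, p, smooth = 1) {
  # y, p: [H, W, C] or [H, W, C, N]; batch-Dice per channel, channel average
  d <- dim(y)
  C <- d[3]
  out <- 0
  for (ch in seq_len(C)) {
    yc <- if (length(d) == 3) y[, , ch] else y[, , ch, ]
    pc <- if (length(d) == 3) p[, , ch] else p[, , ch, ]
    i <- 0; sy <- 0; sp <- 0
    for (k in seq_along(yc)) {
      i <- i + yc[k] * pc[k]; sy <- sy + yc[k]; sp <- sp + pc[k]
    }
    out <- out + 1 - (2 * i + smooth) / (sy + sp + smooth)
  }
  out / C
}

oracle_cce <- function(y, p, eps = 1e-7) {
  d <- dim(y)
  C <- d[3]
  n_pix <- prod(d) / C
  tot <- 0
  for (ch in seq_len(C)) {
    yc <- if (length(d) == 3) y[, , ch] else y[, , ch, ]
    pc <- if (length(d) == 3) p[, , ch] else p[, , ch, ]
    for (k in seq_along(yc))
      tot <- tot + yc[k] * log(min(max(pc[k], eps), 1 - eps))
  }
  -tot / n_pix
}

# Set-arithmetic segmentation metrics on label maps
oracle_metrics <- function(pred, truth, n_classes) {
  idx <- seq_along(pred)
  iou <- prec <- rec <- numeric(n_classes)
  for (c in 0:(n_classes - 1)) {
    P <- idx[as.vector(pred) == c]
    T <- idx[as.vector(truth) == c]
    inter <- length(intersect(P, T))
    uni <- length(union(P, T))
    iou[c + 1] <- if (uni == 0) 1 else inter / uni
    prec[c + 1] <- if (length(P) == 0) (if (uni == 0) 1 else 0) else inter / length(P)
    rec[c + 1] <- if (length(T) == 0) (if (uni == 0) 1 else 0) else inter / length(T)
  }
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  acc <- mean(as.vector(pred) == as.vector(truth))
  if (n_classes == 2)
    list(miou = mean(iou), accuracy = acc, precision = prec[2], recall = rec[2],
         f1 = f1[2])
  else
    list(miou = mean(iou), accuracy = acc, precision = mean(prec),
         recall = mean(rec), f1 = mean(f1))
}

oracle_confusion <- function(pred, truth, n_classes) {
  tp <- fp <- fn <- tn <- integer(n_classes)
  for (i in seq_along(pred)) {
    for (c in 0:(n_classes - 1)) {
      pc <- pred[i] == c; tc <- truth[i] == c
      if (pc && tc) tp[c + 1] <- tp[c + 1] + 1L
      else if (pc && !tc) fp[c + 1] <- fp[c + 1] + 1L
      else if (!pc && tc) fn[c + 1] <- fn[c + 1] + 1L
      else tn[c + 1] <- tn[c + 1] + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Exhaustive pairwise boundary distances
oracle_hd_assd <- function(a, b) {
  dmin_a <- rep(Inf, nrow(a)); dmin_b <- rep(Inf, nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < dmin_a[i]) dmin_a[i] <- d
      if (d < dmin_b[j]) dmin_b[j] <- d
    }
  list(hd = max(max(dmin_a), max(dmin_b)),
       assd = (sum(dmin_a) + sum(dmin_b)) / (nrow(a) + nrow(b)))
}

# Erosion-difference boundary: boundary = mask minus 4-neighbour erosion
oracle_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- NULL
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      if (mask[i, j] == 0) next
      nb <- c(if (i > 1) mask[i - 1, j] else 0,
              if (i < nr) mask[i + 1, j] else 0,
              if (j > 1) mask[i, j - 1] else 0,
              if (j < nc) mask[i, j + 1] else 0)
      if (any(nb == 0)) out <- rbind(out, c(i, j))
    }
  out
}

# Nearest-neighbour resize by explicit per-cell index mapping
oracle_resize_nearest <- function(m, out_n) {
  in_n <- nrow(m)
  out <- matrix(0L, out_n, out_n)
  for (i in seq_len(out_n))
    for (j in seq_len(out_n)) {
      si <- min(max(floor((i - 0.5) * in_n / out_n), 0), in_n - 1) + 1
      sj <- min(max(floor((j - 0.5) * in_n / out_n), 0), in_n - 1) + 1
      out[i, j] <- m[si, sj]
    }
  out
}

# Direct convolution loop ('same' zero padding)
oracle_conv2d <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Ci <- dim(x)[3]; N <- dim(x)[4]
  k <- dim(w)[1]; Co <- dim(w)[4]; p <- k %/% 2
  y <- array(0, dim = c(H, W, Co, N))
  for (n in seq_len(N)) for (co in seq_len(Co)) for (i in seq_len(H))
    for (j in seq_len(W)) {
      s <- b[co]
      for (a in seq_len(k)) for (bb in seq_len(k)) {
        ii <- i + a - 1 - p; jj <- j + bb - 1 - p
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
          for (ci in seq_len(Ci))
            s <- s + x[ii, jj, ci, n] * w[a, bb, ci, co]
      }
      y[i, j, co, n] <- s
    }
  y
}

oracle_tconv2d <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Ci <- dim(x)[3]; N <- dim(x)[4]
  Co <- dim(w)[4]
  y <- array(0, dim = c(2 * H, 2 * W, Co, N))
  for (n in seq_len(N)) for (co in seq_len(Co)) y[, , co, n] <- b[co]
  for (n in seq_len(N)) for (co in seq_len(Co)) for (i in seq_len(H))
    for (j in seq_len(W)) for (a in 1:2) for (bb in 1:2)
      for (ci in seq_len(Ci))
        y[2 * (i - 1) + a, 2 * (j - 1) + bb, co, n] <-
          y[2 * (i - 1) + a, 2 * (j - 1) + bb, co, n] +
          x[i, j, ci, n] * w[a, bb, ci, co]
  y
}

flood_components <- function(mask) {
  # 4-connected component count of a binary matrix
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    count <- count + 1L
    stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        i <- p[1] + d[1]; j <- p[2] + d[2]
        if (i >= 1 && i <= nr && j >= 1 && j <= nc && mask[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE
          stack[[length(stack) + 1L]] <- c(i, j)
        }
      }
    }
  }
  count
}

# Small network configuration used across engine/train/explain tests
tiny_unet_config <- function(n_classes = 2L, use_inception = TRUE,
                             use_dual_output = TRUE, dropout_rate = 0) {
  unet_config(input_size = 32L, n_classes = n_classes,
              encoder_filters = c(8L, 12L, 16L), bottleneck_filters = 32L,
              decoder_filters = c(16L, 12L, 8L, 8L),
              inception = inception_config(4L, 6L, 8L, 2L, 4L, 4L),
              dropout_rate = dropout_rate,
              use_inception = use_inception, use_dual_output = use_dual_output)
}

tiny_phantom_data <- function(n = 12L, seed = 3L, n_classes = 2L) {
  generate_phantom_dataset(phantom_config(size = 32L, n_vertebrae = 3L),
                           n = n, seed = seed, n_classes = n_classes)
}

# Memoized small trained model shared by the train and explain tests
.toy_fit_env <- new.env(parent = emptyenv())
get_toy_fit <- function() {
  if (!is.null(.toy_fit_env$fit)) return(.toy_fit_env$fit)
  data <- tiny_phantom_data(n = 24L, seed = 11L)
  cfg <- train_config(model = tiny_unet_config(), loss_name = "dice",
                      learning_rate = 2e-3, batch_size = 4L, epochs = 6L,
                      seed = 5L)
  .toy_fit_env$fit <- list(fit = train_unet(data, cfg), data = data)
  .toy_fit_env$fit
}

random_valid_config <- function(seed) {
  withr::with_seed(seed, {
    ef <- sample(2:12, 3)
    unet_config(input_size = sample(c(16L, 32L, 64L), 1),
                input_channels = sample(1:2, 1),
                n_classes = sample(2:4, 1),
                encoder_filters = ef,
                bottleneck_filters = sample(4:24, 1),
                decoder_filters = sample(2:12, 4),
                dropout_rate = sample(c(0, 0.5), 1),
                use_inception = sample(c(TRUE, FALSE), 1),
                use_dual_output = sample(c(TRUE, FALSE), 1),
                inception = inception_config(sample(2:8, 1), sample(2:8, 1),
                                             sample(2:8, 1), sample(2:8, 1),
                                             sample(2:8, 1), sample(2:8, 1)))
  })
}
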