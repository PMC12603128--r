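## Forward and reverse-mode execution of a layer plan over named tensors.
## Tensors are dense [H, W, C, N] arrays.  The cache produced by nn_forward()
## holds every intermediate tensor plus per-op auxiliaries (batch statistics,
## pooling argmax indices, dropout masks) so nn_backward() can replay the plan
## in reverse.

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9  # running <- 0.9 * running + 0.1 * batch

relu_fw <- function(x) { x[x < 0] <- 0; x }

softmax_channels <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  M <- matrix(x, hw, C * N)
  out <- M
  for (n in seq_len(N)) {
    cols <- (n - 1L) * C + seq_len(C)
    B <- M[, cols, drop = FALSE]
    mx <- B[, 1]
    for (c in 2:C) mx <- pmax(mx, B[, c])
    E <- exp(B - mx)
    out[, cols] <- E / rowSums(E)
  }
  array(out, dim = d)
}

softmax_bw <- function(p, dy) {
  d <- dim(p)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  P <- matrix(p, hw, C * N); G <- matrix(dy, hw, C * N)
  out <- P
  for (n in seq_len(N)) {
    cols <- (n - 1L) * C + seq_len(C)
    Pb <- P[, cols, drop = FALSE]; Gb <- G[, cols, drop = FALSE]
    s <- rowSums(Pb * Gb)
    out[, cols] <- Pb * (Gb - s)
  }
  array(out, dim = d)
}

bn_channel_stats <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  M <- matrix(x, hw, C * N)
  mu <- rowSums(matrix(.colSums(M, hw, C * N), C, N)) / (hw * N)
  m2 <- rowSums(matrix(.colSums(M * M, hw, C * N), C, N)) / (hw * N)
  list(mean = mu, var = pmax(m2 - mu^2, 0))
}

bn_apply <- function(x, gamma, beta, mean, var) {
  d <- dim(x)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  inv <- 1 / sqrt(var + BN_EPS)
  scl <- rep(rep(gamma * inv, N), each = hw)
  sft <- rep(rep(beta - gamma * inv * mean, N), each = hw)
  array(matrix(x, hw, C * N) * scl + sft, dim = d)
}

concat_channels <- function(tensors) {
  d1 <- dim(tensors[[1]])
  cs <- vapply(tensors, function(t) dim(t)[3], integer(1))
  out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (t in tensors) {
    k <- dim(t)[3]
    out[, , at + seq_len(k), ] <- t
    at <- at + k
  }
  out
}

#' Run the network forward
#'
#' @param model A `spine_unet`.
#' @param x Input tensor `[H, W, C, N]` (a single `H x W` matrix is promoted).
#' @param training Use batch statistics, apply dropout, and update running
#'   batch-norm statistics (returned, not applied in place).
#' @param keep Keep all intermediate tensors and auxiliaries for a backward
#'   pass.
#' @return A list with `outputs` (named list of softmax tensors), `state`
#'   (possibly updated batch-norm running statistics) and, when `keep = TRUE`,
#'   `tensors` and `aux` environments.
#' @keywords internal
nn_forward <- function(model, x, training = FALSE, keep = FALSE) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, dim = c(dim(x), 1L))
  tensors <- new.env(parent = emptyenv())
  aux <- new.env(parent = emptyenv())
  assign("input", x, envir = tensors)
  state <- model$state
  for (op in model$plan) {
    inp <- lapply(op$inputs, get, envir = tensors)
    out <- switch(op$type,
      conv = .conv2d_fw(inp[[1]], model$params[[op$name]]$w,
                        model$params[[op$name]]$b),
      tconv = .tconv2d_fw(inp[[1]], model$params[[op$name]]$w,
                          model$params[[op$name]]$b),
      bn = {
        p <- model$params[[op$name]]
        if (training) {
          st <- bn_channel_stats(inp[[1]])
          if (keep) assign(op$name, st, envir = aux)
          s0 <- state[[op$name]]
          state[[op$name]] <- list(
            mean = BN_MOMENTUM * s0$mean + (1 - BN_MOMENTUM) * st$mean,
            var = BN_MOMENTUM * s0$var + (1 - BN_MOMENTUM) * st$var)
          bn_apply(inp[[1]], p$gamma, p$beta, st$mean, st$var)
        } else {
          st <- state[[op$name]]
          bn_apply(inp[[1]], p$gamma, p$beta, st$mean, st$var)
        }
      },
      relu = relu_fw(inp[[1]]),
      pool2 = {
        r <- .maxpool2_fw(inp[[1]])
        if (keep) assign(op$name, r$idx, envir = aux)
        r$y
      },
      pool3 = {
        r <- .maxpool3_fw(inp[[1]])
        if (keep) assign(op$name, r$idx, envir = aux)
        r$y
      },
      concat = concat_channels(inp),
      dropout = {
        if (training && op$rate > 0) {
          mask <- array((runif(length(inp[[1]])) >= op$rate) / (1 - op$rate),
                        dim = dim(inp[[1]]))
          if (keep) assign(op$name, mask, envir = aux)
          inp[[1]] * mask
        } else inp[[1]]
      },
      softmax = softmax_channels(inp[[1]]),
      stop("unknown op type: ", op$type))
    assign(op$output, out, envir = tensors)
  }
  outputs <- setNames(lapply(model$outputs, get, envir = tensors), model$outputs)
  res <- list(outputs = outputs, state = state, training = training)
  if (keep) { res$tensors <- tensors; res$aux <- aux }
  res
}

zeros_like_params <- function(params) {
  lapply(params, function(p) lapply(p, function(v) {
    z <- v; z[] <- 0; z
  }))
}

#' Reverse-mode pass through a cached forward execution
#'
#' @param model A `spine_unet`.
#' @param cache Result of `nn_forward(..., keep = TRUE)`.
#' @param douts Named list of gradients w.r.t. output tensors (missing heads
#'   receive zero gradient).
#' @param want_tensor_grads Optional character vector of tensor names whose
#'   accumulated gradients should be returned (used by Grad-CAM).
#' @return List with `pgrads` (per-parameter gradients, same structure as
#'   `model$params`) and `tgrads` (requested tensor gradients).
#' @keywords internal
nn_backward <- function(model, cache, douts, want_tensor_grads = character(0)) {
  tensors <- cache$tensors; aux <- cache$aux
  training <- isTRUE(cache$training)
  grads <- new.env(parent = emptyenv())
  acc <- function(name, g) {
    if (exists(name, envir = grads, inherits = FALSE))
      assign(name, get(name, envir = grads) + g, envir = grads)
    else assign(name, g, envir = grads)
  }
  for (nm in names(douts)) acc(nm, douts[[nm]])
  pgrads <- zeros_like_params(model$params)
  for (op in rev(model$plan)) {
    if (!exists(op$output, envir = grads, inherits = FALSE)) next
    g <- get(op$output, envir = grads)
    xin <- get(op$inputs[[1]], envir = tensors)
    switch(op$type,
      conv = {
        r <- .conv2d_bw(xin, model$params[[op$name]]$w, g)
        pgrads[[op$name]]$w <- pgrads[[op$name]]$w + r$dw
        pgrads[[op$name]]$b <- pgrads[[op$name]]$b + r$db
        acc(op$inputs[[1]], r$dx)
      },
      tconv = {
        r <- .tconv2d_bw(xin, model$params[[op$name]]$w, g)
        pgrads[[op$name]]$w <- pgrads[[op$name]]$w + r$dw
        pgrads[[op$name]]$b <- pgrads[[op$name]]$b + r$db
        acc(op$inputs[[1]], r$dx)
      },
      bn = {
        p <- model$params[[op$name]]
        d <- dim(xin); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
        st <- if (training) get(op$name, envir = aux) else model$state[[op$name]]
        inv <- 1 / sqrt(st$var + BN_EPS)
        Xh <- (matrix(xin, hw, C * N) -
                 rep(rep(st$mean, N), each = hw)) * rep(rep(inv, N), each = hw)
        G <- matrix(g, hw, C * N)
        sum_g <- rowSums(matrix(.colSums(G, hw, C * N), C, N))
        sum_gx <- rowSums(matrix(.colSums(G * Xh, hw, C * N), C, N))
        pgrads[[op$name]]$gamma <- pgrads[[op$name]]$gamma + sum_gx
        pgrads[[op$name]]$beta <- pgrads[[op$name]]$beta + sum_g
        if (training) {
          m <- hw * N
          t1 <- G * m - rep(rep(sum_g, N), each = hw) -
            Xh * rep(rep(sum_gx, N), each = hw)
          dx <- t1 * rep(rep(p$gamma * inv / m, N), each = hw)
        } else {
          dx <- G * rep(rep(p$gamma * inv, N), each = hw)
        }
        acc(op$inputs[[1]], array(dx, dim = d))
      },
      relu = acc(op$inputs[[1]], g * (xin > 0)),
      pool2 = {
        idx <- get(op$name, envir = aux)
        dx <- numeric(length(xin))
        dx[as.vector(idx)] <- as.vector(g)  # windows are disjoint
        acc(op$inputs[[1]], array(dx, dim = dim(xin)))
      },
      pool3 = {
        idx <- as.vector(get(op$name, envir = aux))
        dx <- numeric(length(xin))
        s <- rowsum(as.vector(g), group = idx)
        dx[as.numeric(rownames(s))] <- s[, 1]
        acc(op$inputs[[1]], array(dx, dim = dim(xin)))
      },
      concat = {
        at <- 0L
        for (nm in op$inputs) {
          k <- dim(get(nm, envir = tensors))[3]
          acc(nm, g[, , at + seq_len(k), , drop = FALSE])
          at <- at + k
        }
      },
      dropout = {
        if (training && op$rate > 0)
          acc(op$inputs[[1]], g * get(op$name, envir = aux))
        else acc(op$inputs[[1]], g)
      },
      softmax = {
        p <- get(op$output, envir = tensors)
        acc(op$inputs[[1]], softmax_bw(p, g))
      })
  }
  tg <- setNames(lapply(want_tensor_grads, function(nm)
    if (exists(nm, envir = grads, inherits = FALSE)) get(nm, envir = grads) else NULL),
    want_tensor_grads)
  list(pgrads = pgrads, tgrads = tg)
}

#' Predict segmentation probabilities
#'
#' Runs the network in inference mode (running batch-norm statistics, no
#' dropout) and returns the per-pixel softmax maps of each output head.
#'
#' @param object A `spine_unet`.
#' @param newdata Input tensor `[H, W, C, N]`, a single `H x W` matrix, or a
#'   list of matrices.
#' @param ... Unused.
#' @return Named list of probability tensors, one per head (`out_final`, and
#'   `out_bottleneck` when the dual output is enabled).
#' @export
predict.spine_unet <- function(object, newdata, ...) {
  x <- as_input_tensor(newdata, object$config)
  nn_forward(object, x, training = FALSE, keep = FALSE)$outputs
}

as_input_tensor <- function(newdata, cfg) {
  if (is.list(newdata) && !is.array(newdata)) {
    n <- length(newdata)
    x <- array(0, dim = c(cfg$input_size, cfg$input_size, cfg$input_channels, n))
    for (i in seq_len(n)) x[, , 1L, i] <- newdata[[i]]
    return(x)
  }
  if (is.matrix(newdata))
    return(array(newdata, dim = c(dim(newdata), 1L, 1L)))
  if (length(dim(newdata)) == 3L)
    return(array(newdata, dim = c(dim(newdata), 1L)))
  newdata
}
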