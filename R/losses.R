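#' Loss configuration
#'
#' Constants of the segmentation losses: the focal balance factor `alpha`
#' (0.5 gives both classes equal importance) and focusing exponent `gamma`
#' (2 down-weights easy pixels), the weights `lambda1`/`lambda2` of the
#' cross-entropy and Dice terms in the compound losses (both 1 so each term
#' contributes equally), the Dice smoothing constant added to numerator and
#' denominator, and the probability clipping bound applied before logarithms.
#'
#' @param alpha Focal balance factor in (0, 1].
#' @param gamma Focal focusing exponent, >= 0.
#' @param lambda1,lambda2 Weights of the cross-entropy and Dice terms.
#' @param smooth Dice smoothing constant, >= 0.
#' @param clip_eps Probability clipping bound in (0, 0.5).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.5, gamma = 2.0, lambda1 = 1.0, lambda2 = 1.0,
                        smooth = 1.0, clip_eps = 1e-7) {
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0, lambda1 >= 0, lambda2 >= 0,
            smooth >= 0, clip_eps > 0, clip_eps < 0.5)
  structure(list(alpha = alpha, gamma = gamma, lambda1 = lambda1,
                 lambda2 = lambda2, smooth = smooth, clip_eps = clip_eps),
            class = "loss_config")
}

check_pair <- function(y_true, y_pred) {
  if (!identical(dim(y_true), dim(y_pred)) ||
      (is.null(dim(y_true)) && length(y_true) != length(y_pred)))
    stop("y_true and y_pred must have identical shapes")
}

clip_probs <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

#' Segmentation losses
#'
#' Scalar training losses over a target/prediction pair of identical shape.
#' `y_true` is a one-hot (or 0/1) array, `y_pred` holds per-entry
#' probabilities.  Cross-entropy style losses average over every scalar entry
#' (pixels x channels) after clipping probabilities to
#' `[clip_eps, 1 - clip_eps]`; the Dice loss is computed per channel over the
#' whole tensor (batch-Dice) with smoothing in numerator and denominator, then
#' averaged over channels.
#'
#' * `bce_loss`: mean binary cross-entropy.
#' * `dice_loss`: mean over channels of `1 - (2*I + s) / (U + s)`.
#' * `focal_loss`: mean of `alpha * (1 - p_t)^gamma * (-log p_t)` with
#'   `p_t = y_pred` where the target is 1 and `1 - y_pred` where it is 0;
#'   with `gamma = 0, alpha = 1` it reduces to `bce_loss`.
#' * `bce_dice_loss`: `lambda1 * BCE + lambda2 * Dice`.
#' * `cce_loss`: categorical cross-entropy, averaged over pixels (the channel
#'   sum collapses on a one-hot target).
#' * `cce_dice_loss`: `lambda1 * CCE + lambda2 * Dice`.
#'
#' @param y_true Target array with entries in {0, 1}.
#' @param y_pred Probability array, same shape.
#' @param cfg A [loss_config()].
#' @return A non-negative scalar.
#' @export
bce_loss <- function(y_true, y_pred, cfg = loss_config()) {
  check_pair(y_true, y_pred)
  p <- clip_probs(y_pred, cfg$clip_eps)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}

#' @rdname bce_loss
#' @export
dice_loss <- function(y_true, y_pred, cfg = loss_config()) {
  check_pair(y_true, y_pred)
  d <- dim(y_true)
  C <- if (!is.null(d) && length(d) >= 3L) d[3] else 1L
  per_channel <- vapply(seq_len(C), function(ch) {
    yt <- channel_slice(y_true, ch, C)
    yp <- channel_slice(y_pred, ch, C)
    i <- sum(yt * yp)
    u <- sum(yt) + sum(yp)
    1 - (2 * i + cfg$smooth) / (u + cfg$smooth)
  }, numeric(1))
  mean(per_channel)
}

# Extract channel ch of an array whose 3rd axis (of possibly 4) is channels;
# vectors/matrices are treated as single-channel.
channel_slice <- function(x, ch, C) {
  d <- dim(x)
  if (is.null(d) || length(d) < 3L) {
    if (C != 1L) stop("array without channel axis but C > 1")
    return(x)
  }
  if (length(d) == 3L) return(x[, , ch])
  x[, , ch, ]
}

#' @rdname bce_loss
#' @export
focal_loss <- function(y_true, y_pred, cfg = loss_config()) {
  check_pair(y_true, y_pred)
  p <- clip_probs(y_pred, cfg$clip_eps)
  pt <- ifelse(y_true == 1, p, 1 - p)
  mean(cfg$alpha * (1 - pt)^cfg$gamma * (-log(pt)))
}

#' @rdname bce_loss
#' @export
bce_dice_loss <- function(y_true, y_pred, cfg = loss_config()) {
  cfg$lambda1 * bce_loss(y_true, y_pred, cfg) +
    cfg$lambda2 * dice_loss(y_true, y_pred, cfg)
}

#' @rdname bce_loss
#' @export
cce_loss <- function(y_true, y_pred, cfg = loss_config()) {
  check_pair(y_true, y_pred)
  d <- dim(y_true)
  if (is.null(d) || length(d) < 3L)
    stop("cce_loss requires a one-hot target with a channel axis")
  C <- d[3]
  sums <- channel_slice(y_true, 1L, C)
  for (ch in 2:C) sums <- sums + channel_slice(y_true, ch, C)
  if (any(abs(sums - 1) > 1e-8))
    stop("cce_loss: y_true is not one-hot (channel sums differ from 1)")
  p <- clip_probs(y_pred, cfg$clip_eps)
  n_pixels <- length(y_true) / C
  -sum(y_true * log(p)) / n_pixels
}

#' @rdname bce_loss
#' @export
cce_dice_loss <- function(y_true, y_pred, cfg = loss_config()) {
  cfg$lambda1 * cce_loss(y_true, y_pred, cfg) +
    cfg$lambda2 * dice_loss(y_true, y_pred, cfg)
}

## ---- gradients w.r.t. predictions (used by the trainer) --------------------

bce_loss_grad <- function(y_true, y_pred, cfg = loss_config()) {
  p <- clip_probs(y_pred, cfg$clip_eps)
  inside <- (y_pred > cfg$clip_eps) & (y_pred < 1 - cfg$clip_eps)
  g <- (p - y_true) / (p * (1 - p)) / length(y_true)
  g * inside
}

dice_loss_grad <- function(y_true, y_pred, cfg = loss_config()) {
  d <- dim(y_true)
  C <- if (!is.null(d) && length(d) >= 3L) d[3] else 1L
  g <- y_pred
  g[] <- 0
  for (ch in seq_len(C)) {
    yt <- channel_slice(y_true, ch, C)
    yp <- channel_slice(y_pred, ch, C)
    i <- sum(yt * yp)
    u <- sum(yt) + sum(yp)
    # d/dyp of 1 - (2i+s)/(u+s): -(2*yt*(u+s) - (2i+s)) / (u+s)^2, / C channels
    gch <- -(2 * yt * (u + cfg$smooth) - (2 * i + cfg$smooth)) /
      (u + cfg$smooth)^2 / C
    g <- assign_channel(g, gch, ch, C)
  }
  g
}

assign_channel <- function(x, value, ch, C) {
  d <- dim(x)
  if (is.null(d) || length(d) < 3L) return(value)
  if (length(d) == 3L) { x[, , ch] <- value; return(x) }
  x[, , ch, ] <- value
  x
}

focal_loss_grad <- function(y_true, y_pred, cfg = loss_config()) {
  p <- clip_probs(y_pred, cfg$clip_eps)
  inside <- (y_pred > cfg$clip_eps) & (y_pred < 1 - cfg$clip_eps)
  pt <- ifelse(y_true == 1, p, 1 - p)
  dpt <- cfg$alpha * (cfg$gamma * (1 - pt)^(cfg$gamma - 1) * log(pt) -
                        (1 - pt)^cfg$gamma / pt) / length(y_true)
  sign <- ifelse(y_true == 1, 1, -1)
  dpt * sign * inside
}

bce_dice_loss_grad <- function(y_true, y_pred, cfg = loss_config()) {
  cfg$lambda1 * bce_loss_grad(y_true, y_pred, cfg) +
    cfg$lambda2 * dice_loss_grad(y_true, y_pred, cfg)
}

cce_loss_grad <- function(y_true, y_pred, cfg = loss_config()) {
  d <- dim(y_true)
  C <- d[3]
  p <- clip_probs(y_pred, cfg$clip_eps)
  inside <- (y_pred > cfg$clip_eps) & (y_pred < 1 - cfg$clip_eps)
  n_pixels <- length(y_true) / C
  -(y_true / p) / n_pixels * inside
}

cce_dice_loss_grad <- function(y_true, y_pred, cfg = loss_config()) {
  cfg$lambda1 * cce_loss_grad(y_true, y_pred, cfg) +
    cfg$lambda2 * dice_loss_grad(y_true, y_pred, cfg)
}

#' Look up a loss by name
#'
#' @param name One of `"bce"`, `"dice"`, `"focal"`, `"bce_dice"`, `"cce"`,
#'   `"cce_dice"`.
#' @return List with elements `fn(y_true, y_pred, cfg)` and
#'   `grad(y_true, y_pred, cfg)`.
#' @export
get_loss <- function(name) {
  switch(match.arg(name, c("bce", "dice", "focal", "bce_dice", "cce", "cce_dice")),
         bce = list(fn = bce_loss, grad = bce_loss_grad),
         dice = list(fn = dice_loss, grad = dice_loss_grad),
         focal = list(fn = focal_loss, grad = focal_loss_grad),
         bce_dice = list(fn = bce_dice_loss, grad = bce_dice_loss_grad),
         cce = list(fn = cce_loss, grad = cce_loss_grad),
         cce_dice = list(fn = cce_dice_loss, grad = cce_dice_loss_grad))
}
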