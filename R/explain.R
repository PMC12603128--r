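#' Grad-CAM heatmap
#'
#' Class-discriminative localisation for the segmentation output: the class
#' score is the spatial sum of the chosen class's final softmax channel, the
#' channel weights are the global-average-pooled gradients of that score with
#' respect to the target layer's activations, and the map is the ReLU of the
#' weighted activation sum, bilinearly upsampled to the input resolution and
#' min-max normalised to `[0, 1]` (an all-zero map stays all-zero).
#'
#' @param model A `spine_unet` or `spine_unet_fit`.
#' @param image Input image matrix (`input_size x input_size`).
#' @param layer Plan name of a convolutional op (e.g. `"dec4.b.conv"`); the
#'   default is the last decoder convolution before the final 1x1 head.
#' @param class_index Zero-based class channel (1 = foreground in the binary
#'   model).
#' @return An object of class `gradcam_map`: list with the heatmap `map`,
#'   `layer` and `class_index`.
#' @export
gradcam <- function(model, image, layer = NULL, class_index = 1L) {
  if (inherits(model, "spine_unet_fit")) model <- model$model
  stopifnot(inherits(model, "spine_unet"))
  cfg <- model$config
  if (class_index < 0L || class_index >= cfg$n_classes)
    stop("class_index must lie in [0, n_classes)")
  conv_ops <- vapply(Filter(function(op) op$type %in% c("conv", "tconv"),
                            model$plan), `[[`, character(1), "name")
  if (is.null(layer)) {
    # last decoder conv unit output (post-activation), before the final head
    layer <- model$last_decoder_conv
  } else if (!layer %in% c(conv_ops, model$last_decoder_conv)) {
    stop("unknown convolutional layer '", layer, "'; available: ",
         paste(conv_ops, collapse = ", "))
  }
  x <- as_input_tensor(image, cfg)
  fwd <- nn_forward(model, x, training = FALSE, keep = TRUE)
  g <- fwd$outputs$out_final
  g[] <- 0
  g[, , class_index + 1L, ] <- 1
  bw <- nn_backward(model, fwd, list(out_final = g),
                    want_tensor_grads = layer)
  A <- get(layer, envir = fwd$tensors)
  G <- bw$tgrads[[layer]]
  if (is.null(G)) stop("no gradient reaches layer '", layer, "'")
  C <- dim(A)[3]
  wts <- vapply(seq_len(C), function(c) mean(G[, , c, 1]), numeric(1))
  m <- matrix(0, dim(A)[1], dim(A)[2])
  for (c in seq_len(C)) m <- m + wts[c] * A[, , c, 1]
  m[m < 0] <- 0
  m <- resize_bilinear(m, cfg$input_size, cfg$input_size)
  m[m < 0] <- 0
  mx <- max(m)
  if (mx > 0) m <- m / mx
  structure(list(map = m, layer = layer, class_index = as.integer(class_index)),
            class = "gradcam_map")
}

#' @export
print.gradcam_map <- function(x, ...) {
  cat(sprintf("<gradcam_map> %dx%d, layer %s, class %d, mean %.3f\n",
              nrow(x$map), ncol(x$map), x$layer, x$class_index, mean(x$map)))
  invisible(x)
}

#' @export
plot.gradcam_map <- function(x, image = NULL, ...) {
  op <- par(mar = c(1, 1, 2, 1))
  on.exit(par(op))
  if (!is.null(image)) {
    image(t(image[nrow(image):1, ]), col = gray(seq(0, 1, length.out = 256)),
          axes = FALSE, main = "Grad-CAM overlay")
    image(t(x$map[nrow(x$map):1, ]),
          col = hcl.colors(64, "inferno", alpha = 0.4), add = TRUE)
  } else {
    image(t(x$map[nrow(x$map):1, ]), col = hcl.colors(64, "inferno"),
          axes = FALSE, main = sprintf("Grad-CAM (class %d)", x$class_index))
  }
  invisible(x)
}
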