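## Layer-graph construction.  A plan is an ordered list of primitive ops
## (conv, tconv, bn, relu, pool2, pool3, concat, dropout, softmax); each op has
## one output tensor whose name equals the op name, so the plan doubles as the
## human-readable layer table.

build_plan <- function(cfg) {
  ops <- list()
  shapes <- list(input = c(cfg$input_size, cfg$input_channels))
  add_op <- function(op, size, channels) {
    ops[[length(ops) + 1L]] <<- op
    shapes[[op$output]] <<- c(size, channels)
  }
  # conv -> (BN) -> (ReLU); returns the name of the unit's output tensor
  conv_unit <- function(id, input, k, cout, bn = TRUE, act = "relu") {
    s <- shapes[[input]][1]; cin <- shapes[[input]][2]
    nm <- paste0(id, ".conv")
    add_op(list(name = nm, type = "conv", k = k, cin = cin, cout = cout,
                inputs = input, output = nm), s, cout)
    cur <- nm
    if (bn) {
      nm <- paste0(id, ".bn")
      add_op(list(name = nm, type = "bn", c = cout, inputs = cur, output = nm), s, cout)
      cur <- nm
    }
    if (act == "relu") {
      nm <- paste0(id, ".relu")
      add_op(list(name = nm, type = "relu", inputs = cur, output = nm), s, cout)
      cur <- nm
    }
    cur
  }
  pool2 <- function(id, input) {
    s <- shapes[[input]][1]; cch <- shapes[[input]][2]
    add_op(list(name = id, type = "pool2", inputs = input, output = id), s %/% 2L, cch)
    id
  }
  dropout <- function(id, input) {
    s <- shapes[[input]]
    add_op(list(name = id, type = "dropout", rate = cfg$dropout_rate,
                inputs = input, output = id), s[1], s[2])
    id
  }

  # -- first encoder block --------------------------------------------------
  if (cfg$use_inception) {
    ic <- cfg$inception
    b1 <- conv_unit("inc.b1", "input", 1L, ic$branch1_filters)
    b2 <- conv_unit("inc.b2r", "input", 1L, ic$branch2_reduce)
    b2 <- conv_unit("inc.b2", b2, 3L, ic$branch2_filters)
    b3 <- conv_unit("inc.b3r", "input", 1L, ic$branch3_reduce)
    b3 <- conv_unit("inc.b3", b3, 5L, ic$branch3_filters)
    s <- shapes[["input"]]
    add_op(list(name = "inc.pool", type = "pool3", inputs = "input",
                output = "inc.pool"), s[1], s[2])
    b4 <- conv_unit("inc.b4", "inc.pool", 1L, ic$branch4_filters)
    parts <- c(b1, b2, b3, b4)
    cch <- sum(vapply(parts, function(p) shapes[[p]][2], integer(1)))
    add_op(list(name = "enc0", type = "concat", inputs = parts, output = "enc0"),
           s[1], cch)
    skip0 <- "enc0"
  } else {
    a <- conv_unit("enc0.a", "input", 3L, 64L)
    skip0 <- conv_unit("enc0.b", a, 3L, 64L)
  }
  cur <- pool2("pool1", skip0)

  # -- encoder blocks 2..4 --------------------------------------------------
  skips <- character(3)
  for (i in seq_along(cfg$encoder_filters)) {
    f <- cfg$encoder_filters[i]
    a <- conv_unit(sprintf("enc%d.a", i), cur, 3L, f)
    b <- conv_unit(sprintf("enc%d.b", i), a, 3L, f)
    # dropout in the deeper encoder blocks (overall blocks 3 and 4)
    if (i >= 2L && cfg$dropout_rate > 0)
      b <- dropout(sprintf("enc%d.drop", i), b)
    skips[i] <- b
    cur <- pool2(sprintf("pool%d", i + 1L), b)
  }

  # -- bottleneck -----------------------------------------------------------
  fb <- cfg$bottleneck_filters
  cur <- conv_unit("bott.a", cur, 3L, fb)
  if (cfg$dropout_rate > 0) cur <- dropout("bott.a.drop", cur)
  cur <- conv_unit("bott.b", cur, 3L, fb)
  if (cfg$dropout_rate > 0) cur <- dropout("bott.b.drop", cur)

  outputs <- character(0)
  if (cfg$use_dual_output) {
    h <- conv_unit("bott.head", cur, 1L, cfg$n_classes, bn = FALSE, act = "linear")
    s <- shapes[[h]]
    add_op(list(name = "out_bottleneck", type = "softmax", inputs = h,
                output = "out_bottleneck"), s[1], s[2])
    outputs <- "out_bottleneck"
  }

  # -- decoder --------------------------------------------------------------
  skip_order <- c(rev(skips), skip0)
  for (j in seq_along(cfg$decoder_filters)) {
    dj <- cfg$decoder_filters[j]
    s <- shapes[[cur]][1]; cin <- shapes[[cur]][2]
    nm <- sprintf("dec%d.up", j)
    add_op(list(name = nm, type = "tconv", cin = cin, cout = dj,
                inputs = cur, output = nm), s * 2L, dj)
    nm2 <- sprintf("dec%d.up.relu", j)
    add_op(list(name = nm2, type = "relu", inputs = nm, output = nm2), s * 2L, dj)
    sk <- skip_order[j]
    cch <- dj + shapes[[sk]][2]
    nm3 <- sprintf("dec%d.cat", j)
    add_op(list(name = nm3, type = "concat", inputs = c(nm2, sk), output = nm3),
           s * 2L, cch)
    a <- conv_unit(sprintf("dec%d.a", j), nm3, 3L, dj)
    cur <- conv_unit(sprintf("dec%d.b", j), a, 3L, dj)
  }

  h <- conv_unit("final.head", cur, 1L, cfg$n_classes, bn = FALSE, act = "linear")
  s <- shapes[[h]]
  add_op(list(name = "out_final", type = "softmax", inputs = h,
              output = "out_final"), s[1], s[2])
  outputs <- c(outputs, "out_final")

  list(ops = ops, shapes = shapes, outputs = outputs,
       last_decoder_conv = cur)
}

#' Build the segmentation network
#'
#' Realizes a [unet_config()] as a `spine_unet` model: the ordered layer plan
#' plus initialized weights (He-scaled Gaussian convolution weights, zero
#' biases, unit batch-norm scale, zero shift, running statistics at (0, 1)).
#'
#' @param config A [unet_config()].
#' @param seed Optional integer; when given, weight initialization is drawn
#'   under this seed without disturbing the caller's RNG state.
#' @return An object of class `spine_unet` with elements `config`, `plan`,
#'   `params`, `state` and `outputs` (the softmax output tensor names).
#' @examples
#' m <- build_unet(unet_config(input_size = 16,
#'   encoder_filters = c(4, 8, 8), bottleneck_filters = 8,
#'   decoder_filters = c(8, 8, 4, 4),
#'   inception = inception_config(2, 2, 4, 2, 2, 2)), seed = 1)
#' count_params_built(m)
#' @export
build_unet <- function(config, seed = NULL) {
  validate_unet_config(config)
  plan <- build_plan(config)
  init <- function() {
    params <- list(); state <- list()
    for (op in plan$ops) {
      if (op$type == "conv") {
        k <- op$k
        sdv <- sqrt(2 / (k * k * op$cin))
        params[[op$name]] <- list(
          w = array(rnorm(k * k * op$cin * op$cout, sd = sdv),
                    dim = c(k, k, op$cin, op$cout)),
          b = numeric(op$cout))
      } else if (op$type == "tconv") {
        sdv <- sqrt(2 / (4 * op$cin))
        params[[op$name]] <- list(
          w = array(rnorm(4 * op$cin * op$cout, sd = sdv),
                    dim = c(2L, 2L, op$cin, op$cout)),
          b = numeric(op$cout))
      } else if (op$type == "bn") {
        params[[op$name]] <- list(gamma = rep(1, op$c), beta = numeric(op$c))
        state[[op$name]] <- list(mean = numeric(op$c), var = rep(1, op$c))
      }
    }
    list(params = params, state = state)
  }
  pw <- if (is.null(seed)) init() else withr::with_seed(seed, init())
  structure(list(config = config, plan = plan$ops, shapes = plan$shapes,
                 outputs = plan$outputs, last_decoder_conv = plan$last_decoder_conv,
                 params = pw$params, state = pw$state),
            class = "spine_unet")
}

#' Parameter count of a realized network
#'
#' Reads the counts from the model's actual weight arrays (convolution and
#' batch-norm scale/shift parameters are trainable; batch-norm running
#' statistics are not).  For any valid configuration this agrees field-for-field
#' with [count_params_analytic()].
#'
#' @param model A `spine_unet`.
#' @return A list with `total`, `trainable`, `non_trainable`.
#' @export
count_params_built <- function(model) {
  stopifnot(inherits(model, "spine_unet"))
  tr <- sum(vapply(model$params, function(p) sum(lengths(lapply(p, as.vector))),
                   numeric(1)))
  ntr <- sum(vapply(model$state, function(s) sum(lengths(lapply(s, as.vector))),
                    numeric(1)))
  list(total = tr + ntr, trainable = tr, non_trainable = ntr)
}

#' Layer table of a model
#'
#' @param model A `spine_unet`.
#' @return A data.frame with one row per primitive op: name, type, output shape
#'   and parameter count.
#' @export
layer_table <- function(model) {
  stopifnot(inherits(model, "spine_unet"))
  rows <- lapply(model$plan, function(op) {
    s <- model$shapes[[op$output]]
    np <- 0
    if (!is.null(model$params[[op$name]]))
      np <- np + sum(lengths(lapply(model$params[[op$name]], as.vector)))
    if (!is.null(model$state[[op$name]]))
      np <- np + sum(lengths(lapply(model$state[[op$name]], as.vector)))
    data.frame(name = op$name, type = op$type,
               output_shape = sprintf("(%d, %d, %d)", s[1], s[1], s[2]),
               params = np, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.spine_unet <- function(x, ...) {
  pc <- count_params_built(x)
  cat("<spine_unet>\n")
  cat(sprintf("  input   : %d x %d x %d\n", x$config$input_size,
              x$config$input_size, x$config$input_channels))
  cat(sprintf("  classes : %d\n", x$config$n_classes))
  cat(sprintf("  variant : inception=%s, dual_output=%s\n",
              x$config$use_inception, x$config$use_dual_output))
  cat(sprintf("  params  : total %s | trainable %s | non-trainable %s\n",
              format(pc$total, big.mark = ","),
              format(pc$trainable, big.mark = ","),
              format(pc$non_trainable, big.mark = ",")))
  invisible(x)
}

#' @export
summary.spine_unet <- function(object, ...) {
  tab <- layer_table(object)
  print(object)
  cat("\n")
  print(tab, row.names = FALSE)
  invisible(tab)
}
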