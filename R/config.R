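#' Inception block configuration
#'
#' Filter plan for the four-branch Inception block that replaces the first
#' encoder stage: a 1x1 branch, a 1x1 -> 3x3 branch, a 1x1 -> 5x5 branch and a
#' 3x3 max-pool -> 1x1 branch.  Every convolution carries batch normalisation.
#' The concatenated output has `branch1_filters + branch2_filters +
#' branch3_filters + branch4_filters` channels (256 at the defaults).
#'
#' @param branch1_filters 1x1 branch filters.
#' @param branch2_reduce,branch2_filters 1x1 reduction and 3x3 filters of the
#'   medium-scale branch.
#' @param branch3_reduce,branch3_filters 1x1 reduction and 5x5 filters of the
#'   large-scale branch.
#' @param branch4_filters 1x1 filters after the 3x3 max-pool branch.
#' @return An object of class `inception_config`.
#' @export
inception_config <- function(branch1_filters = 64L,
                             branch2_reduce = 96L, branch2_filters = 128L,
                             branch3_reduce = 16L, branch3_filters = 32L,
                             branch4_filters = 32L) {
  cfg <- list(branch1_filters = as.integer(branch1_filters),
              branch2_reduce = as.integer(branch2_reduce),
              branch2_filters = as.integer(branch2_filters),
              branch3_reduce = as.integer(branch3_reduce),
              branch3_filters = as.integer(branch3_filters),
              branch4_filters = as.integer(branch4_filters))
  if (any(unlist(cfg) <= 0L)) stop("inception_config: all filter counts must be positive")
  structure(cfg, class = "inception_config")
}

inception_out_channels <- function(ic) {
  ic$branch1_filters + ic$branch2_filters + ic$branch3_filters + ic$branch4_filters
}

#' Network configuration
#'
#' Declarative description of the enhanced U-Net.  The encoder is the Inception
#' first block (or a plain two-convolution block when `use_inception = FALSE`)
#' followed by three double-convolution blocks; each of the four stages ends in
#' a 2x2 max pool, so `input_size` must be divisible by 16 and the bottleneck
#' sits at `input_size / 16` (8 pixels at the default 128).  The decoder mirrors
#' the encoder with 2x2 stride-2 transposed convolutions and skip
#' concatenations.  With `use_dual_output = TRUE` a 1x1 softmax head is attached
#' to the bottleneck as an auxiliary supervision signal next to the final
#' full-resolution softmax head.
#'
#' Conventions fixed by the architecture: 'same' padding everywhere, every
#' convolution carries a bias, batch normalisation follows every 3x3/5x5/1x1
#' convolution except the two 1x1 output heads, and transposed convolutions
#' carry bias + ReLU but no batch normalisation.
#'
#' @param input_size Image side in pixels, divisible by 16.
#' @param input_channels Image channels (1 for grayscale MRI).
#' @param n_classes Number of segmentation classes (2 binary, 4 multiclass).
#' @param encoder_filters Filters of the three post-Inception encoder blocks.
#' @param bottleneck_filters Filters of the two bottleneck convolutions.
#' @param decoder_filters Filters of the four decoder stages
#'   (`length(encoder_filters) + 1` entries).
#' @param dropout_rate Dropout rate applied in the deeper encoder blocks and at
#'   the bottleneck.
#' @param use_inception Use the Inception first block; otherwise a plain block
#'   of two 3x3/64 convolutions.
#' @param use_dual_output Attach the auxiliary bottleneck softmax head.
#' @param inception An [inception_config()].
#' @return An object of class `unet_config`.
#' @examples
#' cfg <- unet_config()
#' count_params_analytic(cfg)
#' @export
unet_config <- function(input_size = 128L, input_channels = 1L, n_classes = 2L,
                        encoder_filters = c(128L, 256L, 512L),
                        bottleneck_filters = 1024L,
                        decoder_filters = c(512L, 256L, 128L, 64L),
                        dropout_rate = 0.5,
                        use_inception = TRUE, use_dual_output = TRUE,
                        inception = inception_config()) {
  cfg <- structure(list(
    input_size = as.integer(input_size),
    input_channels = as.integer(input_channels),
    n_classes = as.integer(n_classes),
    encoder_filters = as.integer(encoder_filters),
    bottleneck_filters = as.integer(bottleneck_filters),
    decoder_filters = as.integer(decoder_filters),
    dropout_rate = dropout_rate,
    use_inception = isTRUE(use_inception),
    use_dual_output = isTRUE(use_dual_output),
    inception = inception), class = "unet_config")
  validate_unet_config(cfg)
  cfg
}

validate_unet_config <- function(cfg) {
  if (cfg$input_size <= 0L || cfg$input_size %% 16L != 0L)
    stop("unet_config: input_size must be a positive multiple of 16 (four 2x2 pools)")
  if (cfg$n_classes < 2L)
    stop("unet_config: n_classes must be at least 2")
  if (cfg$input_channels < 1L)
    stop("unet_config: input_channels must be positive")
  if (length(cfg$encoder_filters) != 3L)
    stop("unet_config: encoder_filters must list the three post-Inception blocks")
  if (length(cfg$decoder_filters) != length(cfg$encoder_filters) + 1L)
    stop("unet_config: decoder_filters must have length(encoder_filters) + 1 entries")
  if (any(c(cfg$encoder_filters, cfg$bottleneck_filters, cfg$decoder_filters) <= 0L))
    stop("unet_config: filter counts must be positive")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("unet_config: dropout_rate must lie in [0, 1)")
  if (!inherits(cfg$inception, "inception_config"))
    stop("unet_config: inception must be an inception_config")
  invisible(cfg)
}

## ---- closed-form parameter accounting -------------------------------------

# One convolution: k^2 * cin * cout weights + cout biases; batch norm adds
# 2*cout trainable (scale, shift) and 2*cout non-trainable (running stats).
conv_param_count <- function(k, cin, cout, bn = TRUE) {
  c(trainable = k * k * cin * cout + cout + if (bn) 2 * cout else 0,
    non_trainable = if (bn) 2 * cout else 0)
}

#' Closed-form parameter count
#'
#' Computes total/trainable/non-trainable parameter counts of the configured
#' network by per-layer arithmetic, without constructing any weights.  At the
#' default binary configuration this reproduces the architecture's accounting
#' exactly: 31,475,396 total, 31,463,140 trainable, 12,256 non-trainable.
#'
#' @param config A [unet_config()].
#' @return A list with integer-valued `total`, `trainable`, `non_trainable`.
#' @export
count_params_analytic <- function(config) {
  validate_unet_config(config)
  acc <- c(trainable = 0, non_trainable = 0)
  add <- function(x) acc <<- acc + x
  cin <- config$input_channels
  if (config$use_inception) {
    ic <- config$inception
    add(conv_param_count(1, cin, ic$branch1_filters))
    add(conv_param_count(1, cin, ic$branch2_reduce))
    add(conv_param_count(3, ic$branch2_reduce, ic$branch2_filters))
    add(conv_param_count(1, cin, ic$branch3_reduce))
    add(conv_param_count(5, ic$branch3_reduce, ic$branch3_filters))
    add(conv_param_count(1, cin, ic$branch4_filters))
    c0 <- inception_out_channels(ic)
  } else {
    add(conv_param_count(3, cin, 64L))
    add(conv_param_count(3, 64L, 64L))
    c0 <- 64L
  }
  prev <- c0
  for (f in config$encoder_filters) {
    add(conv_param_count(3, prev, f))
    add(conv_param_count(3, f, f))
    prev <- f
  }
  fb <- config$bottleneck_filters
  add(conv_param_count(3, prev, fb))
  add(conv_param_count(3, fb, fb))
  if (config$use_dual_output)
    add(conv_param_count(1, fb, config$n_classes, bn = FALSE))
  skips <- c(rev(config$encoder_filters), c0)
  prev <- fb
  for (j in seq_along(config$decoder_filters)) {
    dj <- config$decoder_filters[j]
    # transposed conv 2x2: weights + bias, no batch norm
    add(c(trainable = 4 * prev * dj + dj, non_trainable = 0))
    add(conv_param_count(3, dj + skips[j], dj))
    add(conv_param_count(3, dj, dj))
    prev <- dj
  }
  add(conv_param_count(1, prev, config$n_classes, bn = FALSE))
  list(total = unname(acc["trainable"] + acc["non_trainable"]),
       trainable = unname(acc["trainable"]),
       non_trainable = unname(acc["non_trainable"]))
}

## ---- flat serialization ----------------------------------------------------

config_to_flat <- function(cfg) {
  list(input_size = cfg$input_size, input_channels = cfg$input_channels,
       n_classes = cfg$n_classes,
       encoder_filters = cfg$encoder_filters,
       bottleneck_filters = cfg$bottleneck_filters,
       decoder_filters = cfg$decoder_filters,
       dropout_rate = cfg$dropout_rate,
       use_inception = cfg$use_inception,
       use_dual_output = cfg$use_dual_output,
       inception_branch1_filters = cfg$inception$branch1_filters,
       inception_branch2_reduce = cfg$inception$branch2_reduce,
       inception_branch2_filters = cfg$inception$branch2_filters,
       inception_branch3_reduce = cfg$inception$branch3_reduce,
       inception_branch3_filters = cfg$inception$branch3_filters,
       inception_branch4_filters = cfg$inception$branch4_filters)
}

flat_to_config <- function(x) {
  unet_config(input_size = x$input_size,
              input_channels = x$input_channels %||% 1L,
              n_classes = x$n_classes %||% 2L,
              encoder_filters = unlist(x$encoder_filters),
              bottleneck_filters = x$bottleneck_filters,
              decoder_filters = unlist(x$decoder_filters),
              dropout_rate = x$dropout_rate %||% 0.5,
              use_inception = x$use_inception %||% TRUE,
              use_dual_output = x$use_dual_output %||% TRUE,
              inception = inception_config(
                x$inception_branch1_filters %||% 64L,
                x$inception_branch2_reduce %||% 96L,
                x$inception_branch2_filters %||% 128L,
                x$inception_branch3_reduce %||% 16L,
                x$inception_branch3_filters %||% 32L,
                x$inception_branch4_filters %||% 32L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a network configuration
#'
#' Flat key-value serialization.  JSON is written natively; `.yaml`/`.yml`
#' files are read through the yaml package when available.
#'
#' @param config A [unet_config()].
#' @param path File path.
#' @export
write_unet_config <- function(config, path) {
  validate_unet_config(config)
  jsonlite::write_json(config_to_flat(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_unet_config
#' @export
read_unet_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  flat_to_config(x)
}
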