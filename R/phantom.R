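#' Spine phantom configuration
#'
#' Parameters of the synthetic sagittal lumbar-spine phantom: a gently curved
#' vertical column of bright vertebral bodies (class 1), darker elliptical
#' intervertebral discs between consecutive vertebrae (class 2) and a thin
#' low-intensity spinal-canal stripe posterior to the column (class 3), over a
#' noisy dark background.  Geometry defaults are fractions of the image side so
#' the same configuration renders at 128 or 64 pixels.  Intensities mimic
#' T1-weighted contrast: bright marrow/bone, intermediate disc, dark canal.
#'
#' @param size Image side in pixels.
#' @param n_vertebrae Number of vertebral bodies (>= 2).
#' @param vertebra_height,vertebra_width Body size in pixels.
#' @param size_jitter Fractional jitter applied per vertebra/disc.
#' @param disc_height Disc thickness in pixels.
#' @param canal_width Canal stripe width in pixels.
#' @param column_curvature Quadratic bow of the column axis (fraction of the
#'   side at the image border).
#' @param intensity_vertebra,intensity_disc,intensity_canal,intensity_background
#'   Mean intensities on `[0, 1]`.
#' @param blur_sigma Gaussian blur of the rendered image, pixels.
#' @param noise_sigma Additive Gaussian noise s.d.
#' @param seed Integer seed; the sample is fully determined by it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(size = 128L, n_vertebrae = 6L,
                           vertebra_height = round(0.095 * size),
                           vertebra_width = round(0.22 * size),
                           size_jitter = 0.1,
                           disc_height = max(2, round(0.035 * size)),
                           canal_width = max(2, round(0.05 * size)),
                           column_curvature = 0.04,
                           intensity_vertebra = 0.75, intensity_disc = 0.45,
                           intensity_canal = 0.25, intensity_background = 0.10,
                           blur_sigma = 0.7, noise_sigma = 0.03,
                           seed = 1L) {
  cfg <- structure(list(size = as.integer(size),
                        n_vertebrae = as.integer(n_vertebrae),
                        vertebra_height = vertebra_height,
                        vertebra_width = vertebra_width,
                        size_jitter = size_jitter,
                        disc_height = disc_height,
                        canal_width = canal_width,
                        column_curvature = column_curvature,
                        intensity_vertebra = intensity_vertebra,
                        intensity_disc = intensity_disc,
                        intensity_canal = intensity_canal,
                        intensity_background = intensity_background,
                        blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                        seed = as.integer(seed)),
                   class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

# vertical clearance between a vertebra and the neighbouring disc
gap_margin <- function(size) max(1L, round(size / 64))

validate_phantom_config <- function(cfg) {
  if (cfg$n_vertebrae < 2L) stop("phantom_config: n_vertebrae must be >= 2")
  ints <- c(cfg$intensity_vertebra, cfg$intensity_disc, cfg$intensity_canal,
            cfg$intensity_background)
  if (any(ints < 0 | ints > 1)) stop("phantom_config: intensities must lie in [0, 1]")
  gm <- gap_margin(cfg$size)
  col_h <- cfg$n_vertebrae * cfg$vertebra_height +
    (cfg$n_vertebrae - 1) * (cfg$disc_height + gm)
  if (col_h * (1 + cfg$size_jitter) > 0.95 * cfg$size)
    stop("phantom_config: vertebral column does not fit inside the image ",
         "(reduce n_vertebrae, vertebra_height or disc_height)")
  if (cfg$vertebra_width * (1 + cfg$size_jitter) + cfg$canal_width + 4 >
      0.9 * cfg$size)
    stop("phantom_config: column + canal too wide for the image")
  invisible(cfg)
}

# Separable Gaussian blur with kernel truncated at 3 sigma; replicate padding.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_1d <- function(m) {
    n <- nrow(m)
    idx <- outer(seq_len(n), seq(-r, r), "+")
    idx[idx < 1] <- 1; idx[idx > n] <- n
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(smooth_1d(t(smooth_1d(img))))
}

#' Generate one spine phantom
#'
#' Fully determined by `cfg$seed`: geometry jitter, rendering noise and blur
#' all flow through a scoped RNG, leaving the caller's random state untouched.
#' Masks are defined on the crisp pre-blur labels, so ground truth stays exact
#' while the image has soft edges.
#'
#' @param cfg A [phantom_config()].
#' @return An object of class `phantom_sample`: `image` (`size x size` in
#'   `[0, 1]`), `mask4` (labels 0-3), `mask2` (binary foreground), plus the
#'   generating `config`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  validate_phantom_config(cfg)
  withr::with_seed(cfg$seed, {
    S <- cfg$size
    mask <- matrix(0L, S, S)
    rows <- matrix(rep(seq_len(S), S), S, S)      # row index (vertical, y)
    cols <- matrix(rep(seq_len(S), each = S), S, S)
    nv <- cfg$n_vertebrae
    gm <- gap_margin(S)
    col_h <- nv * cfg$vertebra_height + (nv - 1) * (cfg$disc_height + gm)
    top <- (S - col_h) / 2
    cx0 <- S * 0.42
    curve <- function(y) cx0 + cfg$column_curvature * S * ((y - S / 2) / (S / 2))^2
    jit <- function(x) x * (1 + runif(1, -cfg$size_jitter, cfg$size_jitter))
    centres <- numeric(nv)
    heights <- numeric(nv)
    y <- top
    for (i in seq_len(nv)) {
      h <- jit(cfg$vertebra_height)
      w <- jit(cfg$vertebra_width)
      cy <- y + h / 2
      cx <- curve(cy) + runif(1, -1, 1)
      # rounded rectangle: superellipse exponent 4
      inside <- (abs(rows - cy) / (h / 2))^4 + (abs(cols - cx) / (w / 2))^4 <= 1
      mask[inside] <- 1L
      centres[i] <- cy; heights[i] <- h
      y <- y + h + cfg$disc_height + gm
    }
    for (i in seq_len(nv - 1)) {
      gap_top <- centres[i] + heights[i] / 2
      gap_bot <- centres[i + 1] - heights[i + 1] / 2
      cy <- (gap_top + gap_bot) / 2
      hh <- max(1.2, cfg$disc_height * (1 + runif(1, -cfg$size_jitter, cfg$size_jitter))) / 2
      ww <- jit(cfg$vertebra_width * 0.85) / 2
      cx <- curve(cy)
      inside <- ((rows - cy) / hh)^2 + ((cols - cx) / ww)^2 <= 1
      mask[inside & mask == 0L] <- 2L
    }
    # spinal canal: vertical stripe posterior (to the right) of the column
    # clear the widest possible jittered vertebra so the stripe stays connected
    canal_off <- cfg$vertebra_width * (1 + cfg$size_jitter) / 2 + 3 +
      cfg$canal_width / 2
    ys <- seq_len(S)
    span <- ys >= top - 1 & ys <= top + col_h + 1
    canal_cx <- curve(ys) + canal_off
    inside <- abs(sweep(cols, 1, canal_cx)) <= cfg$canal_width / 2 &
      matrix(span, S, S)
    mask[inside & mask == 0L] <- 3L

    means <- c(cfg$intensity_background, cfg$intensity_vertebra,
               cfg$intensity_disc, cfg$intensity_canal)
    img <- matrix(means[mask + 1L], S, S)
    img <- gaussian_blur(img, cfg$blur_sigma)
    if (cfg$noise_sigma > 0)
      img <- img + matrix(rnorm(S * S, sd = cfg$noise_sigma), S, S)
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask4 = mask,
                   mask2 = matrix(as.integer(mask > 0L), S, S),
                   config = cfg),
              class = "phantom_sample")
  })
}

#' Generate a phantom dataset
#'
#' Draws `n` phantoms whose per-sample seeds are derived deterministically from
#' the master seed, converts them to training-ready slice pairs (image,
#' class-index map, one-hot mask and bottleneck target) and optionally writes
#' them in the same cache layout the preprocessing pipeline emits, so training
#' consumes phantoms and real data identically.
#'
#' @param cfg A [phantom_config()]; its `seed` field is overridden per sample.
#' @param n Number of samples.
#' @param seed Master seed.
#' @param n_classes 2 (foreground/background) or 4 (all structures).
#' @param cache_dir Optional cache directory, see [write_cache()].
#' @return List of slice pairs; each carries its phantom seed in `provenance`.
#' @export
generate_phantom_dataset <- function(cfg = phantom_config(), n = 10L,
                                     seed = 1L, n_classes = 2L,
                                     cache_dir = NULL) {
  stopifnot(n >= 1)
  seeds <- (as.integer(seed) + 7919L * seq_len(n)) %% .Machine$integer.max
  pairs <- lapply(seq_len(n), function(i) {
    ci <- cfg; ci$seed <- seeds[i]
    ph <- generate_phantom(ci)
    cm <- if (n_classes == 2L) ph$mask2 else ph$mask4
    make_slice_pair(ph$image, cm, n_classes,
                    provenance = list(kind = "phantom", index = i,
                                      seed = seeds[i]))
  })
  if (!is.null(cache_dir)) write_cache(pairs, cache_dir)
  pairs
}

#' @export
print.phantom_sample <- function(x, ...) {
  fg <- mean(x$mask2)
  cat(sprintf("<phantom_sample> %dx%d, %d vertebrae, foreground %.1f%%, seed %d\n",
              nrow(x$image), ncol(x$image), x$config$n_vertebrae, 100 * fg,
              x$config$seed))
  invisible(x)
}
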