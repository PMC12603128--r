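#' Construct a volume record
#'
#' @param voxels 3D numeric array, slices along the first axis.
#' @param labels 3D integer array of raw mask codes, same shape.
#' @param series_tag Series/modality name, e.g. `"t1"` or `"t2_space"`.
#' @return An object of class `volume_record`.
#' @export
volume_record <- function(voxels, labels, series_tag = "") {
  if (!identical(dim(voxels), dim(labels)))
    stop("voxels and labels must have identical shapes")
  if (length(dim(voxels)) != 3L) stop("expected 3D arrays")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  structure(list(voxels = voxels, labels = array(as.integer(labels), dim(labels)),
                 series_tag = as.character(series_tag)),
            class = "volume_record")
}

#' Keep T1-weighted series
#'
#' Filters volume records whose series tag matches a T1 pattern
#' (case-insensitive regular expression; the default substring `"t1"` also
#' matches names like `"t1_space"`).  Order is preserved.  An empty result
#' raises a warning, not an error.
#'
#' @param records List of [volume_record()]s.
#' @param pattern Regular expression matched against `series_tag`.
#' @return The matching subset of `records`.
#' @export
select_t1 <- function(records, pattern = "t1") {
  tags <- vapply(records, function(r) r$series_tag, character(1))
  keep <- grepl(pattern, tags, ignore.case = TRUE)
  if (!any(keep)) warning("select_t1: no series matched pattern '", pattern, "'")
  records[keep]
}

#' Central slice of a volume
#'
#' Returns the slice at zero-based index `floor(depth / 2)` of both the image
#' and label volumes (the even-depth convention picks the upper of the two
#' middle slices).
#'
#' @param record A [volume_record()].
#' @return List with `image` and `labels` matrices and the zero-based
#'   `slice_index`.
#' @export
central_slice <- function(record) {
  depth <- dim(record$voxels)[1]
  if (is.na(depth) || depth < 1L) stop("central_slice: empty volume")
  idx0 <- depth %/% 2L
  list(image = record$voxels[idx0 + 1L, , ],
       labels = record$labels[idx0 + 1L, , ],
       slice_index = idx0)
}

#' Rescale an image to 8-bit
#'
#' Maps intensities affinely onto `[0, 255]` and rounds half away from zero to
#' integers.  A constant image maps to all zeros.
#'
#' @param image Finite numeric matrix.
#' @return Integer matrix with values in `0:255`.
#' @export
rescale_to_8bit <- function(image) {
  if (any(!is.finite(image))) stop("rescale_to_8bit: non-finite values in input")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    out <- image; out[] <- 0L
    return(matrix(as.integer(out), nrow(image), ncol(image)))
  }
  scaled <- 255 * (image - rng[1]) / (rng[2] - rng[1])
  matrix(as.integer(floor(scaled + 0.5)), nrow(image), ncol(image))
}

# Pixel-centre index mapping shared by both interpolators: destination pixel d
# (0-based) samples source coordinate (d + 0.5) * scale - 0.5.
resize_bilinear <- function(img, out_h, out_w = out_h) {
  in_h <- nrow(img); in_w <- ncol(img)
  coords <- function(n_out, n_in) {
    cc <- (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5
    lo <- pmin(pmax(floor(cc), 0), n_in - 1)
    hi <- pmin(lo + 1, n_in - 1)
    w <- pmin(pmax(cc - lo, 0), 1)
    list(lo = lo + 1, hi = hi + 1, w = w)
  }
  y <- coords(out_h, in_h); x <- coords(out_w, in_w)
  outer(1 - y$w, 1 - x$w) * img[y$lo, x$lo] +
    outer(1 - y$w, x$w) * img[y$lo, x$hi] +
    outer(y$w, 1 - x$w) * img[y$hi, x$lo] +
    outer(y$w, x$w) * img[y$hi, x$hi]
}

resize_nearest <- function(img, out_h, out_w = out_h) {
  pick <- function(n_out, n_in)
    pmin(pmax(floor((seq_len(n_out) - 0.5) * (n_in / n_out)), 0), n_in - 1) + 1
  img[pick(out_h, nrow(img)), pick(out_w, ncol(img)), drop = FALSE]
}

#' Resize an image/label pair
#'
#' The image is resized with bilinear interpolation (pixel-centre convention)
#' and divided by 255 into `[0, 1]`; the labels are resized with
#' nearest-neighbour sampling so no new label values can appear.
#'
#' @param image 8-bit image matrix (values in `0:255`).
#' @param labels Integer label matrix, same shape.
#' @param size Output side in pixels.
#' @return List with `image` (numeric in `[0, 1]`) and `labels` (integer).
#' @export
resize_pair <- function(image, labels, size = 128L) {
  stopifnot(size > 0)
  img <- resize_bilinear(image, size, size) / 255
  lab <- resize_nearest(labels, size, size)
  list(image = img, labels = matrix(as.integer(lab), size, size))
}

#' One-hot mask targets
#'
#' Builds the class-index map from raw mask codes (binary rule: any nonzero
#' code is foreground; multiclass: through `label_map`), one-hot encodes it at
#' full resolution, and derives the auxiliary bottleneck target by
#' nearest-neighbour downsampling of the class-index map to
#' `bottleneck_size` before one-hot encoding.
#'
#' @param labels Integer label matrix.
#' @param label_map Named integer vector mapping raw codes to class indices in
#'   `0:(n_classes - 1)` (ignored when `n_classes == 2`); every raw code
#'   present must be mapped and the background code must map to 0.
#' @param n_classes 2 (binary) or more.
#' @param bottleneck_size Side of the bottleneck target (input side / 16 by
#'   convention; 8 for 128-pixel inputs).
#' @return List with `mask_onehot` (`size x size x C`), `bottleneck_onehot`
#'   (`bottleneck_size x bottleneck_size x C`) and the intermediate
#'   `class_map`.
#' @export
encode_masks <- function(labels, label_map = NULL, n_classes = 2L,
                         bottleneck_size = nrow(labels) %/% 16L) {
  if (n_classes == 2L) {
    cm <- matrix(as.integer(labels != 0L), nrow(labels), ncol(labels))
  } else {
    if (is.null(label_map)) stop("encode_masks: multiclass requires a label_map")
    codes <- sort(unique(as.vector(labels)))
    missing <- setdiff(as.character(codes), names(label_map))
    if (length(missing))
      stop("encode_masks: unmapped raw label codes: ",
           paste(missing, collapse = ", "))
    if (any(label_map < 0L | label_map >= n_classes))
      stop("encode_masks: label_map values must lie in [0, n_classes)")
    cm <- matrix(as.integer(label_map[as.character(labels)]),
                 nrow(labels), ncol(labels))
  }
  bn <- resize_nearest(cm, bottleneck_size, bottleneck_size)
  list(mask_onehot = one_hot(cm, n_classes),
       bottleneck_onehot = one_hot(bn, n_classes),
       class_map = cm)
}

one_hot <- function(class_map, n_classes) {
  out <- array(0, dim = c(nrow(class_map), ncol(class_map), n_classes))
  for (c in seq_len(n_classes)) out[, , c] <- (class_map == c - 1L) * 1
  out
}

make_slice_pair <- function(image, class_map, n_classes, provenance = list()) {
  bn <- resize_nearest(class_map, nrow(image) %/% 16L)
  list(image = image,
       class_map = class_map,
       mask_onehot = one_hot(class_map, n_classes),
       bottleneck_onehot = one_hot(bn, n_classes),
       n_classes = as.integer(n_classes),
       provenance = provenance)
}

#' Build a training dataset from labelled volumes
#'
#' Full preprocessing composition: T1 selection, central slice, 8-bit rescale,
#' 128x128 resize with `[0, 1]` normalisation, one-hot mask encoding with the
#' 8x8 bottleneck target.  Deterministic: identical inputs give identical
#' slice pairs.
#'
#' @param records List of [volume_record()]s.
#' @param label_map See [encode_masks()].
#' @param n_classes 2 or 4.
#' @param size Output image side (bottleneck target side is `size / 16`).
#' @param pattern T1 selection pattern, see [select_t1()].
#' @param cache_dir Optional directory; when given the dataset is persisted
#'   with [write_cache()].
#' @return List of slice pairs (image, class_map, one-hot targets,
#'   provenance).
#' @export
build_dataset <- function(records, label_map = NULL, n_classes = 2L,
                          size = 128L, pattern = "t1", cache_dir = NULL) {
  if (!length(records)) stop("build_dataset: no records supplied")
  kept <- select_t1(records, pattern)
  pairs <- lapply(seq_along(kept), function(i) {
    rec <- kept[[i]]
    sl <- central_slice(rec)
    img8 <- rescale_to_8bit(sl$image)
    rp <- resize_pair(img8, sl$labels, size)
    enc <- encode_masks(rp$labels, label_map, n_classes, size %/% 16L)
    make_slice_pair(rp$image, enc$class_map, n_classes,
                    provenance = list(series_tag = rec$series_tag,
                                      record = i, slice_index = sl$slice_index))
  })
  if (!is.null(cache_dir)) write_cache(pairs, cache_dir)
  pairs
}
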