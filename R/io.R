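#' Read a labelled MRI volume from disk
#'
#' Reads an image volume and its label mask and returns a [volume_record()]
#' with slices along the first axis.  NIfTI (`.nii`, `.nii.gz`) files are read
#' through RNifti; MetaImage (`.mha`, `.mhd`) files through a built-in reader
#' for uncompressed MET_* raw data.
#'
#' @param image_path Path to the image volume.
#' @param label_path Path to the label volume (same grid).  Optional; missing
#'   labels become all-zero.
#' @param series_tag Series name; defaults to the image file name.
#' @param slice_axis Axis of the stored array that enumerates slices (default
#'   3, the usual slice-last storage); it is moved to the first axis.
#' @return A [volume_record()].
#' @export
read_volume <- function(image_path, label_path = NULL, series_tag = NULL,
                        slice_axis = 3L) {
  vox <- read_volume_array(image_path)
  lab <- if (is.null(label_path)) array(0L, dim(vox)) else read_volume_array(label_path)
  perm <- c(slice_axis, setdiff(1:3, slice_axis))
  vox <- aperm(vox, perm); lab <- aperm(lab, perm)
  if (is.null(series_tag))
    series_tag <- sub("\\.(nii(\\.gz)?|mha|mhd)$", "",
                      basename(image_path), ignore.case = TRUE)
  volume_record(vox, round(lab), series_tag)
}

read_volume_array <- function(path) {
  lower <- tolower(path)
  arr <- if (grepl("\\.nii(\\.gz)?$", lower)) {
    as.array(RNifti::readNifti(path))
  } else if (grepl("\\.(mha|mhd)$", lower)) {
    read_metaimage(path)
  } else stop("unsupported volume format: ", path)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  if (length(dim(arr)) != 3L) stop("expected a 3D volume in ", path)
  arr
}

# Minimal MetaImage reader: ASCII "Key = Value" header followed by (or pointing
# to) uncompressed raw voxel data, x fastest.  The header is parsed from raw
# bytes so the data offset is exact.
read_metaimage <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  nl <- which(bytes == as.raw(10L))
  hdr <- list()
  data_at <- NA_integer_
  start <- 1L
  for (e in nl) {
    line <- rawToChar(bytes[start:max(start, e - 1L)])
    line <- sub("\r$", "", line)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) {
      hdr[[kv[2]]] <- trimws(kv[3])
      if (kv[2] == "ElementDataFile") { data_at <- e + 1L; break }
    }
    start <- e + 1L
  }
  if (is.na(data_at)) stop("MetaImage header ended before ElementDataFile")
  if (identical(toupper(hdr$CompressedData %||% "FALSE"), "TRUE"))
    stop("compressed MetaImage data is not supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  type <- hdr$ElementType %||% "MET_FLOAT"
  spec <- switch(type,
                 MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
                 MET_CHAR = list(what = "integer", size = 1, signed = TRUE),
                 MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
                 MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
                 MET_UINT = list(what = "integer", size = 4, signed = TRUE),
                 MET_INT = list(what = "integer", size = 4, signed = TRUE),
                 MET_FLOAT = list(what = "numeric", size = 4, signed = TRUE),
                 MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE),
                 stop("unsupported MetaImage ElementType: ", type))
  n <- prod(dims)
  data_ref <- hdr$ElementDataFile
  payload <- if (identical(toupper(data_ref), "LOCAL")) {
    bytes[data_at:length(bytes)]
  } else {
    dpath <- file.path(dirname(path), data_ref)
    readBin(dpath, "raw", n = file.size(dpath))
  }
  raw <- readBin(payload, spec$what, n = n, size = spec$size,
                 signed = spec$signed, endian = "little")
  if (length(raw) != n) stop("MetaImage raw data shorter than DimSize implies")
  array(raw, dim = dims)
}

## ---- binary array cache ----------------------------------------------------

#' Persist / load a slice-pair dataset
#'
#' The cache is a directory holding one little-endian binary array per sample
#' (image as doubles, class map as 32-bit integers) plus a JSON index with
#' shapes, class count and provenance.  Rebuilding from unchanged inputs is
#' byte-identical.
#'
#' @param pairs List of slice pairs as produced by [build_dataset()] or
#'   [generate_phantom_dataset()].
#' @param dir Cache directory (created if needed).
#' @return `write_cache()` the directory, invisibly; `read_cache()` the list
#'   of slice pairs with one-hot targets reconstructed.
#' @export
write_cache <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    img_file <- sprintf("img_%04d.bin", i)
    lab_file <- sprintf("lab_%04d.bin", i)
    con <- file(file.path(dir, img_file), "wb")
    writeBin(as.vector(p$image), con, size = 8, endian = "little")
    close(con)
    con <- file(file.path(dir, lab_file), "wb")
    writeBin(as.integer(p$class_map), con, size = 4, endian = "little")
    close(con)
    list(id = i, image = img_file, labels = lab_file,
         size = nrow(p$image), provenance = p$provenance)
  })
  idx <- list(n = length(pairs),
              n_classes = pairs[[1]]$n_classes,
              size = nrow(pairs[[1]]$image),
              entries = entries)
  jsonlite::write_json(idx, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cache
#' @export
read_cache <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"), simplifyVector = FALSE)
  lapply(idx$entries, function(e) {
    s <- e$size
    con <- file(file.path(dir, e$image), "rb")
    img <- matrix(readBin(con, "numeric", n = s * s, size = 8,
                          endian = "little"), s, s)
    close(con)
    con <- file(file.path(dir, e$labels), "rb")
    cm <- matrix(readBin(con, "integer", n = s * s, size = 4,
                         endian = "little"), s, s)
    close(con)
    make_slice_pair(img, cm, idx$n_classes, provenance = e$provenance)
  })
}
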