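#' Per-class confusion counts
#'
#' Cross-tabulates predicted against true label maps and derives one-vs-rest
#' TP/FP/FN/TN counts per class.  Counts are additive: `+` pools them across
#' images, which is how test-set metrics are aggregated.
#'
#' @param pred_labels,true_labels Integer label arrays of identical shape with
#'   values in `0:(n_classes - 1)`.
#' @param n_classes Number of classes.
#' @return An object of class `confusion_counts`: a list with integer vectors
#'   `tp`, `fp`, `fn`, `tn` (one entry per class) and `n_classes`.
#' @export
confusion_counts <- function(pred_labels, true_labels, n_classes) {
  if (!identical(dim(pred_labels), dim(true_labels)) ||
      length(pred_labels) != length(true_labels))
    stop("pred_labels and true_labels must have identical shapes")
  p <- as.vector(pred_labels); t <- as.vector(true_labels)
  if (any(p < 0 | p >= n_classes) || any(t < 0 | t >= n_classes))
    stop("labels out of range [0, n_classes)")
  lev <- 0:(n_classes - 1)
  tab <- table(factor(p, levels = lev), factor(t, levels = lev))
  tp <- diag(tab)
  fp <- rowSums(tab) - tp
  fn <- colSums(tab) - tp
  total <- length(p)
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 tn = as.integer(total - tp - fp - fn),
                 n_classes = as.integer(n_classes)),
            class = "confusion_counts")
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  stopifnot(inherits(e1, "confusion_counts"), inherits(e2, "confusion_counts"),
            e1$n_classes == e2$n_classes)
  structure(list(tp = e1$tp + e2$tp, fp = e1$fp + e2$fp, fn = e1$fn + e2$fn,
                 tn = e1$tn + e2$tn, n_classes = e1$n_classes),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts>", x$n_classes, "classes\n")
  print(data.frame(class = 0:(x$n_classes - 1), TP = x$tp, FP = x$fp,
                   FN = x$fn, TN = x$tn), row.names = FALSE)
  invisible(x)
}

#' Scalar segmentation metrics
#'
#' Derives mIoU, accuracy, precision, recall and F1 from pooled confusion
#' counts.  Per-class IoU is `TP / (TP + FP + FN)`; a class absent from both
#' prediction and truth (zero denominator) scores 1.  For two classes,
#' precision/recall/F1 are reported for the foreground class (class 1); with
#' more classes they are macro averages, with the same zero-denominator
#' convention: 1 when the class is entirely absent, 0 when present but the
#' denominator is empty.
#'
#' @param counts A [confusion_counts()] object.
#' @return Named list `miou`, `accuracy`, `precision`, `recall`, `f1`, all in
#'   `[0, 1]`.
#' @export
scalar_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp[1] + counts$fp[1] + counts$fn[1] + counts$tn[1]
  if (total == 0) stop("no pixels evaluated")
  safe <- function(num, den, absent) ifelse(den == 0, ifelse(absent, 1, 0), num / den)
  absent <- (counts$tp + counts$fp + counts$fn) == 0
  iou <- safe(counts$tp, counts$tp + counts$fp + counts$fn, absent)
  prec_c <- safe(counts$tp, counts$tp + counts$fp, absent)
  rec_c <- safe(counts$tp, counts$tp + counts$fn, absent)
  f1_c <- ifelse(prec_c + rec_c == 0, 0, 2 * prec_c * rec_c / (prec_c + rec_c))
  accuracy <- sum(counts$tp) / total
  if (counts$n_classes == 2L) {
    list(miou = mean(iou), accuracy = accuracy, precision = prec_c[2],
         recall = rec_c[2], f1 = f1_c[2])
  } else {
    list(miou = mean(iou), accuracy = accuracy, precision = mean(prec_c),
         recall = mean(rec_c), f1 = mean(f1_c))
  }
}

#' Extract the 4-neighbour boundary of a binary mask
#'
#' A boundary pixel is a foreground pixel with at least one 4-neighbour that is
#' background or lies off the image.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Integer matrix with one `(row, col)` pair per boundary pixel
#'   (zero rows for an all-background mask).
#' @export
extract_boundary <- function(mask) {
  m <- (mask > 0)
  if (!is.matrix(m)) stop("mask must be a matrix")
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(shift_r, shift_c) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + shift_r; cs <- seq_len(nc) + shift_c
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  interior <- m & pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  which(m & !interior, arr.ind = TRUE)
}

boundary_checked <- function(a, what) {
  a <- as.matrix(a)
  if (nrow(a) == 0) stop(what, ": boundary point set is empty")
  if (ncol(a) != 2) stop(what, ": expected an n x 2 coordinate matrix")
  a
}

pairwise_min_dists <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  list(da = sqrt(apply(d2, 1, min)), db = sqrt(apply(d2, 2, min)))
}

#' Boundary distances
#'
#' `hausdorff()` is the symmetric Hausdorff distance between two boundary
#' point sets (maximum of the two directed nearest-neighbour maxima, Euclidean
#' pixel units); `assd()` is the average symmetric surface distance (sum of all
#' nearest-neighbour distances in both directions divided by the total number
#' of boundary points).  `assd(a, b) <= hausdorff(a, b)` always.
#'
#' @param a,b Integer coordinate matrices as returned by [extract_boundary()];
#'   both must be nonempty.
#' @return Distance in pixels.
#' @export
hausdorff <- function(a, b) {
  a <- boundary_checked(a, "hausdorff"); b <- boundary_checked(b, "hausdorff")
  d <- pairwise_min_dists(a, b)
  max(max(d$da), max(d$db))
}

#' @rdname hausdorff
#' @export
assd <- function(a, b) {
  a <- boundary_checked(a, "assd"); b <- boundary_checked(b, "assd")
  d <- pairwise_min_dists(a, b)
  (sum(d$da) + sum(d$db)) / (nrow(a) + nrow(b))
}

#' Render a metrics report
#'
#' @param metrics Named list as returned by [scalar_metrics()].
#' @param path Optional path; when given the report is also written as JSON.
#' @return The aligned text table, invisibly.
#' @export
format_metrics_report <- function(metrics, path = NULL) {
  cols <- c(miou = "mIoU", accuracy = "Accuracy", precision = "Precision",
            recall = "Recall", f1 = "F1-score")
  keep <- intersect(names(cols), names(metrics))
  vals <- vapply(metrics[keep], function(v) sprintf("%.4f", v), character(1))
  widths <- pmax(nchar(cols[keep]), nchar(vals))
  line1 <- paste(mapply(formatC, cols[keep], width = widths), collapse = "  ")
  line2 <- paste(mapply(formatC, vals, width = widths), collapse = "  ")
  txt <- paste(line1, line2, sep = "\n")
  extra <- setdiff(names(metrics), keep)
  if (length(extra))
    txt <- paste(txt, paste(sprintf("%s: %.4f", extra,
                                    unlist(metrics[extra])), collapse = "\n"),
                 sep = "\n")
  if (!is.null(path))
    jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
  invisible(txt)
}
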