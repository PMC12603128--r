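test_that("confusion counts: hand cases and loop oracle", {
  # identical maps: no errors anywhere
  m <- matrix(c(0, 1, 2, 1), 2, 2)
  cc <- confusion_counts(m, m, 3)
  expect_true(all(cc$fp == 0) && all(cc$fn == 0))
  # 2x2 binary: prediction all-1 against half-foreground truth
  truth <- matrix(c(1, 0, 1, 0), 2, 2)
  pred <- matrix(1, 2, 2)
  cc <- confusion_counts(pred, truth, 2)
  expect_equal(cc$tp[2], 2); expect_equal(cc$fp[2], 2)
  expect_equal(cc$fn[2], 0); expect_equal(cc$tn[2], 0)
  # random 16x16 4-class maps vs brute-force per-pixel loop
  withr::with_seed(21, {
    p4 <- matrix(sample(0:3, 256, TRUE), 16, 16)
    t4 <- matrix(sample(0:3, 256, TRUE), 16, 16)
  })
  cc <- confusion_counts(p4, t4, 4)
  o <- oracle_confusion(as.vector(p4), as.vector(t4), 4)
  expect_equal(cc$tp, o$tp); expect_equal(cc$fp, o$fp)
  expect_equal(cc$fn, o$fn); expect_equal(cc$tn, o$tn)
  expect_error(confusion_counts(matrix(5, 2, 2), matrix(0, 2, 2), 4), "range")
})

test_that("scalar metrics: perfect, hand-worked and set-arithmetic cases", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  perfect <- scalar_metrics(confusion_counts(m, m, 2))
  expect_true(all(unlist(perfect) == 1))
  # the all-1 prediction case above, worked by hand
  truth <- matrix(c(1, 0, 1, 0), 2, 2)
  sm <- scalar_metrics(confusion_counts(matrix(1, 2, 2), truth, 2))
  expect_equal(sm$miou, 0.25)      # IoU fg 0.5, IoU bg 0
  expect_equal(sm$accuracy, 0.5)
  expect_equal(sm$precision, 0.5)
  expect_equal(sm$recall, 1)
  expect_equal(sm$f1, 2 / 3)
  # random maps vs intersection/union on pixel index sets
  withr::with_seed(22, {
    for (nc in c(2L, 4L)) {
      p <- matrix(sample(0:(nc - 1), 100, TRUE), 10, 10)
      t <- matrix(sample(0:(nc - 1), 100, TRUE), 10, 10)
      got <- scalar_metrics(confusion_counts(p, t, nc))
      want <- oracle_metrics(p, t, nc)
      for (k in names(want)) expect_equal(got[[k]], want[[k]], tolerance = 1e-12)
    }
  })
  # F1 identity whenever P + R > 0
  withr::with_seed(23, {
    p <- matrix(sample(0:1, 64, TRUE), 8, 8)
    t <- matrix(sample(0:1, 64, TRUE), 8, 8)
  })
  sm <- scalar_metrics(confusion_counts(p, t, 2))
  expect_equal(sm$f1, 2 * sm$precision * sm$recall / (sm$precision + sm$recall))
  # all metrics bounded in [0, 1]
  expect_true(all(unlist(sm) >= 0 & unlist(sm) <= 1))
})

test_that("confusion accumulation over tiles equals the concatenated image", {
  withr::with_seed(24, {
    p <- matrix(sample(0:2, 144, TRUE), 12, 12)
    t <- matrix(sample(0:2, 144, TRUE), 12, 12)
  })
  whole <- confusion_counts(p, t, 3)
  tiles <- confusion_counts(p[1:6, ], t[1:6, ], 3) +
    confusion_counts(p[7:12, ], t[7:12, ], 3)
  expect_equal(whole$tp, tiles$tp); expect_equal(whole$fp, tiles$fp)
  expect_equal(whole$fn, tiles$fn); expect_equal(whole$tn, tiles$tn)
})

test_that("boundary extraction: 4-neighbour rule and erosion oracle", {
  # 3x3 all-foreground: the 8 edge pixels, centre excluded
  b <- extract_boundary(matrix(1, 3, 3))
  expect_equal(nrow(b), 8)
  expect_false(any(b[, 1] == 2 & b[, 2] == 2))
  # single pixel is its own boundary
  m1 <- matrix(0, 5, 5); m1[3, 3] <- 1
  expect_equal(unname(extract_boundary(m1)), matrix(c(3, 3), 1))
  # random blob vs erosion-difference oracle
  withr::with_seed(25, {
    blob <- matrix(rbinom(100, 1, 0.5), 10, 10)
  })
  got <- extract_boundary(blob)
  want <- oracle_boundary(blob)
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
               unname(want[order(want[, 1], want[, 2]), , drop = FALSE]),
               ignore_attr = TRUE)
  # independent morphological route through EBImage, when present
  if (requireNamespace("EBImage", quietly = TRUE)) {
    kern <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
    eroded <- EBImage::erode(blob, kern)
    edge <- which(blob == 1 & eroded == 0, arr.ind = TRUE)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 unname(edge[order(edge[, 1], edge[, 2]), , drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("Hausdorff and ASSD: toys, symmetry, brute force, ordering", {
  a <- matrix(c(0, 0), 1)
  b <- matrix(c(3, 4), 1)
  expect_equal(hausdorff(a, b), 5)
  expect_equal(assd(a, b), 5)
  expect_equal(hausdorff(a, a), 0)
  expect_equal(assd(b, b), 0)
  expect_error(hausdorff(matrix(numeric(0), 0, 2), b), "empty")
  withr::with_seed(26, {
    for (rep in 1:20) {
      A <- matrix(sample(0:30, 2 * sample(2:12, 1), TRUE), ncol = 2)
      B <- matrix(sample(0:30, 2 * sample(2:12, 1), TRUE), ncol = 2)
      o <- oracle_hd_assd(A, B)
      expect_equal(hausdorff(A, B), o$hd, tolerance = 1e-10)
      expect_equal(assd(A, B), o$assd, tolerance = 1e-10)
      expect_equal(hausdorff(A, B), hausdorff(B, A))
      expect_equal(assd(A, B), assd(B, A))
      expect_lte(assd(A, B), hausdorff(A, B) + 1e-12)
    }
  })
})

test_that("metrics report renders the standard column order and writes JSON", {
  m <- list(miou = 0.8974, accuracy = 0.9742, precision = 0.9417,
            recall = 0.9470, f1 = 0.9444)
  path <- tempfile(fileext = ".json")
  txt <- format_metrics_report(m, path)
  expect_match(txt, "mIoU\\s+Accuracy\\s+Precision\\s+Recall\\s+F1-score")
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$miou, 0.8974)
})
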