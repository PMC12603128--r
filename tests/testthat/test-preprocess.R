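mk_record <- function(depth = 5, n = 16, tag = "t1", seed = 1) {
  withr::with_seed(seed, {
    volume_record(array(runif(depth * n * n), c(depth, n, n)),
                  array(sample(0:3, depth * n * n, TRUE), c(depth, n, n)),
                  series_tag = tag)
  })
}

test_that("T1 selection by configurable pattern", {
  recs <- list(mk_record(tag = "t1"), mk_record(tag = "t2"),
               mk_record(tag = "T1_space"))
  kept <- select_t1(recs)
  expect_equal(vapply(kept, function(r) r$series_tag, ""), c("t1", "T1_space"))
  expect_warning(select_t1(list(mk_record(tag = "t2"))), "no series")
  exact <- select_t1(recs, pattern = "^t1$")
  expect_equal(length(exact), 1L)
  expect_equal(exact[[1]]$series_tag, "t1")
})

test_that("central slice uses floor(depth/2), zero-based", {
  expect_equal(central_slice(mk_record(depth = 9))$slice_index, 4)
  expect_equal(central_slice(mk_record(depth = 8))$slice_index, 4)
  expect_equal(central_slice(mk_record(depth = 1))$slice_index, 0)
  r <- mk_record(depth = 9)
  sl <- central_slice(r)
  expect_equal(sl$image, r$voxels[5, , ])
  expect_equal(sl$labels, r$labels[5, , ])
})

test_that("8-bit rescale: anchors, rounding, degenerate input", {
  expect_equal(as.vector(rescale_to_8bit(matrix(c(0, 0.5, 1, 1), 2, 2)))[1:3],
               c(0L, 128L, 255L))
  expect_true(all(rescale_to_8bit(matrix(3.7, 4, 4)) == 0L))
  withr::with_seed(31, {
    x <- matrix(rnorm(64), 8, 8)
  })
  r <- rescale_to_8bit(x)
  expect_equal(range(r), c(0L, 255L))
  expect_error(rescale_to_8bit(matrix(c(1, NaN, 2, 3), 2, 2)), "finite")
})

test_that("pair resize: label closure, uniform images, nearest oracle", {
  withr::with_seed(32, {
    img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
    lab <- matrix(sample(c(0L, 1L, 3L), 64 * 64, TRUE), 64, 64)
  })
  rp <- resize_pair(img, lab, 32)
  expect_true(all(unique(as.vector(rp$labels)) %in% c(0L, 1L, 3L)))
  expect_true(all(rp$image >= 0 & rp$image <= 1))
  # uniform image stays uniform
  ru <- resize_pair(matrix(100L, 20, 20), matrix(0L, 20, 20), 32)
  expect_true(all(abs(ru$image - 100 / 255) < 1e-12))
  # checkerboard labels: nearest-neighbour index-mapping oracle
  cb <- matrix(as.integer((outer(1:256, 1:256, "+") %% 2) == 0), 256, 256)
  got <- resize_pair(matrix(0L, 256, 256), cb, 128)$labels
  expect_equal(got, oracle_resize_nearest(cb, 128))
})

test_that("mask encoding: binary rule, bottleneck target, oracles, errors", {
  # any nonzero raw code is foreground
  lab <- matrix(0L, 16, 16); lab[3, 4] <- 7L
  enc <- encode_masks(lab, n_classes = 2L, bottleneck_size = 1L)
  expect_equal(enc$mask_onehot[3, 4, ], c(0, 1))
  expect_equal(enc$mask_onehot[1, 1, ], c(1, 0))
  # all-background: uniform background bottleneck
  enc0 <- encode_masks(matrix(0L, 128, 128))
  expect_equal(dim(enc0$bottleneck_onehot), c(8, 8, 2))
  expect_true(all(enc0$bottleneck_onehot[, , 1] == 1))
  # one-hot channel sums are exactly 1 everywhere
  withr::with_seed(33, {
    lab <- matrix(sample(0:5, 128 * 128, TRUE, prob = c(0.7, rep(0.06, 5))), 128, 128)
  })
  enc <- encode_masks(lab)
  expect_true(all(apply(enc$mask_onehot, c(1, 2), sum) == 1))
  expect_true(all(apply(enc$bottleneck_onehot, c(1, 2), sum) == 1))
  # half-foreground map: 8x8 target equals the per-cell sampling oracle
  half <- matrix(0L, 128, 128); half[, 1:64] <- 1L
  enc <- encode_masks(half)
  expect_equal(apply(enc$bottleneck_onehot, c(1, 2), which.max) - 1L,
               oracle_resize_nearest(half, 8))
  # binary foreground = nonzero raw labels after resizing
  expect_equal(enc$class_map, half)
  # multiclass label map: every raw code must be covered
  lab4 <- matrix(c(0L, 10L, 20L, 30L), 2, 2)
  map <- c(`0` = 0L, `10` = 1L, `20` = 2L, `30` = 3L)
  enc4 <- encode_masks(lab4, map, n_classes = 4L, bottleneck_size = 1L)
  expect_equal(enc4$class_map, matrix(0:3, 2, 2))
  expect_error(encode_masks(lab4, map[1:3], n_classes = 4L, bottleneck_size = 1L),
               "unmapped.*30")
})

test_that("build_dataset composes the pipeline deterministically", {
  recs <- list(mk_record(tag = "t1", seed = 1), mk_record(tag = "t2", seed = 2),
               mk_record(tag = "t1_tse", seed = 3), mk_record(tag = "t1", seed = 4))
  pairs <- build_dataset(recs, n_classes = 2L, size = 16L)
  expect_length(pairs, 3)  # the t2 record is dropped
  expect_equal(dim(pairs[[1]]$image), c(16, 16))
  expect_equal(dim(pairs[[1]]$bottleneck_onehot), c(1, 1, 2))
  pairs2 <- build_dataset(recs, n_classes = 2L, size = 16L)
  expect_identical(pairs, pairs2)
  expect_error(build_dataset(list()), "no records")
})

test_that("cache round-trip is byte-identical", {
  pairs <- build_dataset(list(mk_record(seed = 7), mk_record(seed = 8)),
                         n_classes = 2L, size = 16L)
  dir <- tempfile("cache")
  write_cache(pairs, dir)
  back <- read_cache(dir)
  expect_length(back, 2)
  expect_identical(back[[1]]$image, pairs[[1]]$image)
  expect_identical(back[[1]]$class_map, pairs[[1]]$class_map)
  expect_identical(back[[2]]$mask_onehot, pairs[[2]]$mask_onehot)
  # rebuilding the cache reproduces identical bytes
  dir2 <- tempfile("cache")
  write_cache(pairs, dir2)
  f1 <- file.path(dir, "img_0001.bin"); f2 <- file.path(dir2, "img_0001.bin")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
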