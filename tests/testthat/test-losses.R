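cfg0 <- loss_config()

test_that("closed-form hand values", {
  # single entry, y = 1, p = 0.5
  expect_equal(bce_loss(1, 0.5, cfg0), log(2), tolerance = 1e-12)
  # crisp correct prediction collapses to the clipping limit
  expect_lt(bce_loss(c(1, 0), c(1, 0), cfg0), 1e-6)
  # single channel Dice toy: y = (1,0), p = (1,1), no smoothing
  sm0 <- loss_config(smooth = 0)
  expect_equal(dice_loss(array(c(1, 0), c(2, 1, 1)),
                         array(c(1, 1), c(2, 1, 1)), sm0),
               1 / 3, tolerance = 1e-12)
  # focal toy: y = 1, p = 0.5, alpha 0.5, gamma 2
  expect_equal(focal_loss(1, 0.5, cfg0), 0.5 * 0.25 * log(2), tolerance = 1e-12)
  # 4-class pixel with probability 1/4 on the correct class
  y <- array(c(1, 0, 0, 0), c(1, 1, 4))
  p <- array(rep(0.25, 4), c(1, 1, 4))
  expect_equal(cce_loss(y, p, cfg0), log(4), tolerance = 1e-12)
})

test_that("reduction identities between losses", {
  withr::with_seed(10, {
    y <- array(rbinom(8 * 8 * 2, 1, 0.4), c(8, 8, 2))
    p <- array(runif(8 * 8 * 2), c(8, 8, 2))
  })
  # focal with gamma = 0, alpha = 1 is exactly BCE
  cfg_id <- loss_config(alpha = 1, gamma = 0)
  expect_equal(focal_loss(y, p, cfg_id), bce_loss(y, p, cfg_id),
               tolerance = 1e-12)
  # compound loss at unit weights is the exact sum
  expect_equal(bce_dice_loss(y, p, cfg0),
               bce_loss(y, p, cfg0) + dice_loss(y, p, cfg0), tolerance = 1e-12)
  # linearity in the lambda weights
  cA <- loss_config(lambda1 = 0, lambda2 = 3)
  expect_equal(bce_dice_loss(y, p, cA), 3 * dice_loss(y, p, cA),
               tolerance = 1e-12)
  cB <- loss_config(lambda1 = 2, lambda2 = 0)
  expect_equal(bce_dice_loss(y, p, cB), 2 * bce_loss(y, p, cB),
               tolerance = 1e-12)
})

test_that("random tensors match independent scalar-loop oracles", {
  withr::with_seed(11, {
    y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 2))
    p <- array(runif(8 * 8 * 2), c(8, 8, 2))
    expect_equal(bce_loss(y, p, cfg0), oracle_bce(y, p), tolerance = 1e-6)
    expect_equal(focal_loss(y, p, cfg0), oracle_focal(y, p), tolerance = 1e-6)
    expect_equal(dice_loss(y, p, cfg0), oracle_dice(y, p), tolerance = 1e-6)
    # 4-class one-hot pair
    cm <- matrix(sample(0:3, 36, TRUE), 6, 6)
    y4 <- spineseg:::one_hot(cm, 4)
    logits <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
    p4 <- exp(logits)
    p4 <- p4 / array(rep(apply(p4, c(1, 2), sum), 4), dim(p4))
    expect_equal(cce_loss(y4, p4, cfg0), oracle_cce(y4, p4), tolerance = 1e-6)
    expect_equal(cce_dice_loss(y4, p4, cfg0),
                 oracle_cce(y4, p4) + oracle_dice(y4, p4), tolerance = 1e-6)
  })
})

test_that("loss invariants: range, permutation symmetry, focal bound", {
  withr::with_seed(12, {
    for (rep in 1:5) {
      y <- array(rbinom(32, 1, 0.5), c(4, 4, 2))
      p <- array(runif(32), c(4, 4, 2))
      for (fn in list(bce_loss, dice_loss, focal_loss, bce_dice_loss)) {
        v <- fn(y, p, cfg0)
        expect_true(is.finite(v) && v >= 0)
      }
      expect_lte(dice_loss(y, p, cfg0), 1)
      # with alpha = 1, (1-p)^gamma <= 1 makes focal <= BCE for any gamma
      c1 <- loss_config(alpha = 1, gamma = 2)
      expect_lte(focal_loss(y, p, c1), bce_loss(y, p, c1) + 1e-12)
      # permutation invariance over pixels (same permutation on y and p)
      perm <- sample(16)
      yp <- array(0, dim(y)); pp <- array(0, dim(p))
      for (ch in 1:2) {
        yp[, , ch] <- matrix(as.vector(y[, , ch])[perm], 4, 4)
        pp[, , ch] <- matrix(as.vector(p[, , ch])[perm], 4, 4)
      }
      expect_equal(bce_loss(yp, pp, cfg0), bce_loss(y, p, cfg0), tolerance = 1e-12)
      expect_equal(dice_loss(yp, pp, cfg0), dice_loss(y, p, cfg0), tolerance = 1e-12)
    }
  })
})

test_that("Dice degenerate cases: perfect overlap and empty channels", {
  y <- spineseg:::one_hot(matrix(c(0, 1, 1, 0), 2, 2), 2)
  expect_equal(dice_loss(y, y, cfg0), 0, tolerance = 1e-12)
  # both-empty channel contributes 0 with smoothing
  y2 <- array(0, c(2, 2, 2)); y2[, , 1] <- 1  # channel 2 empty in truth & pred
  expect_equal(dice_loss(y2, y2, cfg0), 0, tolerance = 1e-12)
})

test_that("input validation: shape mismatch and non-one-hot CCE targets", {
  expect_error(bce_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  y_bad <- array(1, c(2, 2, 2))  # channel sums are 2
  expect_error(cce_loss(y_bad, array(0.5, c(2, 2, 2)), cfg0), "one-hot")
})

test_that("analytic loss gradients match finite differences", {
  withr::with_seed(13, {
    y <- array(rbinom(2 * 2 * 2, 1, 0.5), c(2, 2, 2))
    p <- array(runif(2 * 2 * 2, 0.05, 0.95), c(2, 2, 2))
    cm <- matrix(sample(0:3, 4, TRUE), 2, 2)
    y4 <- spineseg:::one_hot(cm, 4)
    p4 <- array(runif(2 * 2 * 4, 0.05, 0.95), c(2, 2, 4))
    cases <- list(
      list(fn = bce_loss, gr = spineseg:::bce_loss_grad, y = y, p = p),
      list(fn = dice_loss, gr = spineseg:::dice_loss_grad, y = y, p = p),
      list(fn = focal_loss, gr = spineseg:::focal_loss_grad, y = y, p = p),
      list(fn = bce_dice_loss, gr = spineseg:::bce_dice_loss_grad, y = y, p = p),
      list(fn = cce_loss, gr = spineseg:::cce_loss_grad, y = y4, p = p4),
      list(fn = cce_dice_loss, gr = spineseg:::cce_dice_loss_grad, y = y4, p = p4))
    for (cs in cases) {
      g <- cs$gr(cs$y, cs$p, cfg0)
      for (i in sample(length(cs$p), 4)) {
        eps <- 1e-6
        pp <- cs$p; pp[i] <- pp[i] + eps
        pm <- cs$p; pm[i] <- pm[i] - eps
        num <- (cs$fn(cs$y, pp, cfg0) - cs$fn(cs$y, pm, cfg0)) / (2 * eps)
        expect_equal(g[i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("losses are selectable by configured name", {
  l <- get_loss("bce_dice")
  y <- array(c(1, 0), c(2, 1, 1)); p <- array(c(0.8, 0.3), c(2, 1, 1))
  expect_equal(l$fn(y, p, cfg0), bce_dice_loss(y, p, cfg0))
  expect_error(get_loss("tversky"))
})
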