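test_that("BerHu matches its closed form on both branches and at the knot", {
  expect_equal(berhu_loss(0.1, 0, c = 0.2), 0.1, tolerance = 1e-10)
  expect_equal(berhu_loss(0.4, 0, c = 0.2), 0.5, tolerance = 1e-10)  # (0.16+0.04)/0.4
  expect_equal(berhu_loss(0.2, 0, c = 0.2), 0.2, tolerance = 1e-10)  # continuity
  expect_equal(berhu_loss(c(0.1, 0.4), c(0, 0), c = 0.2, reduction = "sum"),
               0.6, tolerance = 1e-10)
  expect_error(berhu_loss(c(1, NA), c(0, 0)), "non-finite")
})

test_that("BerHu is continuous, monotone in |r|, and C1 at the threshold", {
  c0 <- 0.2
  r <- seq(0, 1, by = 1e-3)
  l <- vapply(r, function(ri) berhu_loss(ri, 0, c = c0), numeric(1))
  expect_true(all(diff(l) >= 0))
  expect_true(all(abs(l[r <= c0] - r[r <= c0]) < 1e-12))
  # slope from both sides of the knot is 1
  eps <- 1e-6
  sl_lo <- (berhu_loss(c0, 0) - berhu_loss(c0 - eps, 0)) / eps
  sl_hi <- (berhu_loss(c0 + eps, 0) - berhu_loss(c0, 0)) / eps
  expect_equal(sl_lo, 1, tolerance = 1e-4)
  expect_equal(sl_hi, 1, tolerance = 1e-4)
})

test_that("metrics reproduce hand-evaluated toy values", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-10)
  expect_equal(r_squared(c(1, 2, 3), c(2, 2, 2)), 0, tolerance = 1e-10)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5, tolerance = 1e-10)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2, 3), c(2, 2, 2)), 2 / 3, tolerance = 1e-10)
  expect_equal(mae(c(2, 2, 2), c(1, 2, 3)), mae(c(1, 2, 3), c(2, 2, 2)))
  expect_equal(tanimoto(c(1, 2), c(1, 2)), 1, tolerance = 1e-10)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0, tolerance = 1e-10)
  expect_equal(tanimoto(c(1, 2), c(2, 1)), 2 / 3, tolerance = 1e-10)
  expect_error(tanimoto(c(0, 0), c(0, 0)), "all zero")
})

test_that("global SSIM is 1 at identity, penalizes shifts, handles constants", {
  set.seed(6)
  y <- runif(500, -0.9, 0.9)
  expect_equal(ssim_global(y, y), 1, tolerance = 1e-10)
  # independent evaluation of the SSIM formula at a 0.2 shift
  yh <- y + 0.2
  L <- 1.8; C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu_y <- mean(y); mu_p <- mean(yh)
  vy <- mean((y - mu_y)^2); vp <- mean((yh - mu_p)^2)
  cv <- mean((y - mu_y) * (yh - mu_p))
  ref <- ((2 * mu_p * mu_y + C1) * (2 * cv + C2)) /
    ((mu_p^2 + mu_y^2 + C1) * (vp + vy + C2))
  expect_equal(ssim_global(y, yh), ref, tolerance = 1e-12)
  expect_lt(ssim_global(y, yh), 1)
  expect_equal(ssim_global(rep(0.4, 10), rep(0.4, 10)), 1)   # stabilizers
})

test_that("all metrics agree with naive one-line formulas on random vectors", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(10:1000, 1)
    y <- rnorm(n); yh <- y + rnorm(n, sd = 0.5)
    expect_equal(r_squared(y, yh), 1 - sum((y - yh)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
    expect_equal(mae(y, yh), sum(abs(y - yh)) / n, tolerance = 1e-10)
    expect_equal(tanimoto(y, yh),
                 sum(y * yh) / (sum(y^2) + sum(yh^2) - sum(y * yh)),
                 tolerance = 1e-10)
    expect_lte(r_squared(y, yh), 1)
    # joint permutation invariance
    p <- sample(n)
    expect_equal(r_squared(y[p], yh[p]), r_squared(y, yh), tolerance = 1e-12)
    expect_equal(tanimoto(y[p], yh[p]), tanimoto(y, yh), tolerance = 1e-12)
  }
})

test_that("windowed SSIM variant is 1 at identity and below 1 for noise", {
  set.seed(8)
  y <- array(runif(10 * 12 * 12, -0.5, 0.5), c(10, 12, 12))
  expect_equal(ssim_windowed(y, y), 1, tolerance = 1e-8)
  expect_lt(ssim_windowed(y, y + array(rnorm(length(y), sd = 0.3), dim(y))), 1)
})

test_that("evaluate_subject returns 5 phases x 4 metrics with exact ideals", {
  set.seed(9)
  D <- 3; H <- 10; W <- 10
  truth <- collateral_maps(array(runif(5 * D * H * W, -0.9, 0.9),
                                 c(5, D, H, W)), "target")
  mask <- brain_mask(array(rbinom(D * H * W, 1, 0.7), c(D, H, W)))
  rec <- evaluate_subject(truth, truth, mask)
  expect_equal(dim(rec), c(5L, 5L))
  expect_equal(rec$phase, c("Art", "Cap", "EVen", "LVen", "Del"))
  expect_true(all(rec$r_squared == 1))
  expect_true(all(rec$mae == 0))
  expect_true(all(abs(rec$tanimoto - 1) < 1e-12))
  expect_true(all(abs(rec$ssim - 1) < 1e-12))
  # voxel-shuffled prediction on a smooth map scores at or below zero
  smooth <- array(0, c(5, D, H, W))
  for (p in 1:5) for (z in 1:D)
    smooth[p, z, , ] <- outer(sin(seq_len(H) / 2), cos(seq_len(W) / 3)) * 0.8
  truth_s <- collateral_maps(smooth, "target")
  shuf <- smooth
  idx <- which(mask$mask != 0)
  for (p in 1:5) {
    v <- smooth[p, , , ][idx]
    tmp <- smooth[p, , , ]
    tmp[idx] <- sample(v)
    shuf[p, , , ] <- tmp
  }
  rec2 <- evaluate_subject(collateral_maps(shuf, "target"), truth_s, mask)
  expect_true(all(rec2$r_squared <= 0.1))
})
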