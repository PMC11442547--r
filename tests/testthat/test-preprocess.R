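test_that("brain mask recovers a bright sphere up to morphology margins", {
  D <- 24L; H <- 40L; W <- 40L; r <- 8
  ctr <- c(12, 20, 20)
  z <- slice.index(array(0, c(D, H, W)), 1)
  y <- slice.index(array(0, c(D, H, W)), 2)
  x <- slice.index(array(0, c(D, H, W)), 3)
  d2 <- (z - ctr[1])^2 + (y - ctr[2])^2 + (x - ctr[3])^2
  sphere <- (d2 <= r^2) * 1
  vol <- array(rep(as.vector(sphere * 100), each = 3), c(3, D, H, W))
  s <- perfusion_series(vol + 0)
  cfg <- preprocess_config(morph_radius = 6)
  m <- build_brain_mask(s, cfg)$mask
  # oracle: the mask must contain the sphere eroded by the morphology radius
  # and stay within the sphere dilated by it (with 1-voxel discrete margin)
  inner <- d2 <= (r - 6 - 1)^2
  outer <- d2 <= (r + 6 + 1)^2
  expect_true(all(m[inner] == 1))
  expect_true(all(m[!outer] == 0))
  # scale invariance of min-max normalization
  s10 <- perfusion_series(vol * 10)
  expect_identical(build_brain_mask(s10, cfg)$mask, m)
})

test_that("degenerate inputs produce informative masking errors", {
  s <- perfusion_series(array(0, c(3, 4, 10, 10)))
  expect_error(build_brain_mask(s), "dynamic range")
})

test_that("series normalization is exact, masked and idempotent", {
  set.seed(3)
  vol <- array(runif(4 * 4 * 8 * 8, 200, 1200), c(4, 4, 8, 8))
  vol[1, 1, 1, 1] <- 200; vol[2, 2, 2, 2] <- 1200; vol[3, 3, 3, 3] <- 700
  s <- perfusion_series(vol)
  mk <- brain_mask(array(1, c(4, 8, 8)))
  n <- normalize_series(s, mk)
  expect_equal(n$data[3, 3, 3, 3], 0.5)        # (700 - 200) / 1000
  expect_equal(min(n$data), 0)
  expect_equal(max(n$data), 1)
  n2 <- normalize_series(n, mk)
  expect_equal(n2$data, n$data)
  # masked-out voxels become zero
  mk2 <- brain_mask(array(c(1, rep(0, 4 * 8 * 8 - 1)), c(4, 8, 8)))
  expect_error(normalize_series(s, mk2), NA)
  # constant region errors
  sc <- perfusion_series(array(5, c(3, 2, 4, 4)) + 0)
  expect_error(normalize_series(sc, brain_mask(array(1, c(2, 4, 4)))),
               "zero dynamic range")
})

test_that("target normalization maps [0,1] affinely onto [-0.9, 0.9] with clipping", {
  vals <- c(0, 0.25, 0.5, 1, 1.2, -0.1)
  arr <- array(rep(vals, length.out = 5 * 2 * 4 * 4), c(5, 2, 4, 4))
  m <- collateral_maps(arr, value_range = "unit")
  nt <- normalize_targets(m)
  expect_identical(nt$value_range, "target")
  ref <- function(v) 1.8 * pmin(pmax(v, 0), 1) - 0.9
  expect_equal(as.vector(nt$maps), rep(ref(vals), length.out = length(arr)))
  expect_equal(ref(0.5), 0)
  expect_equal(ref(1.2), 0.9)
  expect_equal(ref(0), -0.9)
  expect_equal(ref(1), 0.9)
  # raw maps are min-max scaled first: bijection endpoints
  raw <- rand_maps(D = 2, H = 6, W = 6)
  nr <- normalize_targets(raw)
  expect_equal(min(nr$maps), -0.9)
  expect_equal(max(nr$maps), 0.9)
})

test_that("median filtering removes impulses and is window-bounded", {
  cfg <- preprocess_config(median_kernel = 5)
  cst <- collateral_maps(array(0.3, c(5, 1, 12, 12)) + 0, "raw")
  expect_equal(median_filter_targets(cst, cfg)$maps, cst$maps)
  imp <- array(0, c(5, 1, 12, 12))
  imp[1, 1, 6, 6] <- 1
  mf <- median_filter_targets(collateral_maps(imp, "raw"), cfg)
  expect_equal(mf$maps[1, 1, 6, 6], 0)       # 1 of 25 samples cannot win
  # membership: every output value occurs in its input window
  rmap <- rand_maps(D = 1, H = 10, W = 10, seed = 9)
  out <- median_filter_targets(rmap, cfg)$maps
  for (i in 3:8) for (j in 3:8) {
    win <- rmap$maps[2, 1, (i - 2):(i + 2), (j - 2):(j + 2)]
    expect_true(out[2, 1, i, j] %in% win)
  }
})

test_that("center crop keeps the central index range and is idempotent at size", {
  set.seed(4)
  vol <- array(runif(2 * 2 * 230 * 230), c(2, 2, 230, 230))
  s <- perfusion_series(vol)
  cr <- center_crop(s, preprocess_config(crop_size = 224))
  expect_equal(dim(cr$data), c(2, 2, 224, 224))
  # 0-based [3, 227) on each spatial axis = R indices 4..227
  expect_equal(cr$data, vol[, , 4:227, 4:227, drop = FALSE])
  expect_equal(center_crop(cr, preprocess_config(crop_size = 224))$data, cr$data)
  expect_error(center_crop(cr, preprocess_config(crop_size = 230)), "smaller")
})

test_that("the full preprocessing pipeline yields the canonical tensor", {
  ph <- make_phantom(phantom_spec(grid = c(40L, 20L, 230L, 230L)))
  pp <- preprocess_subject(ph$series, ph$maps, preprocess_config())
  expect_equal(dim(pp$series$data), c(40L, 20L, 224L, 224L))
  expect_equal(dim(pp$maps$maps), c(5L, 20L, 224L, 224L))
  expect_equal(dim(pp$mask$mask), c(20L, 224L, 224L))
  expect_gte(min(pp$maps$maps), -0.9)
  expect_lte(max(pp$maps$maps), 0.9)
  expect_true(all(pp$series$data >= 0 & pp$series$data <= 1))
})
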