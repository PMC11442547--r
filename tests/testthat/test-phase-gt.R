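test_that("baseline subtraction clips at zero and zeroes frame 0", {
  vol <- array(100, c(6, 2, 4, 4))
  vol[6, 1, 2, 2] <- 60
  vol[3, 1, 1, 1] <- 130            # above baseline: clipped for sign=drop
  s <- perfusion_series(vol + 0)
  sub <- subtract_baseline(s, "drop")
  expect_equal(sub$data[6, 1, 2, 2], 40)
  expect_true(all(sub$data[1, , , ] == 0))
  expect_equal(sub$data[3, 1, 1, 1], 0)
  # rising signal with sign=drop is clipped everywhere
  up <- perfusion_series(array(rep(seq(100, 150, length.out = 6),
                                   times = 2 * 4 * 4), c(6, 2, 4, 4)))
  expect_true(all(subtract_baseline(up, "drop")$data == 0))
  expect_equal(subtract_baseline(up, "rise")$data[6, 1, 1, 1], 50)
})

test_that("temporal MIP is the windowed voxelwise maximum and monotone", {
  set.seed(5)
  s <- rand_series(Tn = 10, D = 2, H = 5, W = 5)
  full <- temporal_mip(s)
  # oracle: explicit max over the constructed sequence per voxel
  expect_equal(full[2, 3, 4], max(s$data[, 2, 3, 4]))
  expect_equal(temporal_mip(s, c(4, 4)), array(s$data[5, , , ], c(2, 5, 5)))
  small <- temporal_mip(s, c(2, 5))
  expect_true(all(temporal_mip(s, c(2, 7)) >= small))
  expect_error(temporal_mip(s, c(5, 2)), "window")
  expect_error(temporal_mip(s, c(0, 10)), "window")
})

test_that("ROI curves are per-frame means over the ROI", {
  vol <- array(0, c(4, 2, 3, 3))
  vol[, 1, 1, 1] <- c(0, 2, 4, 6)
  vol[, 1, 2, 2] <- c(0, 4, 8, 12)
  s <- perfusion_series(vol + 0)
  roi1 <- array(0, c(2, 3, 3)); roi1[1, 1, 1] <- 1
  expect_equal(extract_roi_curve(s, brain_mask(roi1))$values, c(0, 2, 4, 6))
  roi2 <- roi1; roi2[1, 2, 2] <- 1
  cv <- extract_roi_curve(s, brain_mask(roi2))
  expect_equal(cv$values, c(0, 3, 6, 9))
  expect_length(cv$values, 4)
  expect_error(extract_roi_curve(s, brain_mask(array(0, c(2, 3, 3)))), "empty ROI")
})

# brute-force oracle for the landmark rules, written independently of the
# package implementation
oracle_landmarks <- function(a, v, frac = 0.1, tol = 0.05) {
  art <- which(a == max(a))[1] - 1
  ven <- which(v == max(v))[1] - 1
  arr <- NA
  for (k in seq_along(a)) if (a[k] > frac * max(a)) { arr <- k - 1; break }
  ps <- NA
  for (k in (ven + 1):(length(v) - 2)) {
    if (abs(v[k + 2] - v[k + 1]) <= tol * max(v)) { ps <- k; break }
  }
  ve <- ps
  while (ve + 1 <= length(v) - 2 &&
         abs(v[ve + 2 + 1] - v[ve + 1 + 1]) <= tol * max(v)) ve <- ve + 1
  c(arr, art, ven, ps, min(ve + 1, length(v) - 2))
}

test_that("landmark detection matches a brute-force scan on triangular curves", {
  Tn <- 40
  a <- numeric(Tn); a[1:11] <- c(0, 0, 0, 2, 6, 10, 6, 4, 2, 1, 0)
  v <- numeric(Tn)
  v[9:20] <- c(1, 3, 6, 8, 10, 8, 6, 4, 4, 4, 4, 0)   # peak 12, flat 15..18
  lm <- detect_landmarks(signal_time_curve(a), signal_time_curve(v))
  ref <- oracle_landmarks(a, v)
  expect_equal(lm$t_arrival, ref[1])
  expect_equal(lm$t_arterial_peak, 5)
  expect_equal(lm$t_venous_peak, 12)
  expect_equal(lm$t_plateau_start, ref[4])
  expect_equal(lm$t_venous_end, ref[5])
})

test_that("degenerate curves raise informative landmark errors", {
  z <- signal_time_curve(numeric(20))
  expect_error(detect_landmarks(z, z), "no bolus")
  mono <- signal_time_curve(seq(0, 1, length.out = 20))
  expect_error(detect_landmarks(mono, mono), "no bolus")
  a <- signal_time_curve(c(0, 1, 5, 1, 0, 0, 0, 0))
  v_early <- signal_time_curve(c(0, 5, 1, 0, 0, 0, 0, 0) + 0.01)
  expect_error(detect_landmarks(a, v_early), "venous peak")
})

test_that("gamma-variate peak lands on the grid point nearest the analytic peak", {
  gv <- gamma_variate(6.4, 2, 1.6, K = 3)
  # analytic maximum at t0 + alpha*beta = 9.6 s
  tt <- seq(0, 100, by = 0.001)
  cc <- gamma_variate_curve(gv, tt)
  expect_equal(tt[which.max(cc)], 9.6, tolerance = 1e-3)
  expect_equal(max(cc), 3, tolerance = 1e-6)
  expect_equal(gamma_variate_curve(gv, 6.4), 0)
  grid <- (0:39) * 1.6
  disc <- gamma_variate_curve(gv, grid)
  expect_equal(which.max(disc) - 1, round(9.6 / 1.6))
})

test_that("phase partition follows the stated convention and covers the tail", {
  lm <- phase_landmarks(3, 5, 12, 15, 18)
  w <- partition_phases(lm, 40)
  expect_equal(w$Art, c(3, 5))
  expect_equal(w$Cap, c(6, 12))
  expect_equal(w$EVen, c(13, 15))
  expect_equal(w$LVen, c(16, 18))
  expect_equal(w$Del, c(19, 39))
  # disjoint and contiguous cover of [arrival, T-1]
  idx <- unlist(lapply(unclass(w)[1:5], function(iv) seq(iv[1], iv[2])),
                use.names = FALSE)
  expect_equal(sort(idx), 3:39)
  expect_equal(anyDuplicated(idx), 0)
  lm2 <- phase_landmarks(3, 5, 12, 18, 18)
  expect_error(partition_phases(lm2, 40), "LVen")
  expect_error(phase_landmarks(3, 5, 5, 15, 18), "ordering")
})

test_that("phase maps are windowed maxima of the subtracted series", {
  Tn <- 40
  vol <- array(100, c(Tn, 2, 4, 4))
  vol[5, 1, 2, 2] <- 92      # drop of 8 inside the Art window
  vol[20, 1, 2, 2] <- 98     # drop of 2 later
  s <- subtract_baseline(perfusion_series(vol + 0))
  w <- partition_phases(phase_landmarks(3, 5, 12, 15, 18), Tn)
  mp <- compose_phase_maps(s, w)
  expect_equal(mp$maps[1, 1, 2, 2], 8)
  expect_true(all(mp$maps[2:5, 1, 2, 2] <= 2))
  # all-zero series gives all-zero maps
  zs <- subtract_baseline(perfusion_series(array(7, c(Tn, 2, 4, 4)) + 0))
  expect_true(all(compose_phase_maps(zs, w)$maps == 0))
  # per-voxel: sum of phase maxima bounds the global temporal max
  set.seed(11)
  rs <- subtract_baseline(rand_series(Tn = Tn, D = 2, H = 4, W = 4))
  mr <- compose_phase_maps(rs, w)
  tail_max <- temporal_mip(rs, c(3, Tn - 1))
  sums <- apply(mr$maps, c(2, 3, 4), sum)
  expect_true(all(sums >= tail_max - 1e-12))
  # mean/sum variants stay within [0, max]
  mm <- compose_phase_maps(rs, w, stat = "mean")
  expect_true(all(mm$maps <= mr$maps + 1e-12))
})
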