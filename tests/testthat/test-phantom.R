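test_that("gamma-variate curves are zero before onset and peak-normalized", {
  gv <- gamma_variate(5, 2.5, 1.8, K = 7)
  expect_equal(gamma_variate_curve(gv, c(0, 2, 5)), c(0, 0, 0))
  expect_equal(gamma_variate_curve(gv, 5 + 2.5 * 1.8), 7, tolerance = 1e-12)
  expect_error(gamma_variate(5, -1, 2), "positive")
  expect_error(gamma_variate(5, 1, 0), "positive")
  expect_error(gamma_variate_curve(gv, c(3, 2, 1)), "ascending")
})

test_that("phantoms are deterministic given a seed and differ across seeds", {
  sp <- phantom_spec(grid = c(40L, 20L, 32L, 32L), seed = 4L)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$series$data, b$series$data)
  sp2 <- sp; sp2$seed <- 5L
  expect_false(identical(make_phantom(sp2)$series$data, a$series$data))
})

test_that("noiseless phantom closes the ground-truth pipeline exactly", {
  sp <- phantom_spec(noise_sigma = 0)
  ph <- make_phantom(sp)
  expect_identical(ph$series$data, ph$series_noiseless$data)
  sub <- subtract_baseline(ph$series)
  lm <- detect_landmarks(extract_roi_curve(sub, ph$roi_mca),
                         extract_roi_curve(sub, ph$roi_sss))
  expect_identical(unclass(lm), unclass(ph$landmarks))
  win <- partition_phases(lm, ph$series$t_count)
  expect_identical(unclass(win), unclass(ph$windows))
  maps <- compose_phase_maps(sub, win)
  expect_identical(maps$maps, ph$maps$maps)
  # windows partition [arrival, T-1]
  idx <- unlist(lapply(unclass(win)[1:5], function(iv) seq(iv[1], iv[2])),
                use.names = FALSE)
  expect_equal(sort(idx), seq(lm$t_arrival, ph$series$t_count - 1))
})

test_that("lesion kinetics scale the arterial peak by the amplitude factor", {
  le <- phantom_lesion(delay_s = 4.8, amplitude_factor = 0.55)
  sp <- phantom_spec(lesion = le, noise_sigma = 0)
  ph <- make_phantom(sp)
  expect_gt(sum(ph$lesion_mask), 0)
  sub <- subtract_baseline(ph$series)
  peak_map <- temporal_mip(sub)
  ns <- asNamespace("collmapnet")
  geo <- ns$phantom_geometry(20, 64, 64)
  lidx <- which(ph$lesion_mask != 0)
  # delayed arterial peak falls on the sampling grid, so the lesion's
  # temporal max is exactly amplitude_factor * drop * baseline * amp field
  expect_equal(peak_map[lidx],
               0.55 * sp$drop_fraction * sp$baseline_intensity * geo$amp[lidx],
               tolerance = 1e-9)
  tidx <- which(geo$tissue * (1 - ph$lesion_mask) != 0)
  # and strictly below what the same voxels would show with tissue kinetics
  expect_lt(max(peak_map[lidx] / geo$amp[lidx]),
            min(peak_map[tidx] / geo$amp[tidx]) + 1e-9)
})

test_that("cohorts have the requested composition and valid, distinct series", {
  cohort <- make_cohort(4, 4, phantom_spec(grid = c(40L, 20L, 32L, 32L)), seed = 3)
  expect_length(cohort, 8)
  expect_equal(sum(vapply(cohort, function(s) s$group == "stroke", logical(1))), 4)
  sums <- vapply(cohort, function(s) sum(s$series$data), numeric(1))
  expect_equal(anyDuplicated(sums), 0)
  for (s in cohort) expect_silent(validate_series(s$series, c(40L, 20L)))
  # deterministic replay
  cohort2 <- make_cohort(4, 4, phantom_spec(grid = c(40L, 20L, 32L, 32L)), seed = 3)
  expect_identical(cohort[[5]]$series$data, cohort2[[5]]$series$data)
  expect_length(make_cohort(0, 0), 0)
})

test_that("landmark peaks survive 2% noise within one frame in >= 95/100 trials", {
  sp <- phantom_spec(noise_sigma = 0)
  ph <- make_phantom(sp)
  sigma <- 0.02 * sp$baseline_intensity * sp$drop_fraction
  aidx <- which(ph$roi_mca$mask != 0)
  vidx <- which(ph$roi_sss$mask != 0)
  x <- ph$series_noiseless$data
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[2:4]))
  A <- x[, aidx]; V <- x[, vidx]
  truth <- ph$landmarks
  set.seed(2024)
  hits <- 0
  for (trial in 1:100) {
    An <- A + rnorm(length(A), sd = sigma)
    Vn <- V + rnorm(length(V), sd = sigma)
    ca <- rowMeans(pmax(rep(An[1, ], each = d[1]) - An, 0))
    cv <- rowMeans(pmax(rep(Vn[1, ], each = d[1]) - Vn, 0))
    lm <- tryCatch(detect_landmarks(signal_time_curve(ca), signal_time_curve(cv)),
                   error = function(e) NULL)
    if (!is.null(lm) &&
        abs(lm$t_arterial_peak - truth$t_arterial_peak) <= 1 &&
        abs(lm$t_venous_peak - truth$t_venous_peak) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
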