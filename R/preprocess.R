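# Preprocessing chain: brain-mask creation, min-max normalization of the
# series and targets, median filtering of the targets, center cropping.
# Fixed pipeline order: mask -> normalize -> (targets: clip/scale, median
# filter) -> crop.

#' Preprocessing configuration
#'
#' @param mask_threshold threshold on the min-max-normalized temporal-sum
#'   image (default 0.1).
#' @param morph_radius radius (voxels) of the spherical structuring element
#'   used for closing, erosion and dilation (default 6).
#' @param median_kernel odd window size of the per-slice 2D median filter
#'   applied to the target maps (default 5).
#' @param crop_size in-plane output size of the center crop (default 224).
#' @param target_range closed interval the target maps are mapped onto
#'   (default `c(-0.9, 0.9)`).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(mask_threshold = 0.1, morph_radius = 6L,
                              median_kernel = 5L, crop_size = 224L,
                              target_range = c(-0.9, 0.9)) {
  stopifnot(mask_threshold > 0, mask_threshold < 1,
            morph_radius >= 1, median_kernel %% 2 == 1,
            crop_size >= 1, length(target_range) == 2,
            target_range[1] < target_range[2])
  structure(list(mask_threshold = mask_threshold,
                 morph_radius = as.integer(morph_radius),
                 median_kernel = as.integer(median_kernel),
                 crop_size = as.integer(crop_size),
                 target_range = target_range),
            class = "preprocess_config")
}

## ---- 3D binary morphology via FFT convolution ------------------------------

# discrete Euclidean ball of radius r as a (2r+1)^3 0/1 array
ball_kernel <- function(r) {
  g <- seq(-r, r)
  k <- outer(outer(g^2, g^2, `+`), g^2, `+`) <= r^2
  array(as.numeric(k), dim = c(2 * r + 1, 2 * r + 1, 2 * r + 1))
}

# sum of kernel over each neighborhood, computed by FFT convolution with
# replicate (edge-extension) borders so a brain touching the volume edge --
# routine for 20-slice stacks -- is not eaten by erosion at the walls;
# exact up to ~1e-8, then thresholded at half-integers
binary_conv3d <- function(mask, kernel) {
  dm <- dim(mask); dk <- dim(kernel)
  r <- (dk - 1L) %/% 2L
  zi <- pmin(pmax(seq_len(dm[1] + 2L * r[1]) - r[1], 1L), dm[1])
  yi <- pmin(pmax(seq_len(dm[2] + 2L * r[2]) - r[2], 1L), dm[2])
  xi <- pmin(pmax(seq_len(dm[3] + 2L * r[3]) - r[3], 1L), dm[3])
  padded <- mask[zi, yi, xi]
  dmp <- dim(padded)
  dp <- dmp + dk - 1L
  a <- array(0, dp); a[seq_len(dmp[1]), seq_len(dmp[2]), seq_len(dmp[3])] <- padded
  b <- array(0, dp); b[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  conv <- Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / prod(dp)
  conv[2L * r[1] + seq_len(dm[1]), 2L * r[2] + seq_len(dm[2]), 2L * r[3] + seq_len(dm[3])]
}

dilate3d <- function(mask, kernel) (binary_conv3d(mask, kernel) > 0.5) * 1
erode3d <- function(mask, kernel) (binary_conv3d(mask, kernel) > sum(kernel) - 0.5) * 1

#' Build a brain mask from a perfusion series
#'
#' Sums the series over time, min-max normalizes the summed volume to
#' `[0, 1]`, thresholds it, and refines the result with morphological
#' closing, erosion and dilation (in that order) using a spherical
#' structuring element.
#'
#' @param series a [perfusion_series()].
#' @param cfg a [preprocess_config()].
#' @return a [brain_mask()] (non-empty, or an error).
#' @export
build_brain_mask <- function(series, cfg = preprocess_config()) {
  stopifnot(inherits(series, "perfusion_series"))
  x <- series$data
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[2:4]))
  s <- colSums(x)
  lo <- min(s); hi <- max(s)
  if (hi <= lo) stop("empty mask: summed image has no dynamic range")
  s <- (s - lo) / (hi - lo)
  m <- array(as.numeric(s > cfg$mask_threshold), d[2:4])
  k <- ball_kernel(cfg$morph_radius)
  m <- erode3d(dilate3d(m, k), k)   # closing
  m <- erode3d(m, k)
  m <- dilate3d(m, k)
  if (sum(m) == 0) stop("empty mask after morphology")
  brain_mask(m)
}

#' Min-max normalize a perfusion series within a brain mask
#'
#' Intensities are linearly mapped so that the minimum and maximum over all
#' masked voxels across all time points become 0 and 1 (global statistics,
#' preserving the temporal bolus dynamics); voxels outside the mask are set
#' to 0.
#'
#' @param series a [perfusion_series()].
#' @param mask a [brain_mask()].
#' @return normalized [perfusion_series()].
#' @export
normalize_series <- function(series, mask) {
  stopifnot(inherits(series, "perfusion_series"), inherits(mask, "brain_mask"))
  idx <- which(mask$mask != 0)
  if (length(idx) == 0) stop("empty mask")
  x <- series$data
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[2:4]))
  vals <- x[, idx, drop = FALSE]
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) stop("zero dynamic range within mask")
  x <- (x - lo) / (hi - lo)
  x[, -idx] <- 0
  dim(x) <- d
  out <- series
  out$data <- x
  out$meta$normalized <- c(lo = lo, hi = hi)
  out
}

#' Normalize collateral maps onto the target interval
#'
#' Raw maps are min-max scaled to `[0, 1]` (global statistics over the whole
#' five-phase set, preserving relative phase amplitudes); maps already on the
#' unit scale have out-of-range values clipped to 0 or 1. The unit-scale
#' values are then mapped affinely onto the target interval,
#' `v -> 1.8 v - 0.9` for the default `[-0.9, 0.9]`.
#'
#' @param maps a [collateral_maps()] with `value_range` `"raw"` or `"unit"`.
#' @param cfg a [preprocess_config()].
#' @return a [collateral_maps()] with `value_range = "target"`.
#' @export
normalize_targets <- function(maps, cfg = preprocess_config()) {
  stopifnot(inherits(maps, "collateral_maps"))
  if (maps$value_range == "target") return(maps)
  m <- maps$maps
  if (!all(is.finite(m))) stop("non-finite values in maps")
  if (maps$value_range == "raw") {
    lo <- min(m); hi <- max(m)
    if (hi <= lo) stop("zero dynamic range in maps")
    m <- (m - lo) / (hi - lo)
  }
  m <- pmin(pmax(m, 0), 1)
  tr <- cfg$target_range
  m <- (tr[2] - tr[1]) * m + tr[1]
  collateral_maps(m, value_range = "target")
}

#' Median filter collateral maps
#'
#' Applies a per-phase, per-slice 2D median filter (window
#' `median_kernel x median_kernel`, replicate padding at borders). Filtering
#' is 2D rather than 3D because slice spacing is roughly an order of
#' magnitude coarser than in-plane resolution.
#'
#' @param maps a [collateral_maps()].
#' @param cfg a [preprocess_config()].
#' @return filtered [collateral_maps()] of identical shape.
#' @export
median_filter_targets <- function(maps, cfg = preprocess_config()) {
  stopifnot(inherits(maps, "collateral_maps"))
  m <- maps$maps
  d <- dim(m)
  for (p in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      m[p, z, , ] <- cm_median2d(array(m[p, z, , ], d[3:4]), cfg$median_kernel)
    }
  }
  out <- maps
  out$maps <- m
  out
}

#' Center crop a series or map set to the configured in-plane size
#'
#' Crops the two spatial axes symmetrically; when the size difference is
#' odd, the extra dropped pixel comes from the high-index side. Time and
#' slice axes are untouched.
#'
#' @param volume a [perfusion_series()] or [collateral_maps()].
#' @param cfg a [preprocess_config()].
#' @return same type as `volume`, cropped to `crop_size x crop_size`.
#' @export
center_crop <- function(volume, cfg = preprocess_config()) {
  cs <- cfg$crop_size
  arr <- if (inherits(volume, "perfusion_series")) volume$data
         else if (inherits(volume, "collateral_maps")) volume$maps
         else stop("expected a perfusion_series or collateral_maps")
  d <- dim(arr)
  if (d[3] < cs || d[4] < cs)
    stop("input (", d[3], "x", d[4], ") smaller than crop size ", cs)
  oy <- (d[3] - cs) %/% 2L
  ox <- (d[4] - cs) %/% 2L
  arr <- arr[, , oy + seq_len(cs), ox + seq_len(cs), drop = FALSE]
  if (inherits(volume, "perfusion_series")) {
    out <- volume
    out$data <- arr
    out$spatial <- c(cs, cs)
  } else {
    out <- volume
    out$maps <- arr
  }
  out
}

#' Run the full preprocessing pipeline on one subject
#'
#' Mask creation, series normalization, target normalization and median
#' filtering (when maps are supplied), and center cropping of everything.
#'
#' @param series a [perfusion_series()].
#' @param maps optional [collateral_maps()] ground truth.
#' @param cfg a [preprocess_config()].
#' @return list with elements `series`, `mask`, and (if given) `maps`, all
#'   cropped to `crop_size`.
#' @export
preprocess_subject <- function(series, maps = NULL, cfg = preprocess_config()) {
  mask <- build_brain_mask(series, cfg)
  ser <- center_crop(normalize_series(series, mask), cfg)
  cs <- cfg$crop_size
  d <- dim(mask$mask)
  oy <- (d[2] - cs) %/% 2L
  ox <- (d[3] - cs) %/% 2L
  mk <- brain_mask(mask$mask[, oy + seq_len(cs), ox + seq_len(cs), drop = FALSE])
  out <- list(series = ser, mask = mk)
  if (!is.null(maps)) {
    mp <- median_filter_targets(normalize_targets(maps, cfg), cfg)
    out$maps <- center_crop(mp, cfg)
  }
  out
}
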