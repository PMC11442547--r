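# BerHu (reverse Huber) training loss and the four evaluation metrics:
# R-squared, mean absolute error, Tanimoto measure, and global SSIM,
# computed per phase per subject over brain-mask voxels.

#' BerHu (reverse Huber) loss
#'
#' Elementwise `L(r) = |r|` when `|r| <= c`, else `(r^2 + c^2) / (2c)`, with
#' residual \code{r = y - y_hat}. The two branches agree at `|r| = c` (both give
#' `c`) with matching slope, so the loss is continuous and C1 at the knot:
#' L1 behavior near zero, scaled-quadratic growth for outliers.
#'
#' @param y ground-truth array/vector.
#' @param y_hat predicted values, same shape.
#' @param c positive threshold (default 0.2).
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return non-negative scalar loss.
#' @export
berhu_loss <- function(y, y_hat, c = 0.2, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  stopifnot(c > 0, length(y) == length(y_hat))
  if (!all(is.finite(y)) || !all(is.finite(y_hat)))
    stop("non-finite inputs to BerHu loss")
  r <- as.numeric(y) - as.numeric(y_hat)
  a <- abs(r)
  l <- ifelse(a <= c, a, (r * r + c * c) / (2 * c))
  if (reduction == "mean") mean(l) else sum(l)
}

# gradient of mean-reduced BerHu loss wrt y_hat (used by the trainer)
berhu_grad <- function(y, y_hat, c = 0.2) {
  r <- y - y_hat
  a <- abs(r)
  g <- ifelse(a <= c, -sign(r), -r / c)
  g / length(y)
}

#' Coefficient of determination between prediction and ground truth
#'
#' `1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`; equals 1 iff the
#' prediction is exact and can be negative for poor predictions (no
#' clamping is applied).
#'
#' @param y ground-truth vector (non-constant).
#' @param y_hat prediction vector.
#' @return scalar, at most 1.
#' @export
r_squared <- function(y, y_hat) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  stopifnot(length(y) == length(y_hat))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) stop("constant ground truth: R-squared undefined")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Mean absolute error
#' @inheritParams r_squared
#' @return non-negative scalar, 0 iff inputs are equal.
#' @export
mae <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  mean(abs(as.numeric(y) - as.numeric(y_hat)))
}

#' Tanimoto measure (generalized Jaccard similarity for real vectors)
#'
#' `sum(y * y_hat) / (sum(y^2) + sum(y_hat^2) - sum(y * y_hat))`.
#'
#' @inheritParams r_squared
#' @return scalar; 1 for identical nonzero vectors.
#' @export
tanimoto <- function(y, y_hat) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  stopifnot(length(y) == length(y_hat))
  dot <- sum(y * y_hat)
  den <- sum(y * y) + sum(y_hat * y_hat) - dot
  if (den == 0) stop("Tanimoto undefined: both inputs all zero")
  dot / den
}

#' Global structural similarity between two masked voxel populations
#'
#' Single-statistic SSIM over the whole voxel population (means, variances
#' and covariance over all n voxels), not a windowed mean-SSIM; see
#' [ssim_windowed()] for the windowed variant. Stabilizers
#' `C1 = (K1 L)^2`, `C2 = (K2 L)^2` with dynamic range `L` defaulting to 1.8
#' (the width of the target interval `[-0.9, 0.9]`).
#'
#' @inheritParams r_squared
#' @param dynamic_range value range L of the data (default 1.8).
#' @param K1,K2 stabilizer constants (0.01, 0.03).
#' @return scalar in `[-1, 1]`.
#' @export
ssim_global <- function(y, y_hat, dynamic_range = 1.8, K1 = 0.01, K2 = 0.03) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  n <- length(y)
  mu_y <- mean(y); mu_p <- mean(y_hat)
  v_y <- mean((y - mu_y)^2)
  v_p <- mean((y_hat - mu_p)^2)
  cov_py <- mean((y_hat - mu_p) * (y - mu_y))
  ((2 * mu_p * mu_y + C1) * (2 * cov_py + C2)) /
    ((mu_p^2 + mu_y^2 + C1) * (v_p + v_y + C2))
}

#' Windowed SSIM over a volume (non-default variant)
#'
#' Mean of local SSIM computed with a cubic Gaussian window, for users who
#' prefer the windowed convention; [ssim_global()] is the package default.
#'
#' @param y,y_hat numeric 3D arrays of identical shape.
#' @param window odd window edge length (default 11).
#' @param sigma Gaussian sigma in voxels (default 1.5).
#' @inheritParams ssim_global
#' @return scalar mean local SSIM.
#' @export
ssim_windowed <- function(y, y_hat, window = 11L, sigma = 1.5,
                          dynamic_range = 1.8, K1 = 0.01, K2 = 0.03) {
  stopifnot(identical(dim(y), dim(y_hat)), length(dim(y)) == 3)
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  g <- exp(-0.5 * (seq(-(window %/% 2), window %/% 2) / sigma)^2)
  g <- g / sum(g)
  k <- outer(outer(g, g), g)
  smooth <- function(a) {
    da <- dim(a); dk <- dim(k)
    dp <- da + dk - 1L
    pa <- array(0, dp); pa[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- a
    pk <- array(0, dp); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
    conv <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) / prod(dp)
    r <- (dk - 1L) %/% 2L
    conv[r[1] + seq_len(da[1]), r[2] + seq_len(da[2]), r[3] + seq_len(da[3])]
  }
  mu_y <- smooth(y); mu_p <- smooth(y_hat)
  v_y <- smooth(y * y) - mu_y^2
  v_p <- smooth(y_hat * y_hat) - mu_p^2
  cv <- smooth(y * y_hat) - mu_y * mu_p
  s <- ((2 * mu_p * mu_y + C1) * (2 * cv + C2)) /
    ((mu_p^2 + mu_y^2 + C1) * (v_p + v_y + C2))
  mean(s)
}

#' Evaluate one subject: all four metrics for each of the five phases
#'
#' Metrics are computed over brain-mask voxels only (background is constant
#' and would inflate R-squared and SSIM); pass an all-ones mask for
#' whole-volume metrics.
#'
#' @param pred predicted [collateral_maps()].
#' @param truth ground-truth [collateral_maps()].
#' @param mask a [brain_mask()].
#' @return data frame with one row per phase and columns `phase`,
#'   `r_squared`, `mae`, `tanimoto`, `ssim` (20 numbers).
#' @export
evaluate_subject <- function(pred, truth, mask) {
  stopifnot(inherits(pred, "collateral_maps"), inherits(truth, "collateral_maps"),
            inherits(mask, "brain_mask"))
  if (!identical(dim(pred$maps), dim(truth$maps)))
    stop("prediction and truth shapes differ")
  idx <- which(mask$mask != 0)
  if (length(idx) < 2) stop("mask selects fewer than 2 voxels")
  out <- lapply(seq_along(PHASE_NAMES), function(i) {
    yp <- pred$maps[i, , , ][idx]
    yt <- truth$maps[i, , , ][idx]
    data.frame(phase = PHASE_NAMES[i],
               r_squared = r_squared(yt, yp),
               mae = mae(yt, yp),
               tanimoto = tanimoto(yt, yp),
               ssim = ssim_global(yt, yp))
  })
  do.call(rbind, out)
}
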