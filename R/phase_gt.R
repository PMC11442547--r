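# Semi-automatic five-phase ground-truth generation: baseline subtraction,
# ROI signal-time curves from the middle cerebral artery (MCA) and superior
# sagittal sinus (SSS), landmark detection, phase partitioning, and
# per-phase map composition.
#
# All temporal indices in this module are 0-based (frame 0 is the
# pre-contrast baseline).

#' Construct an ROI signal-time curve
#' @param values numeric vector, one mean signal value per time point.
#' @param dt_seconds temporal resolution in seconds.
#' @return object of class `signal_time_curve`.
#' @export
signal_time_curve <- function(values, dt_seconds = 1.6) {
  if (!all(is.finite(values))) stop("non-finite curve values")
  structure(list(values = as.numeric(values), dt_seconds = dt_seconds),
            class = "signal_time_curve")
}

#' Construct the five temporal landmarks
#'
#' 0-based frame indices: contrast arrival at the MCA, arterial peak,
#' venous peak (SSS), start of the venous plateau, and end of the venous
#' phase. The ordering invariant
#' `arrival <= arterial_peak < venous_peak < plateau_start <= venous_end`
#' is enforced.
#'
#' @param t_arrival,t_arterial_peak,t_venous_peak,t_plateau_start,t_venous_end
#'   integer 0-based frame indices.
#' @return object of class `phase_landmarks`.
#' @export
phase_landmarks <- function(t_arrival, t_arterial_peak, t_venous_peak,
                            t_plateau_start, t_venous_end) {
  lm <- list(t_arrival = as.integer(t_arrival),
             t_arterial_peak = as.integer(t_arterial_peak),
             t_venous_peak = as.integer(t_venous_peak),
             t_plateau_start = as.integer(t_plateau_start),
             t_venous_end = as.integer(t_venous_end))
  with(lm, {
    if (!(t_arrival <= t_arterial_peak && t_arterial_peak < t_venous_peak &&
          t_venous_peak < t_plateau_start && t_plateau_start <= t_venous_end))
      stop("landmark ordering violated: need arrival <= arterial peak < ",
           "venous peak < plateau start <= venous end")
  })
  structure(lm, class = "phase_landmarks")
}

#' @export
print.phase_landmarks <- function(x, ...) {
  cat(sprintf("<phase_landmarks> arrival %d, arterial peak %d, venous peak %d, plateau %d, venous end %d\n",
              x$t_arrival, x$t_arterial_peak, x$t_venous_peak,
              x$t_plateau_start, x$t_venous_end))
  invisible(x)
}

#' Subtract the pre-contrast baseline frame
#'
#' For T2*-weighted DSC data the bolus causes a signal drop, so the default
#' subtraction is baseline minus frame, clipped at zero
#' (`s_t = max(0, I_0 - I_t)`), making bolus passage a positive quantity;
#' `sign = "rise"` gives `max(0, I_t - I_0)` for signal-increasing data.
#'
#' @param series a [perfusion_series()] with at least 2 frames.
#' @param sign `"drop"` (default) or `"rise"`.
#' @return a baseline-subtracted [perfusion_series()] (frame 0 all zero).
#' @export
subtract_baseline <- function(series, sign = c("drop", "rise")) {
  sign <- match.arg(sign)
  stopifnot(inherits(series, "perfusion_series"))
  x <- series$data
  d <- dim(x)
  base <- x[1, , , ]
  base <- array(rep(as.vector(base), each = d[1]), d)
  s <- if (sign == "drop") pmax(base - x, 0) else pmax(x - base, 0)
  out <- series
  out$data <- s
  out$meta$baseline_subtracted <- sign
  out
}

#' Temporal maximum-intensity projection over a frame window
#'
#' @param subtracted a baseline-subtracted [perfusion_series()].
#' @param window inclusive 0-based frame interval `c(lo, hi)`; defaults to
#'   the full time range (the subtracted MIP, sMIP).
#' @return numeric 3D array `(z, y, x)`.
#' @export
temporal_mip <- function(subtracted, window = NULL) {
  stopifnot(inherits(subtracted, "perfusion_series"))
  Tn <- subtracted$t_count
  if (is.null(window)) window <- c(0L, Tn - 1L)
  window <- as.integer(window)
  if (window[1] > window[2] || window[1] < 0 || window[2] >= Tn)
    stop("empty or out-of-range window [", window[1], ", ", window[2], "]")
  slices <- lapply(seq(window[1], window[2]),
                   function(t) {
                     s <- subtracted$data[t + 1L, , , ]
                     array(s, dim(subtracted$data)[2:4])
                   })
  do.call(pmax, slices)
}

#' Mean ROI signal-time curve
#'
#' @param subtracted a [perfusion_series()] (typically baseline-subtracted).
#' @param roi a [brain_mask()] selecting the ROI voxels.
#' @return a [signal_time_curve()] of length `t_count`.
#' @export
extract_roi_curve <- function(subtracted, roi) {
  stopifnot(inherits(subtracted, "perfusion_series"), inherits(roi, "brain_mask"))
  idx <- which(roi$mask != 0)
  if (length(idx) == 0) stop("empty ROI")
  x <- subtracted$data
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[2:4]))
  signal_time_curve(rowMeans(x[, idx, drop = FALSE]), subtracted$dt_seconds)
}

#' Detect the five temporal landmarks from MCA and SSS curves
#'
#' Deterministic rules replacing the expert-in-the-loop step of the
#' semi-automatic procedure: the arterial and venous peaks are the argmax of
#' the MCA and SSS curves; contrast arrival is the first frame where the MCA
#' curve exceeds `arrival_frac` of its maximum; the venous plateau starts at
#' the first frame after the venous peak whose forward difference falls
#' below `plateau_tol` of the SSS maximum, and the venous end is the last
#' frame reached by the maximal run of consecutive plateau-satisfying steps
#' (capped at `T - 2` so the delay phase is non-empty). Any landmark can be
#' overridden manually via `override`.
#'
#' @param mca,sss [signal_time_curve()]s for the arterial and venous ROIs.
#' @param arrival_frac fraction of the MCA maximum defining arrival (0.1).
#' @param plateau_tol fraction of the SSS maximum bounding plateau steps (0.05).
#' @param override named list of manual landmark replacements (0-based).
#' @return a [phase_landmarks()].
#' @export
detect_landmarks <- function(mca, sss, arrival_frac = 0.1, plateau_tol = 0.05,
                             override = list()) {
  stopifnot(inherits(mca, "signal_time_curve"), inherits(sss, "signal_time_curve"))
  a <- mca$values; v <- sss$values
  Tn <- length(a)
  if (length(v) != Tn) stop("curve lengths differ")
  if (max(a) <= 0 || max(v) <= 0) stop("no bolus detected: flat or empty curve")
  t_art <- which.max(a) - 1L
  t_ven <- which.max(v) - 1L
  if (t_art %in% c(0L, Tn - 1L) || t_ven %in% c(0L, Tn - 1L))
    stop("no bolus detected: curve maximum is not interior")
  if (t_ven <= t_art)
    stop("venous peak (", t_ven, ") not after arterial peak (", t_art, ")")
  t_arrival <- which(a > arrival_frac * max(a))[1] - 1L
  if (is.na(t_arrival)) stop("no bolus detected: arrival threshold never crossed")
  steps_ok <- abs(diff(v)) <= plateau_tol * max(v)   # steps_ok[k+1]: step k -> k+1
  cand <- which(steps_ok) - 1L                       # 0-based step start indices
  cand <- cand[cand > t_ven]
  if (length(cand) == 0) stop("no venous plateau found after the venous peak")
  t_ps <- cand[1]
  k <- t_ps
  while (k + 1L <= Tn - 2L && steps_ok[k + 2L]) k <- k + 1L
  t_ve <- min(k + 1L, Tn - 2L)
  lm <- list(t_arrival = t_arrival, t_arterial_peak = t_art,
             t_venous_peak = t_ven, t_plateau_start = t_ps, t_venous_end = t_ve)
  for (nm in names(override)) lm[[nm]] <- as.integer(override[[nm]])
  phase_landmarks(lm$t_arrival, lm$t_arterial_peak, lm$t_venous_peak,
                  lm$t_plateau_start, lm$t_venous_end)
}

#' Partition the time axis into the five collateral phases
#'
#' Art spans arrival to arterial peak; Cap spans arterial peak + 1 to venous
#' peak; EVen venous peak + 1 to plateau start; LVen plateau start + 1 to
#' venous end; Del venous end + 1 to `T - 1`. Windows are inclusive 0-based
#' intervals, pairwise disjoint and contiguous from arrival to `T - 1`.
#'
#' @param lm a [phase_landmarks()].
#' @param T_n total number of time points.
#' @return object of class `phase_windows`: named list of `c(lo, hi)` pairs.
#' @export
partition_phases <- function(lm, T_n) {
  stopifnot(inherits(lm, "phase_landmarks"))
  T_n <- as.integer(T_n)
  if (T_n <= lm$t_venous_end) stop("T must exceed the venous end landmark")
  w <- list(Art = c(lm$t_arrival, lm$t_arterial_peak),
            Cap = c(lm$t_arterial_peak + 1L, lm$t_venous_peak),
            EVen = c(lm$t_venous_peak + 1L, lm$t_plateau_start),
            LVen = c(lm$t_plateau_start + 1L, lm$t_venous_end),
            Del = c(lm$t_venous_end + 1L, T_n - 1L))
  for (nm in names(w)) {
    if (w[[nm]][1] > w[[nm]][2]) stop("empty ", nm, " phase window")
  }
  structure(w, class = "phase_windows")
}

#' @export
print.phase_windows <- function(x, ...) {
  for (nm in names(unclass(x)))
    cat(sprintf("%5s: [%d, %d]\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

#' Compose the five-phase collateral maps from a subtracted series
#'
#' Each phase map is the voxelwise temporal maximum (default; `"mean"` and
#' `"sum"` are available alternatives) of the baseline-subtracted series
#' within the phase window, mirroring the subtracted-MIP construction.
#'
#' @param subtracted a baseline-subtracted [perfusion_series()].
#' @param windows a [phase_windows()].
#' @param stat `"max"` (default), `"mean"` or `"sum"`.
#' @return a [collateral_maps()] with `value_range = "raw"`.
#' @export
compose_phase_maps <- function(subtracted, windows, stat = c("max", "mean", "sum")) {
  stat <- match.arg(stat)
  stopifnot(inherits(subtracted, "perfusion_series"), inherits(windows, "phase_windows"))
  d <- dim(subtracted$data)
  maps <- array(0, c(5L, d[2:4]))
  for (i in seq_along(PHASE_NAMES)) {
    w <- windows[[PHASE_NAMES[i]]]
    if (stat == "max") {
      maps[i, , , ] <- temporal_mip(subtracted, w)
    } else {
      idx <- seq(w[1], w[2]) + 1L
      sl <- subtracted$data[idx, , , , drop = FALSE]
      agg <- colSums(array(sl, c(length(idx), prod(d[2:4]))))
      if (stat == "mean") agg <- agg / length(idx)
      maps[i, , , ] <- array(agg, d[2:4])
    }
  }
  collateral_maps(maps, value_range = "raw")
}
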