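# Synthetic DSC-MRP phantom: analytic gamma-variate bolus dynamics in
# distinct arterial, capillary and venous compartments inside an ellipsoidal
# brain, an optional stroke lesion with delayed/diminished kinetics, and
# additive Gaussian noise. The generator returns exact ground truth --
# landmarks derived from the noiseless analytic ROI curves and phase maps
# composed from the noiseless series -- so every downstream module can be
# tested without patient data.

#' Gamma-variate bolus kinetics
#'
#' Peak-normalized gamma variate: zero for `t <= t0`, peaking with value `K`
#' at `t0 + alpha * beta`.
#'
#' @param t0 bolus onset (s).
#' @param alpha shape parameter (> 0).
#' @param beta scale parameter (s, > 0).
#' @param K peak amplitude (> 0).
#' @return object of class `gamma_variate`.
#' @export
gamma_variate <- function(t0, alpha, beta, K = 1) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (K <= 0) stop("K must be positive")
  structure(list(t0 = t0, alpha = alpha, beta = beta, K = K),
            class = "gamma_variate")
}

#' Evaluate a gamma-variate curve at given times
#'
#' `c(t) = K ((t - t0)/(alpha beta))^alpha exp(alpha - (t - t0)/beta)` for
#' `t > t0`, else 0; normalized so the continuous peak at `t0 + alpha beta`
#' has value `K`.
#'
#' @param gv a [gamma_variate()].
#' @param times ascending numeric vector of times (s).
#' @return numeric vector of concentrations.
#' @export
gamma_variate_curve <- function(gv, times) {
  stopifnot(inherits(gv, "gamma_variate"))
  if (is.unsorted(times)) stop("times must be ascending")
  u <- (times - gv$t0) / (gv$alpha * gv$beta)
  out <- ifelse(times > gv$t0,
                gv$K * u^gv$alpha * exp(gv$alpha * (1 - u)),
                0)
  as.numeric(out)
}

#' Phantom parameterization
#'
#' Defaults emulate the study acquisition at reduced in-plane scale:
#' 40 frames of 20 slices at 1.6 s temporal resolution, with a T2* signal
#' drop following compartment-specific gamma-variate kinetics. The venous
#' (SSS) curve adds a recirculation steady state so a genuine venous plateau
#' exists. The lesion (stroke subjects) uses arterial kinetics delayed by
#' `delay_s` and scaled by `amplitude_factor`.
#'
#' @param grid integer `(T, D, H, W)` (default 40, 20, 64, 64).
#' @param dt_seconds temporal resolution (1.6 s).
#' @param baseline_intensity pre-contrast signal level (100).
#' @param drop_fraction maximal fractional T2* signal drop in (0,1) (0.4).
#' @param artery,capillary,vein [gamma_variate()] kinetics per compartment.
#' @param recirc_frac venous steady-state amplitude as a fraction of the
#'   venous bolus peak (0.3).
#' @param lesion `NULL` or list with `delay_s`, `amplitude_factor`,
#'   `radius`, `center` (z, y, x; `NULL` centers it in the left hemisphere).
#' @param noise_sigma additive Gaussian noise SD in signal units (default
#'   1\% of the peak signal drop).
#' @param seed integer RNG seed for the noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(40L, 20L, 64L, 64L), dt_seconds = 1.6,
                         baseline_intensity = 100, drop_fraction = 0.4,
                         artery = gamma_variate(6.4, 3, 1.6),
                         capillary = gamma_variate(8.0, 3, 2.2),
                         vein = gamma_variate(11.2, 3.5, 2.0),
                         recirc_frac = 0.3,
                         lesion = NULL,
                         noise_sigma = 0.01 * baseline_intensity * drop_fraction,
                         seed = 1L) {
  stopifnot(length(grid) == 4, grid[1] >= 2, dt_seconds > 0,
            drop_fraction > 0, drop_fraction < 1, noise_sigma >= 0)
  ap <- artery$t0 + artery$alpha * artery$beta
  vp <- vein$t0 + vein$alpha * vein$beta
  if (vp <= ap) stop("venous peak must come after arterial peak")
  if (!is.null(lesion)) {
    stopifnot(lesion$amplitude_factor > 0, lesion$amplitude_factor <= 1)
  }
  structure(list(grid = as.integer(grid), dt_seconds = dt_seconds,
                 baseline_intensity = baseline_intensity,
                 drop_fraction = drop_fraction,
                 artery = artery, capillary = capillary, vein = vein,
                 recirc_frac = recirc_frac, lesion = lesion,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default lesion parameterization for stroke phantoms
#' @param delay_s bolus delay in the lesion (s).
#' @param amplitude_factor peak scaling in (0, 1].
#' @param radius lesion radius (voxels).
#' @param center optional `(z, y, x)` 1-based center.
#' @return list usable as the `lesion` field of [phantom_spec()].
#' @export
phantom_lesion <- function(delay_s = 4.8, amplitude_factor = 0.55,
                           radius = 7, center = NULL) {
  list(delay_s = delay_s, amplitude_factor = amplitude_factor,
       radius = radius, center = center)
}

# compartment geometry on the (z, y, x) grid: ellipsoidal brain, anterior
# midline arterial tube (MCA), posterior midline venous tube (SSS), cortical
# tissue elsewhere inside the brain. Vessel radius 3 so vessels survive the
# 5x5 median filter of the preprocessing chain; a smooth multiplicative
# perfusion-heterogeneity field over the tissue emulates gray/white-matter
# blood-volume variation.
phantom_geometry <- function(D, H, W) {
  # exact left-right symmetry about the midline: the method's flip
  # augmentation presumes mirror-symmetric anatomy, so the phantom honors it
  # (lesions, added elsewhere, stay lateralized as in real stroke)
  zc <- (D + 1) / 2; yc <- (H + 1) / 2; xc <- (W + 1) / 2
  z <- slice.index(array(0, c(D, H, W)), 1)
  y <- slice.index(array(0, c(D, H, W)), 2)
  x <- slice.index(array(0, c(D, H, W)), 3)
  brain <- ((z - zc) / (0.48 * D))^2 + ((y - yc) / (0.42 * H))^2 +
    ((x - xc) / (0.42 * W))^2 <= 1
  tube <- function(yq, r) (y - yq)^2 + (x - xc)^2 <= r^2
  artery <- brain & tube(round(0.28 * H), 3)
  vein <- brain & tube(round(0.78 * H), 3)
  tissue <- brain & !artery & !vein
  # smooth heterogeneity in [0.7, 1.3], even in (x - xc): flip-invariant
  amp <- 1 + 0.3 * cos(2 * pi * (y / H)) * cos(2 * pi * (x - xc) / W) *
    cos(pi * (z - zc) / D)
  list(brain = brain * 1, artery = artery * 1, vein = vein * 1,
       tissue = tissue * 1, amp = amp)
}

#' Generate a synthetic 4D perfusion phantom with exact ground truth
#'
#' Voxel signal is `baseline * (1 - drop_fraction * c(t) / K)` for the
#' voxel's compartment kinetics `c`, plus iid additive Gaussian noise;
#' background (outside the ellipsoidal brain) sits at 5\% of baseline with
#' no bolus. Returned ground truth is computed from the noiseless series:
#' landmarks by the deterministic detection rules on the analytic ROI
#' curves, and phase maps by windowed temporal maxima of the noiseless
#' subtracted series.
#'
#' @param spec a [phantom_spec()].
#' @return list with `series` (noisy), `series_noiseless`, `roi_mca`,
#'   `roi_sss`, `brain`, `lesion_mask`, `landmarks`, `windows`, `maps`
#'   (exact raw-range [collateral_maps()]).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  Tn <- spec$grid[1]; D <- spec$grid[2]; H <- spec$grid[3]; W <- spec$grid[4]
  times <- (seq_len(Tn) - 1) * spec$dt_seconds
  geo <- phantom_geometry(D, H, W)

  c_art <- gamma_variate_curve(spec$artery, times) / spec$artery$K
  # tissue: bolus plus a small blood-pool steady state (contrast recirculation)
  c_tis <- gamma_variate_curve(spec$capillary, times) / spec$capillary$K +
    0.15 * (1 - exp(-pmax(0, times - spec$capillary$t0) / 10))
  c_tis <- c_tis / max(c_tis)
  # venous curve: bolus + recirculation plateau, then late washout so the
  # plateau ends before the end of the acquisition (non-trivial delay phase)
  t_wash <- spec$vein$t0 + 36
  c_ven <- gamma_variate_curve(spec$vein, times) / spec$vein$K +
    spec$recirc_frac * (1 - exp(-pmax(0, times - spec$vein$t0) / 8))
  c_ven <- c_ven * exp(-pmax(0, times - t_wash) / 6)
  c_ven <- c_ven / max(c_ven)

  lesion_mask <- array(0, c(D, H, W))
  c_les <- NULL
  if (!is.null(spec$lesion)) {
    le <- spec$lesion
    ctr <- le$center
    if (is.null(ctr)) ctr <- c((D + 1) / 2, round(0.5 * H), round(0.3 * W))
    z <- slice.index(lesion_mask, 1); y <- slice.index(lesion_mask, 2)
    x <- slice.index(lesion_mask, 3)
    lesion_mask <- ((z - ctr[1])^2 + (y - ctr[2])^2 + (x - ctr[3])^2 <= le$radius^2) *
      geo$tissue
    gv_les <- gamma_variate(spec$artery$t0 + le$delay_s, spec$artery$alpha,
                            spec$artery$beta, le$amplitude_factor)
    c_les <- gamma_variate_curve(gv_les, times)
  }

  base <- spec$baseline_intensity
  bg <- 0.05 * base
  # concentration field per voxel class, expanded over time
  conc <- matrix(0, Tn, D * H * W)
  classes <- list(list(mask = geo$artery, curve = c_art),
                  list(mask = geo$vein, curve = c_ven),
                  list(mask = geo$tissue * (1 - lesion_mask), curve = c_tis))
  if (!is.null(c_les))
    classes[[length(classes) + 1]] <- list(mask = lesion_mask, curve = c_les)
  for (cl in classes) {
    idx <- which(cl$mask != 0)
    if (length(idx)) conc[, idx] <- cl$curve %o% geo$amp[idx]
  }
  signal <- base * (1 - spec$drop_fraction * conc)
  bg_idx <- which(geo$brain == 0)
  signal[, bg_idx] <- bg
  dim(signal) <- c(Tn, D, H, W)

  series_clean <- perfusion_series(signal, dt_seconds = spec$dt_seconds,
                                   subject_id = sprintf("phantom-%04d", spec$seed),
                                   meta = list(phantom = TRUE, seed = spec$seed))
  noisy <- signal
  if (spec$noise_sigma > 0) {
    rng_state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    noisy <- signal + stats::rnorm(length(signal), sd = spec$noise_sigma)
    if (!is.null(rng_state)) assign(".Random.seed", rng_state, envir = globalenv())
  }
  series <- perfusion_series(noisy, dt_seconds = spec$dt_seconds,
                             subject_id = series_clean$subject_id,
                             meta = series_clean$meta)

  roi_mca <- brain_mask(geo$artery)
  roi_sss <- brain_mask(geo$vein)
  sub_clean <- subtract_baseline(series_clean)
  lm <- detect_landmarks(extract_roi_curve(sub_clean, roi_mca),
                         extract_roi_curve(sub_clean, roi_sss))
  win <- partition_phases(lm, Tn)
  maps <- compose_phase_maps(sub_clean, win)

  list(series = series, series_noiseless = series_clean,
       roi_mca = roi_mca, roi_sss = roi_sss,
       brain = brain_mask(geo$brain), lesion_mask = lesion_mask,
       landmarks = lm, windows = win, maps = maps)
}

#' Generate a phantom cohort of stroke and control subjects
#'
#' Per-subject kinetics are jittered by +/-10\% (uniform) on `t0`, `alpha`
#' and `beta` of every compartment; lesions are present only in stroke
#' subjects; centers alternate between "1" and "2". Deterministic given
#' `seed`.
#'
#' @param n_stroke,n_control subject counts.
#' @param base_spec a [phantom_spec()] providing the unjittered conditions.
#' @param seed integer master seed.
#' @return list of [subject_record()]s with raw-range targets attached.
#' @export
make_cohort <- function(n_stroke, n_control, base_spec = phantom_spec(),
                        seed = 1L) {
  n <- n_stroke + n_control
  if (n == 0) return(list())
  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(rng_state))
    assign(".Random.seed", rng_state, envir = globalenv()))
  set.seed(seed)
  jit <- function(gv) {
    f <- function(v) v * stats::runif(1, 0.9, 1.1)
    gamma_variate(f(gv$t0), f(gv$alpha), f(gv$beta), gv$K)
  }
  out <- vector("list", n)
  groups <- c(rep("stroke", n_stroke), rep("control", n_control))
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$artery <- jit(base_spec$artery)
    sp$capillary <- jit(base_spec$capillary)
    sp$vein <- jit(base_spec$vein)
    vp <- sp$vein$t0 + sp$vein$alpha * sp$vein$beta
    ap <- sp$artery$t0 + sp$artery$alpha * sp$artery$beta
    if (vp <= ap + 2) sp$vein$t0 <- sp$vein$t0 + (ap + 2 - vp) + 0.5
    sp$lesion <- if (groups[i] == "stroke") phantom_lesion() else NULL
    sp$seed <- as.integer(seed * 1000L + i)
    ph <- make_phantom(sp)
    out[[i]] <- subject_record(ph$series, mask = ph$brain,
                               targets = ph$maps, group = groups[i],
                               center = as.character(1L + (i %% 2L)))
  }
  out
}
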