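# Domain types for 4D perfusion series and five-phase collateral map sets,
# plus NIfTI/DICOM readers and writers.
#
# Axis convention, used by every module in the package: series arrays are
# indexed (t, z, y, x) -- time first and fastest -- and map sets are indexed
# (phase, z, y, x). Voxel indices are 0-based wherever they appear in public
# fields (temporal index 0 is the first, pre-contrast frame).

PHASE_NAMES <- c("Art", "Cap", "EVen", "LVen", "Del")

#' Construct a 4D perfusion series
#'
#' @param data numeric 4D array indexed `(t, z, y, x)`.
#' @param dt_seconds temporal resolution in seconds (canonical 1.6).
#' @param subject_id subject identifier.
#' @param meta free-form named list of provenance.
#' @return object of class `perfusion_series`.
#' @export
perfusion_series <- function(data, dt_seconds = 1.6, subject_id = "", meta = list()) {
  d <- dim(data)
  if (length(d) != 4) stop("expected 4D series (t, z, y, x), got ",
                           length(d), " dimensions")
  if (d[1] < 2) stop("need at least 2 time points")
  if (!all(is.finite(data))) stop("series contains non-finite voxels")
  if (!is.numeric(dt_seconds) || dt_seconds <= 0) stop("dt_seconds must be > 0")
  structure(list(data = data, t_count = d[1], z_count = d[2],
                 spatial = d[3:4], dt_seconds = dt_seconds,
                 subject_id = subject_id, meta = meta),
            class = "perfusion_series")
}

#' @export
print.perfusion_series <- function(x, ...) {
  cat(sprintf("<perfusion_series> %s: %d time points x %d slices x %d x %d, dt = %gs\n",
              if (nzchar(x$subject_id)) x$subject_id else "(unnamed)",
              x$t_count, x$z_count, x$spatial[1], x$spatial[2], x$dt_seconds))
  invisible(x)
}

#' Construct a binary brain mask
#' @param mask binary/logical 3D array indexed `(z, y, x)`.
#' @return object of class `brain_mask`.
#' @export
brain_mask <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3) stop("expected 3D mask (z, y, x)")
  m <- array(as.numeric(mask != 0), d)
  structure(list(mask = m), class = "brain_mask")
}

#' Construct a five-phase collateral map set
#'
#' Phase channels are always ordered Art, Cap, EVen, LVen, Del.
#'
#' @param maps numeric 4D array indexed `(phase, z, y, x)` with 5 phases.
#' @param value_range one of `"raw"`, `"unit"` (values in `[0, 1]`) or
#'   `"target"` (values in `[-0.9, 0.9]`).
#' @return object of class `collateral_maps`.
#' @export
collateral_maps <- function(maps, value_range = c("raw", "unit", "target")) {
  value_range <- match.arg(value_range)
  d <- dim(maps)
  if (length(d) != 4 || d[1] != 5)
    stop("expected exactly 5 phase channels (phase, z, y, x), got ",
         if (length(d) == 4) d[1] else "wrong rank")
  if (!all(is.finite(maps))) stop("maps contain non-finite values")
  # the range invariant applies after normalization; "unit" maps may carry
  # outliers beyond [0, 1] that normalize_targets() clips, and "target" maps
  # may be network predictions living in the Tanh codomain (-1, 1)
  if (value_range == "target") {
    lo <- min(maps); hi <- max(maps)
    if (lo < -1 - 1e-9 || hi > 1 + 1e-9)
      stop(sprintf("values [%g, %g] outside the target codomain [-1, 1]",
                   lo, hi))
  }
  structure(list(maps = maps, value_range = value_range,
                 phases = PHASE_NAMES), class = "collateral_maps")
}

#' @export
print.collateral_maps <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<collateral_maps> 5 phases (%s) x %d x %d x %d, range '%s'\n",
              paste(x$phases, collapse = ","), d[2], d[3], d[4], x$value_range))
  invisible(x)
}

#' Bundle a subject's series, mask and targets
#'
#' @param series a [perfusion_series()].
#' @param mask a [brain_mask()] (optional; derived later if `NULL`).
#' @param targets a [collateral_maps()] or `NULL`.
#' @param group `"stroke"` or `"control"`.
#' @param center acquisition-center identifier.
#' @return object of class `subject_record`.
#' @export
subject_record <- function(series, mask = NULL, targets = NULL,
                           group = c("stroke", "control"), center = "1") {
  group <- match.arg(group)
  stopifnot(inherits(series, "perfusion_series"))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "brain_mask"))
    if (!all(dim(mask$mask) == c(series$z_count, series$spatial)))
      stop("mask shape inconsistent with series")
  }
  if (!is.null(targets)) {
    stopifnot(inherits(targets, "collateral_maps"))
    if (!all(dim(targets$maps)[2:4] == c(series$z_count, series$spatial)))
      stop("targets shape inconsistent with series")
  }
  structure(list(series = series, mask = mask, targets = targets,
                 group = group, center = center), class = "subject_record")
}

## ---- readers / writers -----------------------------------------------------

#' Read a 4D perfusion series
#'
#' NIfTI files are read natively (axes reordered from the on-disk
#' `(x, y, z, t)` to the package convention `(t, z, y, x)`); DICOM series
#' directories are converted through the environment's `python` + pydicom,
#' ordering instances by (temporal index, slice position).
#'
#' @param path file (NIfTI) or directory (DICOM) path.
#' @param format `"nifti"` or `"dicom_dir"`.
#' @param dt_seconds temporal resolution override; taken from the header
#'   when `NULL` and available.
#' @param subject_id identifier; defaults to the file stem.
#' @return a [perfusion_series()].
#' @export
read_perfusion <- function(path, format = c("nifti", "dicom_dir"),
                           dt_seconds = NULL, subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such path: ", path)
  if (format == "dicom_dir") {
    tmp <- tempfile(fileext = ".nii.gz")
    on.exit(unlink(tmp), add = TRUE)
    script <- system.file("python", "dicom_to_nifti.py", package = "collmapnet")
    status <- system2("python", c(script, shQuote(path), shQuote(tmp)),
                      stdout = TRUE, stderr = TRUE)
    if (!file.exists(tmp))
      stop("DICOM conversion failed: ", paste(status, collapse = "\n"))
    path <- tmp
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) stop("expected 4D series, got ", length(d), "D image")
  arr <- aperm(as.array(img), c(4, 3, 2, 1))
  if (is.null(dt_seconds)) {
    pd <- RNifti::pixdim(img)
    dt_seconds <- if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) pd[4] else 1.6
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  perfusion_series(arr, dt_seconds = dt_seconds, subject_id = subject_id,
                   meta = list(source = path, format = format))
}

#' Write a perfusion series as 4D NIfTI
#' @param series a [perfusion_series()].
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_perfusion <- function(series, path) {
  stopifnot(inherits(series, "perfusion_series"))
  arr <- aperm(series$data, c(4, 3, 2, 1))
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  pd[4] <- series$dt_seconds
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a five-phase collateral map set as 4D NIfTI plus JSON sidecar
#'
#' The five volumes are stored in the fixed phase order Art, Cap, EVen,
#' LVen, Del; the sidecar records the phase names and declared value range.
#'
#' @param maps a [collateral_maps()].
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_maps <- function(maps, path) {
  stopifnot(inherits(maps, "collateral_maps"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  arr <- aperm(maps$maps, c(4, 3, 2, 1))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(phases = maps$phases,
                            value_range = maps$value_range),
                       sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a five-phase collateral map set written by [write_maps()]
#' @param path `.nii`/`.nii.gz` path with adjacent `.json` sidecar.
#' @return a [collateral_maps()].
#' @export
read_maps <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) stop("expected 4D map file")
  arr <- aperm(as.array(img), c(4, 3, 2, 1))
  value_range <- "raw"
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(as.character(sc$phases), PHASE_NAMES))
      stop("sidecar phase order differs from Art,Cap,EVen,LVen,Del")
    value_range <- sc$value_range
  }
  collateral_maps(arr, value_range = value_range)
}

#' Validate the shape and finiteness of a perfusion series
#'
#' @param series a [perfusion_series()].
#' @param expect integer pair `(T, D)`: expected time points and slices.
#' @return invisibly `TRUE`; otherwise an error naming the offending axis.
#' @export
validate_series <- function(series, expect = c(40L, 20L)) {
  stopifnot(inherits(series, "perfusion_series"))
  if (series$t_count != expect[1])
    stop(sprintf("time axis: expected %d time points, got %d",
                 expect[1], series$t_count))
  if (series$z_count != expect[2])
    stop(sprintf("slice axis: expected %d slices, got %d",
                 expect[2], series$z_count))
  if (!all(is.finite(series$data)))
    stop("series contains non-finite voxels")
  invisible(TRUE)
}
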