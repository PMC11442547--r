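test_that("series write/read round-trip preserves data and dt", {
  s <- rand_series(Tn = 8, D = 3, H = 12, W = 12, dt = 1.6)
  f <- tempfile(fileext = ".nii.gz")
  write_perfusion(s, f)
  s2 <- read_perfusion(f)
  expect_equal(dim(s2$data), dim(s$data))
  expect_equal(s2$data, s$data, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(s2$dt_seconds, 1.6, tolerance = 1e-6)
  unlink(f)
})

test_that("non-4D images and bad constructions are rejected", {
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(5, 5, 5))), f)
  expect_error(read_perfusion(f), "expected 4D")
  unlink(f)
  expect_error(read_perfusion(tempfile()), "no such path")
  expect_error(perfusion_series(array(1, c(3, 3, 3))), "4D")
  expect_error(perfusion_series(array(NA_real_, c(2, 2, 2, 2))), "finite")
  expect_error(perfusion_series(array(1, c(1, 2, 2, 2))), "2 time points")
})

test_that("map sets enforce the five-phase contract and round-trip", {
  expect_error(collateral_maps(array(0, c(4, 2, 4, 4))), "5 phase")
  m <- rand_maps(D = 3, H = 8, W = 8)
  f <- tempfile(fileext = ".nii.gz")
  write_maps(m, f)
  sidecar <- sub("\\.nii\\.gz$", ".json", f)
  expect_true(file.exists(sidecar))
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  expect_identical(as.character(sc$phases), c("Art", "Cap", "EVen", "LVen", "Del"))
  m2 <- read_maps(f)
  expect_equal(m2$maps, m$maps, tolerance = 1e-7, ignore_attr = TRUE)
  expect_identical(m2$value_range, "raw")
  unlink(c(f, sidecar))
})

test_that("phase order on disk follows the fixed Art..Del convention", {
  # channel i carries constant value i: after write/read the order must hold
  arr <- array(rep(1:5, times = 2 * 4 * 4), c(5, 2, 4, 4))
  m <- collateral_maps(arr, "raw")
  f <- tempfile(fileext = ".nii.gz")
  write_maps(m, f)
  img <- as.array(RNifti::readNifti(f))    # (x, y, z, phase)
  for (i in 1:5) expect_true(all(img[, , , i] == i))
  unlink(c(f, sub("\\.nii\\.gz$", ".json", f)))
})

test_that("validate_series names the offending axis", {
  s <- rand_series(Tn = 5, D = 3)
  expect_silent(validate_series(s, expect = c(5L, 3L)))
  expect_error(validate_series(s, expect = c(6L, 3L)), "time axis")
  expect_error(validate_series(s, expect = c(5L, 4L)), "slice axis")
  s$data[1] <- NaN
  expect_error(validate_series(s, expect = c(5L, 3L)), "non-finite")
})

test_that("DICOM series directories are read with (t, z) ordering", {
  dcmdir <- tempfile("dcm")
  dir.create(dcmdir)
  Tn <- 3L; Z <- 2L
  # build Tn*Z instances with pydicom; voxel values encode (t, z)
  script <- sprintf('
import numpy as np, pydicom, os
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
outdir = %s
for t in range(%d):
    for z in range(%d):
        meta = FileMetaDataset()
        meta.MediaStorageSOPClassUID = pydicom.uid.MRImageStorage
        meta.MediaStorageSOPInstanceUID = generate_uid()
        meta.TransferSyntaxUID = ExplicitVRLittleEndian
        ds = Dataset()
        ds.file_meta = meta
        ds.SOPClassUID = meta.MediaStorageSOPClassUID
        ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
        ds.Rows = 4; ds.Columns = 4
        ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
        ds.PixelRepresentation = 0
        ds.SamplesPerPixel = 1
        ds.PhotometricInterpretation = "MONOCHROME2"
        ds.TemporalPositionIdentifier = t + 1
        ds.InstanceNumber = t * %d + z + 1
        ds.ImagePositionPatient = [0, 0, float(z * 5)]
        ds.RepetitionTime = 1600
        arr = np.full((4, 4), 100 * (t + 1) + z, dtype=np.uint16)
        ds.PixelData = arr.tobytes()
        ds.is_little_endian = True; ds.is_implicit_VR = False
        pydicom.dcmwrite(os.path.join(outdir, "i%%03d.dcm" %% ds.InstanceNumber),
                         ds, write_like_original=False)
', deparse(dcmdir), Tn, Z, Z)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  res <- system2("python", sf, stdout = TRUE, stderr = TRUE)
  expect_true(length(list.files(dcmdir)) == Tn * Z)
  s <- read_perfusion(dcmdir, format = "dicom_dir")
  # oracle: count instances and group by temporal index
  expect_equal(dim(s$data), c(Tn, Z, 4L, 4L))
  for (t in seq_len(Tn)) for (z in seq_len(Z))
    expect_true(all(s$data[t, z, , ] == 100 * t + (z - 1)))
  expect_equal(s$dt_seconds, 1.6, tolerance = 1e-6)
  unlink(dcmdir, recursive = TRUE)
})
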