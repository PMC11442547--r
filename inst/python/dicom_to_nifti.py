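"""Convert a directory of DSC-MRP DICOM slices to a 4D NIfTI volume.

Instances are grouped into time points by TemporalPositionIdentifier (or
AcquisitionNumber as fallback) and ordered within a time point by slice
position (ImagePositionPatient z, or InstanceNumber as fallback). The output
axes are (x, y, z, t) as usual for NIfTI; the R reader permutes to its own
(t, z, y, x) convention.
"""
import sys

import numpy as np
import nibabel as nib
import pydicom


def sort_keys(ds):
    t = getattr(ds, "TemporalPositionIdentifier", None)
    if t is None:
        t = getattr(ds, "AcquisitionNumber", 0)
    pos = getattr(ds, "ImagePositionPatient", None)
    z = float(pos[2]) if pos is not None else float(getattr(ds, "InstanceNumber", 0))
    return int(t), z


def main(indir, outpath):
    import os

    files = [os.path.join(indir, f) for f in sorted(os.listdir(indir))]
    dsets = [pydicom.dcmread(f) for f in files if os.path.isfile(f)]
    if not dsets:
        raise SystemExit("no DICOM instances found in " + indir)
    keyed = sorted(((sort_keys(ds), ds) for ds in dsets), key=lambda kv: kv[0])
    tvals = sorted({k[0] for k, _ in keyed})
    nz = len(keyed) // len(tvals)
    if nz * len(tvals) != len(keyed):
        raise SystemExit("inconsistent slice count across time points")
    rows, cols = keyed[0][1].Rows, keyed[0][1].Columns
    vol = np.zeros((cols, rows, nz, len(tvals)), dtype=np.float64)
    for i, (_, ds) in enumerate(keyed):
        t, z = divmod(i, nz)
        vol[:, :, z, t] = ds.pixel_array.astype(np.float64).T
    dt = float(getattr(keyed[0][1], "RepetitionTime", 1600.0)) / 1000.0
    img = nib.Nifti1Image(vol, np.eye(4))
    img.header["pixdim"][4] = dt
    nib.save(img, outpath)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
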