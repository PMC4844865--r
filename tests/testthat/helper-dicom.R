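# Writes a small DICOM fixture at test time with pydicom (through the system
# python), serving as an independent reference for the package's reader.
# Binary fixtures are never stored in the repository.
write_reference_dicom <- function(path, rows = 20, cols = 30,
                                  spacing = c(0.14, 0.14), bits = 8) {
  script <- sprintf('
import numpy as np
import pydicom
from pydicom.dataset import FileDataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

rows, cols, bits = %d, %d, %d
meta = FileMetaDataset()
meta.MediaStorageSOPClassUID = "1.2.840.10008.5.1.4.1.1.6.1"
meta.MediaStorageSOPInstanceUID = generate_uid()
meta.TransferSyntaxUID = ExplicitVRLittleEndian
ds = FileDataset(r"%s", {}, file_meta=meta, preamble=b"\\x00" * 128)
ds.SOPClassUID = meta.MediaStorageSOPClassUID
ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
ds.Modality = "US"
ds.Rows = rows
ds.Columns = cols
ds.PixelSpacing = [%f, %f]
ds.SamplesPerPixel = 1
ds.PhotometricInterpretation = "MONOCHROME2"
ds.BitsAllocated = bits
ds.BitsStored = bits
ds.HighBit = bits - 1
ds.PixelRepresentation = 0
arr = (np.arange(rows * cols) %% 251).astype(np.uint8 if bits == 8 else np.uint16)
if bits == 16:
    arr = arr * 17
ds.PixelData = arr.tobytes()
ds.save_as(r"%s", enforce_file_format=True)
', rows, cols, bits, path, spacing[1], spacing[2], path)
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  status <- system2("python", f, stdout = TRUE, stderr = TRUE)
  if (!file.exists(path)) {
    stop("reference DICOM writer failed: ", paste(status, collapse = "\n"))
  }
  invisible(path)
}
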