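test_that("NIfTI write/load roundtrip preserves grid, spacing and frame", {
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  set.seed(3)
  v <- image_volume(array(rnorm(10 * 10 * 10), c(10, 10, 10)),
                    spacing = c(0.5, 0.5, 2.4), laterality = "right",
                    origin = c(-2, 1, 4))
  write_volume(v, tmp)
  r <- load_volume(tmp, "right")
  expect_equal(r$grid, v$grid, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-4)
  # determinism of orientation resolution
  r2 <- load_volume(tmp, "right")
  expect_identical(r$grid, r2$grid)
})

test_that("a saved phantom reloads voxel-for-voxel", {
  ph <- ref_phantom()
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, tmp)
  r <- load_volume(tmp, "right")
  expect_equal(as.vector(r$grid), as.vector(ph$volume$grid), tolerance = 1e-6)
})

test_that("left-knee volumes are mirrored into the canonical frame", {
  ph <- ref_phantom()
  left <- ph$volume
  left$laterality <- "left"
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(left, tmp)   # written in the subject's own (mirrored) frame
  back <- load_volume(tmp, "left")
  expect_equal(as.vector(back$grid), as.vector(ph$volume$grid),
               tolerance = 1e-6)
  # loading the same file as a right knee flips the ML axis instead
  asright <- load_volume(tmp, "right")
  n <- dim(asright$grid)[2]
  expect_equal(as.vector(asright$grid[, n:1, ]),
               as.vector(ph$volume$grid), tolerance = 1e-6)
})

test_that("volumes without orientation metadata are rejected", {
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(1, c(4, 4, 4)))
  RNifti::qform(img) <- structure(diag(4) * 0, code = 0L)
  RNifti::sform(img) <- structure(diag(4) * 0, code = 0L)
  RNifti::writeNifti(img, tmp)
  expect_error(load_volume(tmp, "right"), "orientation")
  expect_error(load_volume(file.path(tempdir(), "nope.nii"), "right"),
               "no such file")
})

test_that("a DICOM series with 1.6 mm slices and 0.8 mm gap loads at 2.4 mm", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  dir <- withr::local_tempdir()
  script <- sprintf('
import numpy as np, pydicom, os
from pydicom.dataset import Dataset, FileDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
series = generate_uid(); study = generate_uid(); frame = generate_uid()
for i in range(6):
    ds = FileDataset(None, {}, file_meta=None, preamble=b"\\0"*128)
    ds.file_meta = pydicom.dataset.FileMetaDataset()
    ds.file_meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds.file_meta.MediaStorageSOPClassUID = "1.2.840.10008.5.1.4.1.1.4"
    ds.file_meta.MediaStorageSOPInstanceUID = generate_uid()
    ds.SOPClassUID = ds.file_meta.MediaStorageSOPClassUID
    ds.SOPInstanceUID = ds.file_meta.MediaStorageSOPInstanceUID
    ds.StudyInstanceUID = study; ds.SeriesInstanceUID = series
    ds.FrameOfReferenceUID = frame
    ds.Modality = "MR"; ds.PatientName = "phantom"; ds.PatientID = "0"
    ds.Rows = 16; ds.Columns = 16
    ds.PixelSpacing = [0.5, 0.5]
    ds.SliceThickness = 1.6
    ds.SpacingBetweenSlices = 2.4
    ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]
    ds.ImagePositionPatient = [0, 0, round(2.4 * i, 6)]
    ds.InstanceNumber = i + 1
    ds.SamplesPerPixel = 1; ds.PhotometricInterpretation = "MONOCHROME2"
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 0
    ds.PixelData = (np.ones((16, 16), dtype=np.uint16) * (100 + i)).tobytes()
    ds.save_as(os.path.join("%s", "slice%%03d.dcm" %% i), write_like_original=False)
', dir)
  res <- suppressWarnings(system2(py, c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = TRUE))
  expect_true(is.null(attr(res, "status")) || attr(res, "status") == 0,
              label = paste("DICOM fixture generation:",
                            paste(res, collapse = " ")))
  vol <- load_volume(dir, "right")
  # slice-centre spacing must be thickness + gap, from the series geometry
  expect_true(any(abs(vol$spacing - 2.4) < 1e-6))
  expect_equal(sort(vol$spacing), c(0.5, 0.5, 2.4), tolerance = 1e-6)
})

test_that("reports round-trip samples and refuse empty input", {
  m <- ref_measurement()
  sm <- summarize_subject(m, subject_id = "S1", sex = "F")
  out <- withr::local_tempdir()
  files <- write_report(sm, tidy(m), out)
  got <- utils::read.csv(files[["samples"]])
  expect_equal(nrow(got), nrow(m$samples))
  js <- jsonlite::read_json(files[["summary"]])
  lat <- sm[sm$compartment == "lateral", ]
  expect_equal(js$compartments$lateral$mean_deg, lat$mean_deg,
               tolerance = 1e-12)
  expect_identical(js$subject_id, "S1")
  # empty sample list: error, and no partial files
  out2 <- file.path(out, "empty")
  expect_error(write_report(sm, m$samples[0, ], out2), "No slope samples")
  expect_false(dir.exists(out2))
})
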