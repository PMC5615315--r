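#' Load an MRI volume
#'
#' Reads a NIfTI file or a DICOM series directory into the package's
#' canonical anatomical frame (axes anterior / medial / superior, mm at voxel
#' centres). The image is reoriented from whatever orientation its spatial
#' metadata declares; left knees are mirrored about the sagittal midplane so
#' that compartment labels (medial / lateral) are uniform across sides.
#' Laterality is a required input: it cannot be inferred reliably from a
#' cropped proximal-tibia scan.
#'
#' @param path A `.nii`/`.nii.gz` file, or a directory containing one DICOM
#'   series (read through SimpleITK, which must be importable by the
#'   `python` on the search path).
#' @param laterality `"left"` or `"right"`.
#' @return An [image_volume].
#' @seealso [load_mask()], [write_volume()]
#' @export
load_volume <- function(path, laterality) {
  laterality <- match.arg(laterality, c("left", "right"))
  if (dir.exists(path)) {
    nii <- convert_dicom_series(path)
    on.exit(unlink(nii), add = TRUE)
    return(load_volume(nii, laterality))
  }
  if (!file.exists(path))
    abort(sprintf("Cannot read '%s': no such file or directory.", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(sprintf(
                    "Failed to read NIfTI '%s': %s", path, conditionMessage(e))))
  if (length(dim(img)) == 4L && dim(img)[4] == 1L)
    img <- RNifti::asNifti(array(img, dim(img)[1:3]), reference = img)
  if (length(dim(img)) != 3L)
    abort(sprintf("'%s' is not a single 3D volume (dims: %s).", path,
                  paste(dim(img), collapse = "x")))
  hdr <- RNifti::niftiHeader(img)
  if ((hdr$qform_code %||% 0L) == 0L && (hdr$sform_code %||% 0L) == 0L)
    abort(sprintf(paste0("'%s' carries no qform/sform orientation metadata; ",
                         "cannot resolve anatomical axes."), path))
  RNifti::orientation(img) <- "ALS"
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    abort(sprintf("'%s' has non-positive voxel spacing (pixdim: %s).",
                  path, paste(sp, collapse = ", ")))
  xf <- RNifti::xform(img)
  t0 <- as.numeric(xf[1:3, 4])          # world position of voxel (0,0,0)
  origin <- c(t0[2], -t0[1], t0[3])     # world RAS -> canonical (A, L, S)
  grid <- as.array(img)
  attributes(grid) <- list(dim = dim(grid))
  vol <- image_volume(grid, spacing = as.numeric(sp),
                      laterality = laterality, origin = origin)
  if (laterality == "left") vol <- mirror_ml(vol)
  vol
}

#' Load a precomputed segmentation mask
#'
#' @param path NIfTI file containing a binary tibia mask.
#' @param reference The [image_volume] the mask belongs to; shape and spacing
#'   are checked against it.
#' @return A [binary_mask].
#' @export
load_mask <- function(path, reference) {
  stopifnot(inherits(reference, "image_volume"))
  vol <- load_volume(path, reference$laterality)
  if (!identical(dim(vol$grid), dim(reference$grid)))
    abort("Mask and volume have different grid shapes.")
  if (max(abs(vol$spacing - reference$spacing)) > 1e-4)
    abort("Mask and volume have different voxel spacings.")
  m <- mask_like(reference, vol$grid != 0)
  if (!any(m$grid)) abort("Mask is empty.")
  m
}

#' Write a volume or mask to NIfTI
#'
#' The file is written in the subject's own frame: canonical left-knee
#' volumes (which are mirrored in memory) are mirrored back so that the file
#' on disk is anatomically faithful, and reloading with [load_volume()] and
#' the same laterality reproduces the in-memory object.
#'
#' @param x An [image_volume] or [binary_mask].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, c("image_volume", "binary_mask")))
  if (x$laterality == "left") x <- mirror_ml(x)
  grid <- if (is.logical(x$grid)) array(as.integer(x$grid), dim(x$grid)) else x$grid
  img <- RNifti::asNifti(grid)
  aff <- matrix(0, 4, 4)
  aff[2, 1] <- x$spacing[1]    # i (anterior) -> world +y
  aff[1, 2] <- -x$spacing[2]   # j (subject-left) -> world -x
  aff[3, 3] <- x$spacing[3]    # k (superior) -> world +z
  aff[1:3, 4] <- c(-x$origin[2], x$origin[1], x$origin[3])
  aff[4, 4] <- 1
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert a DICOM series directory to a temporary NIfTI file
#'
#' Uses SimpleITK through the `python` interpreter on the search path. The
#' series reader derives slice-centre spacing from the slice origins, so a
#' protocol with 1.6 mm slice thickness and 0.8 mm gap yields 2.4 mm.
#' @noRd
convert_dicom_series <- function(dir) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "")
    abort("Reading DICOM series requires a `python` with SimpleITK on PATH.")
  out <- tempfile(fileext = ".nii.gz")
  script <- paste(
    "import sys, SimpleITK as sitk",
    "r = sitk.ImageSeriesReader()",
    "ids = r.GetGDCMSeriesIDs(sys.argv[1])",
    "if not ids: sys.exit('no DICOM series found in ' + sys.argv[1])",
    "if len(ids) > 1: sys.exit('multiple DICOM series in ' + sys.argv[1])",
    "r.SetFileNames(r.GetGDCMSeriesFileNames(sys.argv[1], ids[0]))",
    "sitk.WriteImage(r.Execute(), sys.argv[2])",
    sep = "\n")
  res <- suppressWarnings(system2(py, c("-c", shQuote(script), shQuote(dir),
                                        shQuote(out)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L || !file.exists(out))
    abort(sprintf("DICOM conversion failed: %s", paste(res, collapse = " ")))
  out
}

#' Write per-slice samples and a subject summary to disk
#'
#' Writes `samples.csv` (one row per measured slice: plane, compartment,
#' slice index, normalized distance, signed slope in degrees, node
#' coordinates) and `summary.json` (per-compartment means and SDs over all
#' slices and over concavity-zone slices, plus zone bounds) into `out_dir`.
#'
#' @param summary A [summarize_subject()] result.
#' @param samples Tibble of slope samples, e.g. `tidy()` of a
#'   [measure_profiles()] result.
#' @param out_dir Output directory; created if needed.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(summary, samples, out_dir) {
  stopifnot(is.data.frame(summary), is.data.frame(samples))
  if (nrow(samples) == 0)
    abort("No slope samples to report; refusing to write partial output.")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort(sprintf("Cannot create output directory '%s'.", out_dir))
  csv <- file.path(out_dir, "samples.csv")
  json <- file.path(out_dir, "summary.json")
  utils::write.csv(samples, csv, row.names = FALSE)
  meta <- attributes(summary)[c("subject_id", "sex")]
  payload <- list(
    subject_id = meta$subject_id, sex = meta$sex,
    compartments = lapply(split(summary, summary$compartment), function(r) {
      list(n = r$n, mean_deg = r$mean_deg, sd_deg = r$sd_deg,
           zone = if (is.na(r$zone_lo)) NULL else
             list(lo = r$zone_lo, hi = r$zone_hi, n = r$zone_n,
                  mean_deg = r$zone_mean_deg, sd_deg = r$zone_sd_deg))
    }))
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(samples = csv, summary = json))
}
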