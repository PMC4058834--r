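#' 3D scalar volumes and rectangular regions of interest
#'
#' A `volume` is the package's carrier for every gridded quantity: the CT
#' intensity image, the SUV image derived from PET, the continuous tumor
#' membership field and binary masks. It is a plain 3D numeric array plus
#' voxel spacing in millimetres and a modality tag.
#'
#' Modality tags constrain values: `MEMBERSHIP` volumes must lie in
#' \[0, 1\]; `MASK` volumes must contain only 0 and 1.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3 vector of voxel spacing (mm), all
#'   strictly positive.
#' @param modality One of `"CT"`, `"SUV"`, `"MEMBERSHIP"`, `"MASK"`.
#' @return An object of class `fmrf_volume`.
#' @export
#' @examples
#' v <- new_volume(array(0, c(4, 4, 2)), spacing = c(1, 1, 2), modality = "CT")
#' dim(v$data)
new_volume <- function(data, spacing = c(1, 1, 1), modality = c("CT", "SUV", "MEMBERSHIP", "MASK")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    abort_fmrf("volume data must be a 3D array", "fmrf_error_dimensionality")
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    abort_fmrf("spacing must be 3 strictly positive finite numbers", "fmrf_error_spacing")
  storage.mode(data) <- "double"
  if (modality == "MEMBERSHIP" && (anyNA(data) || any(data < 0 | data > 1)))
    abort_fmrf("MEMBERSHIP volume values must lie in [0, 1]", "fmrf_error_values")
  if (modality == "MASK" && (anyNA(data) || !all(data %in% c(0, 1))))
    abort_fmrf("MASK volume values must be 0 or 1", "fmrf_error_values")
  structure(list(data = data, spacing = as.numeric(spacing), modality = modality),
            class = "fmrf_volume")
}

#' @export
print.fmrf_volume <- function(x, ...) {
  cat(sprintf("<fmrf_volume %s> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

vol_shape <- function(v) dim(v$data)

#' Rectangular region of interest in voxel indices
#'
#' Indices are 0-based and the box is half-open on the upper corner, so a
#' box `(0,0,0)`–`(nx,ny,nz)` covers the whole volume and the extent along
#' each axis is simply `upper - lower`. The paper's algorithm operates on a
#' manually selected region containing the tumor; this type describes that
#' region.
#'
#' @param lower Integer length-3, 0-based lower corner (inclusive).
#' @param upper Integer length-3, 0-based upper corner (exclusive).
#' @return An object of class `fmrf_roi_box`.
#' @export
#' @examples
#' roi_box(c(0, 0, 0), c(2, 2, 1))
roi_box <- function(lower, upper) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  if (length(lower) != 3L || length(upper) != 3L || anyNA(lower) || anyNA(upper))
    abort_fmrf("roi_box corners must be integer vectors of length 3", "fmrf_error_roi")
  if (any(lower < 0) || any(upper <= lower))
    abort_fmrf("roi_box requires 0 <= lower < upper componentwise", "fmrf_error_roi")
  structure(list(lower = lower, upper = upper), class = "fmrf_roi_box")
}

roi_extent <- function(box) box$upper - box$lower

check_roi_in_volume <- function(box, shape) {
  if (any(box$upper > shape))
    abort_fmrf(sprintf("roi_box upper corner (%s) exceeds volume shape (%s)",
                       paste(box$upper, collapse = ","),
                       paste(shape, collapse = ",")),
               "fmrf_error_roi_bounds")
  invisible(NULL)
}

infer_modality <- function(path) {
  f <- tolower(basename(path))
  if (grepl("suv|pet", f)) return("SUV")
  if (grepl("member", f)) return("MEMBERSHIP")
  if (grepl("mask|truth|gtv", f)) return("MASK")
  if (grepl("ct", f)) return("CT")
  NA_character_
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path Path to a single-channel 3D NIfTI file (`.nii` / `.nii.gz`).
#' @param modality Optional modality tag; if `NULL` it is inferred from the
#'   filename (`ct`, `suv`/`pet`, `mask`/`truth`/`gtv`, `member`).
#' @return An [new_volume()] object with data and voxel spacing populated.
#' @export
read_volume <- function(path, modality = NULL) {
  if (!file.exists(path) || dir.exists(path))
    abort_fmrf(sprintf("file not found: %s", path), "fmrf_error_missing_file")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort_fmrf(
                    sprintf("unreadable image format: %s (%s)", path, conditionMessage(e)),
                    "fmrf_error_format"))
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    abort_fmrf(sprintf("expected a 3D image, got %s dimension(s): %s",
                       length(d), paste(d, collapse = "x")),
               "fmrf_error_dimensionality")
  if (is.null(modality)) {
    modality <- infer_modality(path)
    if (is.na(modality))
      abort_fmrf(sprintf("cannot infer modality from filename '%s'; pass modality=",
                         basename(path)), "fmrf_error_modality")
  }
  new_volume(array(as.numeric(img), dim = d),
             spacing = as.numeric(RNifti::pixdim(img))[1:3],
             modality = modality)
}

#' Write a volume to a NIfTI file
#'
#' Data and spacing round-trip bit-compatibly through [read_volume()].
#' Masks are stored as unsigned 8-bit integers, everything else as double.
#'
#' @param volume An [new_volume()] object.
#' @param path Output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "fmrf_volume"))
  if (dir.exists(path) || !dir.exists(dirname(path)))
    abort_fmrf(sprintf("unwritable path: %s", path), "fmrf_error_unwritable")
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  dtype <- if (volume$modality == "MASK") "uint8" else "double"
  tryCatch(RNifti::writeNifti(img, path, datatype = dtype),
           error = function(e) abort_fmrf(
             sprintf("unwritable path: %s (%s)", path, conditionMessage(e)),
             "fmrf_error_unwritable"))
  invisible(path)
}

#' Extract a rectangular ROI from a volume
#'
#' @param volume An [new_volume()] object.
#' @param box An [roi_box()] fully inside the volume.
#' @return A volume of shape `upper - lower` with the same spacing.
#' @export
extract_roi <- function(volume, box) {
  stopifnot(inherits(volume, "fmrf_volume"), inherits(box, "fmrf_roi_box"))
  check_roi_in_volume(box, vol_shape(volume))
  l <- box$lower; u <- box$upper
  sub <- volume$data[(l[1] + 1):u[1], (l[2] + 1):u[2], (l[3] + 1):u[3], drop = FALSE]
  new_volume(sub, spacing = volume$spacing, modality = volume$modality)
}

#' Embed an ROI mask back into the full grid
#'
#' Inverse of [extract_roi()] for reporting the segmented GTV on the
#' original image grid: zeros outside the box, the ROI mask values inside.
#'
#' @param roi_mask A `MASK` volume whose shape equals the box extents.
#' @param box The [roi_box()] the mask was segmented in.
#' @param parent_shape Integer length-3 shape of the full grid.
#' @return A full-size `MASK` volume.
#' @export
embed_mask <- function(roi_mask, box, parent_shape) {
  stopifnot(inherits(roi_mask, "fmrf_volume"), inherits(box, "fmrf_roi_box"))
  parent_shape <- as.integer(parent_shape)
  check_roi_in_volume(box, parent_shape)
  if (!all(vol_shape(roi_mask) == roi_extent(box)))
    abort_fmrf(sprintf("roi_mask shape (%s) does not match box extents (%s)",
                       paste(vol_shape(roi_mask), collapse = "x"),
                       paste(roi_extent(box), collapse = "x")),
               "fmrf_error_shape_mismatch")
  full <- array(0, dim = parent_shape)
  l <- box$lower; u <- box$upper
  full[(l[1] + 1):u[1], (l[2] + 1):u[2], (l[3] + 1):u[3]] <- roi_mask$data
  new_volume(full, spacing = roi_mask$spacing, modality = "MASK")
}

#' Assert that two volumes share the same voxel grid
#'
#' The segmentation consumes externally fused, co-registered PET/CT; this
#' check enforces that contract. Shapes must match exactly, spacings within
#' a relative tolerance of 1e-6.
#'
#' @param a,b Volumes to compare.
#' @return `NULL` invisibly on success; otherwise a classed error naming
#'   the differing attribute.
#' @export
check_same_grid <- function(a, b) {
  stopifnot(inherits(a, "fmrf_volume"), inherits(b, "fmrf_volume"))
  if (!all(vol_shape(a) == vol_shape(b)))
    abort_fmrf(sprintf("grid mismatch in shape: %s vs %s",
                       paste(vol_shape(a), collapse = "x"),
                       paste(vol_shape(b), collapse = "x")),
               "fmrf_error_grid_mismatch")
  rel <- abs(a$spacing - b$spacing) / pmax(abs(a$spacing), abs(b$spacing))
  if (any(rel > 1e-6))
    abort_fmrf(sprintf("grid mismatch in spacing: (%s) vs (%s)",
                       paste(a$spacing, collapse = ","),
                       paste(b$spacing, collapse = ",")),
               "fmrf_error_grid_mismatch")
  invisible(NULL)
}
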