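# Core containers: 3D scalar volumes with physical metadata, integer label
# masks aligned to them, and per-patient acquisition metadata.
#
# Arrays are indexed (slice, row, col); spacing is mm per axis in the same
# order.  All thresholds elsewhere in the package are applied in physical
# units (HU or SUV), never in raw stored values.

VOLUME_UNITS <- c("HU", "Bq/mL", "SUV", "dimensionless")

#' Construct a 3D scalar volume
#'
#' A `volume3d` is the package's basic image container: a numeric 3D array
#' indexed `(slice, row, col)` together with the voxel spacing in mm, a
#' physical-unit tag, and a voxel-to-world affine (RAS convention).
#'
#' @param data numeric 3D array, indexed `(slice, row, col)`.
#' @param spacing numeric length-3, mm per axis (slice, row, col). All > 0.
#' @param unit one of `"HU"`, `"Bq/mL"`, `"SUV"`, `"dimensionless"`.
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(spacing)`.
#' @return An object of class `volume3d` with elements `data`, `spacing`,
#'   `unit`, `affine`.
#' @examples
#' v <- volume3d(array(0, c(4, 8, 8)), spacing = c(5, 1, 1), unit = "HU")
#' dim(v$data)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), unit = "dimensionless",
                     affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (slice, row, col)")
  if (!all(is.finite(data)))
    stop("volume3d data must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  unit <- match.arg(unit, VOLUME_UNITS)
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(data = data, spacing = spacing, unit = unit,
                 affine = affine),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels (slice,row,col), spacing %s mm, unit %s\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              x$unit))
  cat(sprintf("  range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a region mask aligned to a volume
#'
#' Integer label volume on the same grid as a [volume3d()]. Binary masks use
#' labels 0/1; bone masks use 0 = background, 1 = marrow, 2 = cortex
#' (see [MASK_LABELS]).
#'
#' @param labels integer 3D array of labels (non-negative).
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return An object of class `region_mask` with elements `labels`, `spacing`.
#' @export
region_mask <- function(labels, spacing = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  structure(list(labels = labels, spacing = spacing), class = "region_mask")
}

#' Label conventions for bone masks
#'
#' Named integer vector mapping region names to label values used in
#' cortex/marrow masks: background 0, marrow 1, cortex 2.
#' @export
MASK_LABELS <- c(background = 0L, marrow = 1L, cortex = 2L)

#' @export
print.region_mask <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(x$labels)
  cat(sprintf("<region_mask> %d x %d x %d voxels; labels: %s\n",
              d[1], d[2], d[3],
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Per-patient acquisition metadata
#'
#' Holds the quantities entering SUV normalization: injected tracer dose,
#' body weight, body height and sex.
#'
#' @param injected_dose_MBq injected FDG activity, MBq (> 0).
#' @param body_weight_kg body weight, kg (> 0).
#' @param body_height_cm body height, cm (> 0).
#' @param sex `"female"` or `"male"`.
#' @param id opaque patient identifier string.
#' @return An object of class `patient_meta`.
#' @examples
#' patient_meta(370, 70, 170, "female", id = "P001")
#' @export
patient_meta <- function(injected_dose_MBq, body_weight_kg, body_height_cm,
                         sex = c("female", "male"), id = "anonymous") {
  if (!is.numeric(injected_dose_MBq) || injected_dose_MBq <= 0)
    stop("injected dose must be > 0 MBq")
  if (!is.numeric(body_weight_kg) || body_weight_kg <= 0)
    stop("body weight must be > 0 kg")
  if (!is.numeric(body_height_cm) || body_height_cm <= 0)
    stop("body height must be > 0 cm")
  sex <- match.arg(sex)
  structure(list(injected_dose_MBq = as.numeric(injected_dose_MBq),
                 body_weight_kg = as.numeric(body_weight_kg),
                 body_height_cm = as.numeric(body_height_cm),
                 sex = sex, id = as.character(id)),
            class = "patient_meta")
}

#' @export
print.patient_meta <- function(x, ...) {
  cat(sprintf("<patient_meta> %s: %s, %g kg, %g cm, dose %g MBq\n",
              x$id, x$sex, x$body_weight_kg, x$body_height_cm,
              x$injected_dose_MBq))
  invisible(x)
}

# ---- NIfTI I/O --------------------------------------------------------------

#' Write a volume or mask to NIfTI
#'
#' Volumes are written as `.nii.gz` with voxel spacing in the NIfTI pixdim.
#' The unit tag is stored in a JSON sidecar `<path minus .nii.gz>.json`
#' because NIfTI has no standard slot for HU/Bq-mL declarations.
#'
#' @param x a [volume3d()] or [region_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "region_mask")) {
    arr <- x$labels
    unit <- "dimensionless"
    spacing <- x$spacing
  } else if (inherits(x, "volume3d")) {
    arr <- x$data
    unit <- x$unit
    spacing <- x$spacing
  } else stop("`x` must be a volume3d or region_mask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(unit = unit, spacing = spacing,
                            axis_order = "slice,row,col"),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file written by [write_volume()] (or any NIfTI
#' with compatible axis order). The physical unit is taken from the JSON
#' sidecar when present, otherwise from `unit`, which is then required.
#'
#' @param path NIfTI file path.
#' @param unit fallback unit tag when no sidecar exists.
#' @return A [volume3d()].
#' @export
read_volume <- function(path, unit = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    unit <- meta$unit
  } else if (is.null(unit)) {
    stop(sprintf("no unit sidecar for %s and no `unit` given; declare HU, Bq/mL, SUV or dimensionless",
                 path))
  }
  arr <- array(as.numeric(img), dim = dim(img))
  volume3d(arr, spacing = spacing, unit = unit)
}

#' Read a label mask from NIfTI
#'
#' @param path NIfTI file path holding integer labels.
#' @return A [region_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path, unit = "dimensionless")
  region_mask(array(as.integer(round(v$data)), dim(v$data)),
              spacing = v$spacing)
}

#' Read patient metadata from a JSON sidecar
#'
#' Reads the `meta.json` written by [write_phantom_case()] (fields
#' `injected_dose_MBq`, `body_weight_kg`, `body_height_cm`, `sex`, `id`).
#'
#' @param path JSON file path.
#' @return A [patient_meta()].
#' @export
read_patient_meta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  patient_meta(m$injected_dose_MBq, m$body_weight_kg, m$body_height_cm,
               m$sex, id = if (is.null(m$id)) "anonymous" else m$id)
}

#' Check that two grids match
#'
#' Internal guard used by every operation pairing a volume with a mask or a
#' second volume.
#' @noRd
check_same_grid <- function(a, b, what = "inputs") {
  da <- if (inherits(a, "region_mask")) dim(a$labels) else dim(a$data)
  db <- if (inherits(b, "region_mask")) dim(b$labels) else dim(b$data)
  if (!identical(da, db))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}

#' Check that two affines agree to tolerance
#' @noRd
check_coregistered <- function(a, b, tol = 1e-3) {
  if (max(abs(a$affine - b$affine)) > tol) {
    stop(sprintf(
      "CT and PET affines differ beyond tolerance %g; volumes are not co-registered.\nA:\n%s\nB:\n%s",
      tol, paste(capture.output(print(a$affine)), collapse = "\n"),
      paste(capture.output(print(b$affine)), collapse = "\n")))
  }
  invisible(TRUE)
}
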