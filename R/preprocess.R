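# PET-to-CT grid upsampling and PET-guided bed removal.
#
# The scanner bed absorbs X-rays and contaminates CT quantification, but it
# never appears in PET.  A smoothed, thresholded PET therefore yields a body
# outline that masks the bed out of the CT.  Masked-out voxels are filled
# with air HU rather than zero: 0 HU is water-equivalent and would corrupt
# the fat/muscle histogram that downstream auto-thresholding fits.

#' Bed-removal parameters
#'
#' @param smooth_sigma Gaussian smoothing width in voxels applied to the PET
#'   before thresholding (a comparatively large kernel).
#' @param body_threshold_mode `"fraction_of_max"` (threshold =
#'   `fraction` x smoothed maximum) or `"otsu"`.
#' @param fraction threshold as a fraction of the smoothed maximum, in (0,1).
#' @param fill_holes fill enclosed holes in each axial slice of the mask.
#' @param keep_largest_component keep only the largest 6-connected
#'   component (drops stray noise blobs).
#' @param trim_to_support also require the raw (unsmoothed) PET to exceed
#'   the threshold, so the smoothing kernel's spill-over beyond the body
#'   outline is trimmed back; hole filling restores noise pinholes this
#'   opens inside the body.
#' @param background_fill HU written outside the body by [remove_bed()];
#'   defaults to air (-1000).
#' @return An object of class `bed_removal_params`.
#' @export
bed_removal_params <- function(smooth_sigma = 3,
                               body_threshold_mode = c("fraction_of_max",
                                                       "otsu"),
                               fraction = 0.01,
                               fill_holes = TRUE,
                               keep_largest_component = TRUE,
                               trim_to_support = TRUE,
                               background_fill = -1000) {
  body_threshold_mode <- match.arg(body_threshold_mode)
  if (smooth_sigma < 0) stop("smooth_sigma must be >= 0")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  structure(list(smooth_sigma = smooth_sigma,
                 body_threshold_mode = body_threshold_mode,
                 fraction = fraction, fill_holes = fill_holes,
                 keep_largest_component = keep_largest_component,
                 trim_to_support = trim_to_support,
                 background_fill = background_fill),
            class = "bed_removal_params")
}

#' Upsample PET by 3x3 in-plane block replication plus zero padding
#'
#' Each in-plane PET pixel is extended into a 3x3 block with the same value,
#' and the result is zero-padded equally on all four sides to reach
#' `target_inplane` (e.g. a 168x168 PET becomes a 504x504 replication core
#' inside a 512x512 frame with a 4-pixel zero border). Slice count is
#' unchanged and the in-plane voxel spacing is divided by 3.
#'
#' @param pet a [volume3d()] on the native (coarse) PET grid.
#' @param target_inplane target in-plane size (rows = cols), must leave an
#'   even non-negative padding after 3x replication.
#' @return A [volume3d()] of size `(slices, target_inplane, target_inplane)`.
#' @export
upsample_pet_replicate <- function(pet, target_inplane = 512L) {
  stopifnot(inherits(pet, "volume3d"))
  d <- dim(pet$data)
  pad_r <- target_inplane - 3L * d[2]
  pad_c <- target_inplane - 3L * d[3]
  if (pad_r < 0 || pad_c < 0)
    stop("target_inplane smaller than 3x the input; nothing to pad")
  if (pad_r %% 2L != 0L || pad_c %% 2L != 0L)
    stop("padding must be even so the border is symmetric")
  out <- array(0, c(d[1], target_inplane, target_inplane))
  rows <- pad_r / 2L + seq_len(3L * d[2])
  cols <- pad_c / 2L + seq_len(3L * d[3])
  rep_idx_r <- rep(seq_len(d[2]), each = 3L)
  rep_idx_c <- rep(seq_len(d[3]), each = 3L)
  out[, rows, cols] <- pet$data[, rep_idx_r, rep_idx_c, drop = FALSE]
  volume3d(out, spacing = pet$spacing * c(1, 1 / 3, 1 / 3),
           unit = pet$unit, affine = NULL)
}

#' Upsample PET by trilinear interpolation
#'
#' Separable linear interpolation onto a finer grid whose voxel centres
#' span the same physical extent. A constant input stays constant and
#' linear ramps are reproduced at interior voxels.
#'
#' @param pet a [volume3d()].
#' @param target_grid integer length-3 target shape, each axis >= source.
#' @return A [volume3d()] on the target grid with scaled spacing.
#' @export
upsample_pet_trilinear <- function(pet, target_grid) {
  stopifnot(inherits(pet, "volume3d"))
  d <- dim(pet$data)
  target_grid <- as.integer(target_grid)
  if (any(d < 2L))
    stop("cannot interpolate along a degenerate (single-voxel) axis")
  if (any(target_grid < d))
    stop("target grid must be at least as fine as the source on every axis")
  arr <- pet$data
  for (axis in 1:3) {
    if (target_grid[axis] == dim(arr)[axis]) next
    # new voxel centres expressed in source voxel index units, aligned so
    # both grids cover the same physical extent
    scale <- d[axis] / target_grid[axis]
    new <- (seq_len(target_grid[axis]) - 0.5) * scale + 0.5
    arr <- .interp_axis(arr, new, axis)
  }
  volume3d(arr, spacing = pet$spacing * d / target_grid, unit = pet$unit)
}

#' Extract a body mask from the PET volume
#'
#' Smooths the PET with a large Gaussian kernel, thresholds it to separate
#' body from the homogeneous background, and optionally keeps the largest
#' connected component and fills slice-wise holes.
#'
#' @param pet a non-negative [volume3d()].
#' @param params a [bed_removal_params()].
#' @return Binary [region_mask()] (1 = body).
#' @export
body_mask_from_pet <- function(pet, params = bed_removal_params()) {
  stopifnot(inherits(pet, "volume3d"))
  if (min(pet$data) < 0) stop("PET volume must be non-negative")
  sm <- .gauss_smooth3(pet$data, params$smooth_sigma)
  thr <- switch(params$body_threshold_mode,
                fraction_of_max = params$fraction * max(sm),
                otsu = .otsu_values(as.numeric(sm)))
  mask <- sm > thr
  if (!any(mask))
    stop(sprintf("body mask is empty: no smoothed PET voxel exceeds threshold %g",
                 thr))
  if (params$trim_to_support)
    mask <- mask & pet$data > thr
  if (!any(mask))
    stop(sprintf("body mask is empty after support trimming at threshold %g",
                 thr))
  if (params$keep_largest_component)
    mask <- .keep_largest_component3(mask)
  if (params$fill_holes)
    mask <- .fill_holes_slicewise(mask)
  region_mask(array(as.integer(mask), dim(mask)), spacing = pet$spacing)
}

#' Remove the scanner bed from a CT volume
#'
#' Replaces every CT voxel outside the body mask with `background_fill`
#' (air HU by default); voxels inside the body are returned untouched.
#' Applying the operation twice equals applying it once.
#'
#' @param ct a [volume3d()] in HU.
#' @param body binary [region_mask()] from [body_mask_from_pet()].
#' @param background_fill HU value written outside the body.
#' @return A [volume3d()] in HU.
#' @export
remove_bed <- function(ct, body, background_fill = -1000) {
  stopifnot(inherits(ct, "volume3d"), inherits(body, "region_mask"))
  check_same_grid(ct, body, "CT and body mask")
  out <- ct$data
  out[body$labels == 0L] <- background_fill
  volume3d(out, spacing = ct$spacing, unit = ct$unit, affine = ct$affine)
}
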