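# SUV normalization and the PIBGM biomarker.
#
# SUV_bw  = concentration(MBq/mL) / (dose(MBq) / body weight(g))
# SUV_bsa = concentration(MBq/mL) / (dose(MBq) / BSA(m^2))
# SUV_lbm = concentration(MBq/mL) / (dose(MBq) / LBM(kg))
# BSA(m^2) = 0.007184 * weight(kg)^0.425 * height(cm)^0.725
# LBM(kg), female: 1.07 w - 148 (w/h)^2 ; male: 1.1 w - 120 (w/h)^2
#
# PIBGM = N_t / N_b: the fraction of bone voxels whose SUV strictly exceeds
# a predefined cutoff t.  PET voxel values are taken as decay-corrected
# activity concentration as exported by the scanner; no further decay
# correction is applied.

#' Body surface area (Du Bois formula)
#'
#' `BSA = 0.007184 * weight^0.425 * height^0.725` in m^2.
#'
#' @param weight_kg body weight in kg (> 0).
#' @param height_cm body height in cm (> 0).
#' @return BSA in m^2.
#' @examples
#' bsa(70, 170) # ~1.810
#' @export
bsa <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be > 0")
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Lean body mass (James formula)
#'
#' Female: `1.07 w - 148 (w/h)^2`; male: `1.1 w - 120 (w/h)^2`, with `w` in
#' kg and `h` in cm. The formula leaves its validity range (and errors) when
#' the result is non-positive.
#'
#' @param weight_kg body weight in kg (> 0).
#' @param height_cm body height in cm (> 0).
#' @param sex `"female"` or `"male"`.
#' @return LBM in kg.
#' @examples
#' lbm(60, 160, "female") # 43.3875
#' @export
lbm <- function(weight_kg, height_cm, sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be > 0")
  r2 <- (weight_kg / height_cm)^2
  out <- if (sex == "female") 1.07 * weight_kg - 148 * r2
         else                 1.1 * weight_kg - 120 * r2
  if (any(out <= 0))
    stop("lean body mass formula yields a non-positive value; inputs outside its validity range")
  out
}

#' Convert a PET activity volume to an SUV map
#'
#' Voxel activity concentration (Bq/mL) is converted to MBq/mL and divided
#' by injected dose per normalizer: body weight in g (`bw`), body surface
#' area in m^2 (`bsa`), or lean body mass in kg (`lbm`). The result is
#' linear in the PET values and inversely linear in the dose.
#'
#' @param pet a [volume3d()] with unit `"Bq/mL"`.
#' @param meta a [patient_meta()].
#' @param mode one of `"bw"`, `"bsa"`, `"lbm"`.
#' @return An object of class `suv_map`: list with `volume` (a [volume3d()]
#'   tagged `SUV`), `mode` and `meta`.
#' @export
suv_map <- function(pet, meta, mode = c("bw", "bsa", "lbm")) {
  stopifnot(inherits(pet, "volume3d"), inherits(meta, "patient_meta"))
  mode <- match.arg(mode)
  if (pet$unit != "Bq/mL")
    stop(sprintf("PET volume must be in Bq/mL, got %s", pet$unit))
  if (meta$injected_dose_MBq <= 0) stop("injected dose must be > 0")
  normalizer <- switch(mode,
    bw  = meta$body_weight_kg * 1000,                       # g
    bsa = bsa(meta$body_weight_kg, meta$body_height_cm),    # m^2
    lbm = lbm(meta$body_weight_kg, meta$body_height_cm, meta$sex))  # kg
  conc_MBq_mL <- pet$data / 1e6
  suv <- conc_MBq_mL / (meta$injected_dose_MBq / normalizer)
  structure(list(volume = volume3d(suv, spacing = pet$spacing, unit = "SUV",
                                   affine = pet$affine),
                 mode = mode, meta = meta),
            class = "suv_map")
}

#' @export
print.suv_map <- function(x, ...) {
  cat(sprintf("<suv_map> mode=%s, patient %s\n", x$mode, x$meta$id))
  print(x$volume)
  invisible(x)
}

.region_index <- function(mask, region = c("whole_bone", "marrow", "cortex",
                                           "body")) {
  region <- match.arg(region)
  switch(region,
         whole_bone = mask$labels > 0,
         body = mask$labels > 0,
         marrow = mask$labels == MASK_LABELS[["marrow"]],
         cortex = mask$labels == MASK_LABELS[["cortex"]])
}

#' Per-region SUV statistics
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and voxel
#' count of the SUV values in a mask region.
#'
#' @param suv an [suv_map()].
#' @param mask a [region_mask()] on the same grid.
#' @param region `"whole_bone"`, `"marrow"` or `"cortex"`.
#' @return Named list `mean`, `sd`, `n`.
#' @export
region_suv_stats <- function(suv, mask,
                             region = c("whole_bone", "marrow", "cortex")) {
  stopifnot(inherits(suv, "suv_map"), inherits(mask, "region_mask"))
  check_same_grid(suv$volume, mask, "SUV map and mask")
  region <- match.arg(region)
  idx <- .region_index(mask, region)
  if (!any(idx)) stop(sprintf("region '%s' is empty", region))
  vals <- suv$volume$data[idx]
  list(mean = mean(vals),
       sd = if (length(vals) > 1) stats::sd(vals) else 0,
       n = length(vals))
}

#' PET index of bone glucose metabolism
#'
#' `PIBGM = N_t / N_b` with `N_b` the number of bone voxels in the chosen
#' region and `N_t` the number of those with SUV strictly greater than the
#' cutoff `t` (ties at exactly `t` count as normal).
#'
#' @param suv an [suv_map()].
#' @param mask a [region_mask()] on the same grid.
#' @param region `"whole_bone"`, `"marrow"` or `"cortex"`.
#' @param t SUV cutoff (finite).
#' @return An object of class `pibgm_result`: list with `t`, `N_t`, `N_b`,
#'   `value` (= `N_t / N_b`) and `region`.
#' @export
pibgm <- function(suv, mask, region = c("whole_bone", "marrow", "cortex"),
                  t = 1.2) {
  stopifnot(inherits(suv, "suv_map"), inherits(mask, "region_mask"),
            is.finite(t))
  check_same_grid(suv$volume, mask, "SUV map and mask")
  region <- match.arg(region)
  idx <- .region_index(mask, region)
  if (!any(idx)) stop(sprintf("region '%s' is empty", region))
  vals <- suv$volume$data[idx]
  n_b <- length(vals)
  n_t <- sum(vals > t)
  structure(list(t = t, N_t = n_t, N_b = n_b, value = n_t / n_b,
                 region = region),
            class = "pibgm_result")
}

#' @export
print.pibgm_result <- function(x, ...) {
  cat(sprintf("<pibgm> region=%s t=%g: %d / %d = %.4f\n",
              x$region, x$t, x$N_t, x$N_b, x$value))
  invisible(x)
}

#' Default SUV-cutoff grid for PIBGM profiles
#'
#' The cutoffs 0.4 to 2.2 in steps of 0.2.
#' @return Numeric vector of 10 cutoffs.
#' @export
default_t_grid <- function() seq(0.4, 2.2, by = 0.2)

#' PIBGM profile over a cutoff grid
#'
#' One [pibgm()] evaluation per cutoff; the profile is a non-increasing
#' step function of `t` with steps at observed SUVs.
#'
#' @inheritParams pibgm
#' @param t_grid strictly increasing numeric vector of SUV cutoffs.
#' @return List of `pibgm_result`, one per cutoff, in grid order.
#' @export
pibgm_profile <- function(suv, mask,
                          region = c("whole_bone", "marrow", "cortex"),
                          t_grid = default_t_grid()) {
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  region <- match.arg(region)
  lapply(t_grid, function(t) pibgm(suv, mask, region, t))
}
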