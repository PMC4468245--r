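# Synthetic co-registered CT/PET phantoms with ground-truth masks.
#
# The phantom is a stylized torso: stacked ellipses of fat enclosing muscle,
# enclosing a circular bone ring (cortex) with a marrow core, plus an
# optional scanner-bed slab below the body that appears in CT only.  The
# geometry is deliberately simple -- the segmentation pipeline is intensity
# driven, not shape driven -- but it exercises every downstream stage:
# three-population soft-tissue histogram, dense cortical shell, enclosed
# marrow, bed artifact, and PET uptake expressed in true SUV_bw units.

#' Phantom generation parameters
#'
#' Describes one synthetic patient: grid, voxel spacing, tissue intensity
#' populations in HU, bed artifact, per-tissue PET uptake expressed as
#' target SUV_bw, optional lesions, and acquisition metadata.
#'
#' Default HU means (fat -100, muscle 40, marrow 150, cortex 700, bed 300,
#' air -1000) follow the usual ordering of clinical CT; default uptake
#' values (marrow 0.93, cortex 0.86 SUV_bw) mirror typical normal-subject
#' skeletal FDG uptake, with fat and muscle well below.
#'
#' @param grid_shape voxels per axis `(slice, row, col)`, all >= 16.
#' @param voxel_spacing mm per axis.
#' @param body_radius_frac body ellipse semi-axes as a fraction of the
#'   in-plane half-extent.
#' @param tissue_means named HU means for `fat`, `muscle`, `marrow`,
#'   `cortex`; must be strictly increasing in that order.
#' @param tissue_sds named HU noise standard deviations per tissue
#'   (same names); zero gives a noiseless CT.
#' @param bed list with `enabled`, `hu`, and `thickness_voxels`; the bed is
#'   a slab spanning the body width just below the body, present in CT only.
#' @param pet_uptake named target SUV_bw per tissue (`fat`, `muscle`,
#'   `marrow`, `cortex`).
#' @param pet_noise_sd PET noise standard deviation in SUV units (additive
#'   Gaussian, clamped at zero activity).
#' @param cortex_frac volume fraction of bone occupied by cortex, in `[0,1]`.
#' @param lesion_spec optional list of lesions, each a list with `region`
#'   (`"marrow"` or `"cortex"`), `multiplier` (uptake factor) and
#'   `volume_frac` (fraction of the region affected).
#' @param meta a [patient_meta()].
#' @param seed integer RNG seed; a fixed seed reproduces the phantom
#'   bit for bit.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(16L, 48L, 48L),
                         voxel_spacing = c(5, 1.5, 1.5),
                         body_radius_frac = 0.7,
                         tissue_means = c(fat = -100, muscle = 40,
                                          marrow = 150, cortex = 700),
                         tissue_sds = c(fat = 15, muscle = 15,
                                        marrow = 15, cortex = 15),
                         bed = list(enabled = TRUE, hu = 300,
                                    thickness_voxels = 2L),
                         pet_uptake = c(fat = 0.2, muscle = 0.5,
                                        marrow = 0.93, cortex = 0.86),
                         pet_noise_sd = 0.15,
                         cortex_frac = 0.5,
                         lesion_spec = NULL,
                         meta = patient_meta(370, 70, 170, "female"),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must be 3 integers, all >= 16")
  tissues <- c("fat", "muscle", "marrow", "cortex")
  if (!all(tissues %in% names(tissue_means)))
    stop("tissue_means must name fat, muscle, marrow, cortex")
  tm <- tissue_means[tissues]
  if (any(diff(tm) <= 0))
    stop("tissue_means must be ordered fat < muscle < marrow < cortex")
  if (!all(tissues %in% names(tissue_sds)) || any(tissue_sds < 0))
    stop("tissue_sds must name all tissues and be >= 0")
  if (!all(tissues %in% names(pet_uptake)) || any(pet_uptake < 0))
    stop("pet_uptake must name all tissues and be >= 0")
  if (cortex_frac < 0 || cortex_frac > 1)
    stop("cortex_frac must lie in [0, 1]")
  if (pet_noise_sd < 0) stop("pet_noise_sd must be >= 0")
  for (les in lesion_spec) {
    stopifnot(les$region %in% c("marrow", "cortex"),
              les$multiplier >= 0,
              les$volume_frac >= 0, les$volume_frac <= 1)
  }
  stopifnot(inherits(meta, "patient_meta"))
  structure(list(grid_shape = grid_shape,
                 voxel_spacing = as.numeric(voxel_spacing),
                 body_radius_frac = body_radius_frac,
                 tissue_means = tm,
                 tissue_sds = tissue_sds[tissues],
                 bed = bed,
                 pet_uptake = pet_uptake[tissues],
                 pet_noise_sd = pet_noise_sd,
                 cortex_frac = cortex_frac,
                 lesion_spec = lesion_spec,
                 meta = meta,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# In-plane tissue geometry shared by CT and PET generation.  Returns integer
# codes on the full grid: 0 air, 1 fat, 2 muscle, 3 marrow, 4 cortex,
# 5 bed (CT only).
.phantom_geometry <- function(spec) {
  d <- spec$grid_shape
  ns <- d[1]; nr <- d[2]; nc <- d[3]
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  ar <- spec$body_radius_frac * nr / 2
  ac <- spec$body_radius_frac * nc / 2
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  e_body <- ((row - cr) / ar)^2 + ((col - cc) / ac)^2
  body2 <- e_body <= 1
  muscle2 <- e_body <= 0.75^2
  r_bone <- 0.45 * min(ar, ac)
  r_marrow <- r_bone * sqrt(1 - spec$cortex_frac)
  rad2 <- (row - cr)^2 + (col - cc)^2
  bone2 <- rad2 <= r_bone^2
  marrow2 <- rad2 <= r_marrow^2
  lab2 <- matrix(0L, nr, nc)
  lab2[body2] <- 1L
  lab2[muscle2] <- 2L
  lab2[bone2] <- 3L + 0L  # provisional; cortex assigned below
  lab2[bone2 & !marrow2] <- 4L
  lab2[marrow2] <- 3L
  if (isTRUE(spec$bed$enabled)) {
    bottom <- ceiling(cr + ar)
    t <- spec$bed$thickness_voxels
    bed_rows <- pmin(nr, (bottom + 2):(bottom + 1 + t))
    bed2 <- matrix(FALSE, nr, nc)
    bed2[bed_rows, abs(col[1, ] - cc) <= ac] <- TRUE
    bed2 <- bed2 & lab2 == 0L
    lab2[bed2] <- 5L
  }
  lab <- array(0L, d)
  for (s in seq_len(ns)) lab[s, , ] <- lab2
  lab
}

#' Generate one synthetic CT/PET phantom
#'
#' Builds co-registered CT (HU) and PET (Bq/mL) volumes plus exact
#' ground-truth body and bone masks. PET activity is set so that each
#' tissue's voxel SUV_bw equals `spec$pet_uptake` for that tissue given
#' `spec$meta` (activity concentration = uptake x dose / body weight,
#' unit-consistent), before optional noise.
#'
#' @param spec a [phantom_spec()].
#' @param group_label cohort group this case belongs to, one of
#'   `"normal"`, `"inflammatory"`, `"infection"`, `"neoplasm"`.
#' @param pet_lowres if `TRUE`, additionally return the PET block-averaged
#'   to a 3x lower in-plane resolution (element `pet_lowres`), emulating the
#'   native PET grid that [upsample_pet_replicate()] restores.
#' @return An object of class `phantom_case`: list with `ct`, `pet`
#'   ([volume3d()]), `truth_body`, `truth_bone` ([region_mask()]; bone mask
#'   uses labels 1 = marrow, 2 = cortex), `meta`, `group_label`, `spec`,
#'   and optionally `pet_lowres`.
#' @examples
#' case <- make_phantom(phantom_spec(seed = 7))
#' case$ct
#' @export
make_phantom <- function(spec,
                         group_label = c("normal", "inflammatory",
                                         "infection", "neoplasm"),
                         pet_lowres = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  group_label <- match.arg(group_label)
  meta <- spec$meta
  set.seed(spec$seed)
  lab <- .phantom_geometry(spec)
  d <- spec$grid_shape

  ct <- array(-1000, d)
  tissue_code <- c(fat = 1L, muscle = 2L, marrow = 3L, cortex = 4L)
  for (t in names(tissue_code)) {
    idx <- which(lab == tissue_code[[t]])
    vals <- rep(spec$tissue_means[[t]], length(idx))
    if (spec$tissue_sds[[t]] > 0)
      vals <- vals + stats::rnorm(length(idx), 0, spec$tissue_sds[[t]])
    ct[idx] <- vals
  }
  if (isTRUE(spec$bed$enabled)) ct[lab == 5L] <- spec$bed$hu

  # SUV_bw target -> activity concentration in Bq/mL:
  # SUV_bw = conc(MBq/mL) / (dose(MBq) / weight(g)), so
  # conc(Bq/mL) = uptake * dose / weight_g * 1e6.
  weight_g <- meta$body_weight_kg * 1000
  suv_scale <- meta$injected_dose_MBq / weight_g * 1e6
  uptake <- array(0, d)
  for (t in names(tissue_code))
    uptake[lab == tissue_code[[t]]] <- spec$pet_uptake[[t]]
  for (les in spec$lesion_spec) {
    reg_code <- tissue_code[[les$region]]
    idx <- which(lab == reg_code)
    n_les <- round(les$volume_frac * length(idx))
    if (n_les > 0) {
      centre <- idx[sample.int(length(idx), 1L)]
      pos <- arrayInd(idx, d)
      cpos <- arrayInd(centre, d)
      dist2 <- colSums((t(pos) - as.numeric(cpos))^2)
      sel <- idx[order(dist2)[seq_len(n_les)]]
      uptake[sel] <- uptake[sel] * les$multiplier
    }
  }
  if (spec$pet_noise_sd > 0) {
    inb <- lab >= 1L & lab <= 4L
    uptake[inb] <- pmax(0, uptake[inb] +
                          stats::rnorm(sum(inb), 0, spec$pet_noise_sd))
  }
  pet <- uptake * suv_scale

  body <- (lab >= 1L & lab <= 4L) * 1L
  bone <- array(0L, d)
  bone[lab == 3L] <- MASK_LABELS[["marrow"]]
  bone[lab == 4L] <- MASK_LABELS[["cortex"]]

  out <- structure(
    list(ct = volume3d(ct, spec$voxel_spacing, "HU"),
         pet = volume3d(pet, spec$voxel_spacing, "Bq/mL"),
         truth_body = region_mask(array(body, d), spec$voxel_spacing),
         truth_bone = region_mask(bone, spec$voxel_spacing),
         meta = meta, group_label = group_label, spec = spec),
    class = "phantom_case")
  if (pet_lowres) out$pet_lowres <- .block_average_pet(out$pet)
  out
}

# Block-average the in-plane PET by 3x3, emulating the coarser native PET
# grid; rows/cols must be divisible by 3.
.block_average_pet <- function(pet) {
  d <- dim(pet$data)
  if (d[2] %% 3L != 0L || d[3] %% 3L != 0L)
    stop("in-plane dimensions must be divisible by 3 for low-res PET")
  nr <- d[2] %/% 3L; nc <- d[3] %/% 3L
  out <- array(0, c(d[1], nr, nc))
  for (i in 0:2) for (j in 0:2) {
    out <- out + pet$data[, seq(1 + i, d[2], by = 3), seq(1 + j, d[3], by = 3)]
  }
  volume3d(out / 9, spacing = pet$spacing * c(1, 3, 3), unit = pet$unit)
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> group=%s, grid %s, %d bone voxels\n",
              x$group_label,
              paste(dim(x$ct$data), collapse = "x"),
              sum(x$truth_bone$labels > 0)))
  invisible(x)
}

#' Generate a cohort of phantoms with group-level uptake differences
#'
#' Each case draws a patient-level cortex uptake from a Gaussian centred at
#' the baseline cortex uptake plus the group's uplift, emulating the
#' between-patient spread of skeletal FDG uptake, with elevated uptake in
#' the disease groups (strongest for neoplasm and non-infectious
#' inflammatory disease, weakest for infection).
#'
#' @param n_per_group named integer vector of case counts, names from
#'   `normal`, `inflammatory`, `infection`, `neoplasm`.
#' @param effect named per-group cortex SUV uplift (>= 0) added to the
#'   baseline cortex uptake.
#' @param seed integer seed controlling both patient-level draws and every
#'   per-case phantom seed; a fixed seed reproduces the cohort exactly.
#' @param base_spec template [phantom_spec()] shared by all cases.
#' @param patient_sd between-patient standard deviation of mean cortex
#'   uptake (SUV units); 0 makes all patients in a group identical in
#'   expectation.
#' @return List of [make_phantom()] cases, each carrying its `group_label`.
#' @export
make_cohort <- function(n_per_group = c(normal = 20, inflammatory = 5,
                                        infection = 7, neoplasm = 5),
                        effect = c(normal = 0, inflammatory = 0.20,
                                   infection = 0.17, neoplasm = 0.23),
                        seed = 1L,
                        base_spec = phantom_spec(),
                        patient_sd = 0.15) {
  groups <- names(n_per_group)
  bad <- setdiff(groups, c("normal", "inflammatory", "infection", "neoplasm"))
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  if (any(n_per_group < 0)) stop("counts must be >= 0")
  if (any(effect[groups] < 0, na.rm = TRUE)) stop("uplifts must be >= 0")
  set.seed(seed)
  cases <- list()
  k <- 0L
  for (g in groups) {
    upl <- if (g %in% names(effect)) effect[[g]] else 0
    for (i in seq_len(n_per_group[[g]])) {
      k <- k + 1L
      cortex_up <- base_spec$pet_uptake[["cortex"]] + upl
      if (patient_sd > 0)
        cortex_up <- max(0, cortex_up + stats::rnorm(1, 0, patient_sd))
      sp <- base_spec
      sp$pet_uptake[["cortex"]] <- cortex_up
      sp$seed <- as.integer((seed * 1000L + k) %% .Machine$integer.max)
      sp$meta$id <- sprintf("%s_%03d", g, i)
      cases[[k]] <- make_phantom(sp, group_label = g)
    }
  }
  cases
}

#' Write a phantom case to disk
#'
#' Writes `ct.nii.gz`, `pet.nii.gz`, `truth_body.nii.gz`, `truth_bone.nii.gz`
#' (each with a JSON unit sidecar) and `meta.json` into `dir`.
#'
#' @param case a [make_phantom()] result.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(case$ct, file.path(dir, "ct.nii.gz"))
  write_volume(case$pet, file.path(dir, "pet.nii.gz"))
  write_volume(case$truth_body, file.path(dir, "truth_body.nii.gz"))
  write_volume(case$truth_bone, file.path(dir, "truth_bone.nii.gz"))
  m <- case$meta
  jsonlite::write_json(list(id = m$id, injected_dose_MBq = m$injected_dose_MBq,
                            body_weight_kg = m$body_weight_kg,
                            body_height_cm = m$body_height_cm, sex = m$sex,
                            group_label = case$group_label),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
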