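# End-to-end orchestration: phantom-or-file -> preprocess -> threshold ->
# segment -> quantify -> diagnose, with JSON/CSV report writing.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default. The configuration
#' round-trips losslessly through [write_config()] / [read_config()].
#'
#' @param bed a [bed_removal_params()].
#' @param thr a [threshold_params()].
#' @param cv a [cv_params()].
#' @param t_grid PIBGM SUV-cutoff grid.
#' @param danp_grid DANP levels for the cohort sweep.
#' @param decision_t SUV cutoff of the decision biomarker (cortex PIBGM).
#' @param decision_region region of the decision biomarker.
#' @param suv_modes SUV normalizations to compute.
#' @param upsample `"replicate"`, `"trilinear"` or `"none"`; applied when
#'   the PET grid is coarser than the CT grid.
#' @param target_inplane in-plane CT size for replication upsampling.
#' @param seed integer seed recorded for provenance.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(bed = bed_removal_params(),
                            thr = threshold_params(),
                            cv = cv_params(),
                            t_grid = default_t_grid(),
                            danp_grid = c(1, 0.95, 0.9, 0.85),
                            decision_t = 1.2,
                            decision_region = "cortex",
                            suv_modes = c("bw", "bsa", "lbm"),
                            upsample = c("replicate", "trilinear", "none"),
                            target_inplane = 512L,
                            seed = 1L) {
  upsample <- match.arg(upsample)
  stopifnot(inherits(bed, "bed_removal_params"),
            inherits(thr, "threshold_params"),
            inherits(cv, "cv_params"),
            all(suv_modes %in% c("bw", "bsa", "lbm")),
            decision_region %in% c("whole_bone", "marrow", "cortex"))
  structure(list(bed = bed, thr = thr, cv = cv, t_grid = t_grid,
                 danp_grid = danp_grid, decision_t = decision_t,
                 decision_region = decision_region, suv_modes = suv_modes,
                 upsample = upsample,
                 target_inplane = as.integer(target_inplane),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the reconstructed [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(el) if (is.list(el) && !is.data.frame(el))
      strip(el) else el)
  }
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$cv$thresh <- if (is.null(raw$cv$thresh)) NA_real_ else raw$cv$thresh
  pipeline_config(
    bed = do.call(bed_removal_params, raw$bed),
    thr = do.call(threshold_params, raw$thr),
    cv = do.call(cv_params, raw$cv),
    t_grid = raw$t_grid, danp_grid = raw$danp_grid,
    decision_t = raw$decision_t, decision_region = raw$decision_region,
    suv_modes = raw$suv_modes, upsample = raw$upsample,
    target_inplane = raw$target_inplane, seed = raw$seed)
}

#' Run the full pipeline for one patient
#'
#' Executes, in order: PET upsampling (when the PET grid is coarser than
#' the CT grid), body-mask extraction and bed removal, histogram
#' auto-thresholding, slice-wise Chan-Vese bone segmentation with
#' cortex/marrow splitting, SUV maps under the configured normalizations,
#' per-region SUV statistics and PIBGM profiles.
#'
#' @param case a [make_phantom()] case, or a list with elements `ct`, `pet`
#'   ([volume3d()]) and `meta` ([patient_meta()]), optionally `group_label`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, masks are written as
#'   NIfTI and the report as `report_<id>.json`.
#' @return An object of class `patient_report`: list with `patient_id`,
#'   `group_label`, `threshold` (fit centres + HU threshold), `counts`
#'   (body/bone/marrow/cortex voxels), `suv_stats` and `pibgm` data frames,
#'   `seg` (the labelled bone [region_mask()]), and `provenance`.
#' @export
run_patient <- function(case, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ct <- case$ct; pet <- case$pet; meta <- case$meta
  stopifnot(inherits(ct, "volume3d"), inherits(pet, "volume3d"),
            inherits(meta, "patient_meta"))
  group_label <- if (!is.null(case$group_label)) case$group_label else NA_character_

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  # 1. bring PET onto the CT grid
  pet_hi <- stage("upsample", {
    if (identical(dim(pet$data), dim(ct$data))) {
      check_coregistered(pet, ct)
      pet
    }
    else if (config$upsample == "replicate")
      upsample_pet_replicate(pet, target_inplane = dim(ct$data)[2])
    else if (config$upsample == "trilinear")
      upsample_pet_trilinear(pet, dim(ct$data))
    else stop("PET and CT grids differ but upsampling is disabled")
  })
  check_same_grid(pet_hi, ct, "upsampled PET and CT")

  # 2. body mask + bed removal
  body <- stage("body_mask", body_mask_from_pet(pet_hi, config$bed))
  ct_clean <- stage("remove_bed",
                    remove_bed(ct, body, config$bed$background_fill))

  # 3. histogram auto-threshold
  fit <- stage("autothreshold", {
    h <- build_histogram(ct_clean, body, config$thr$n_bins,
                         config$thr$hu_range)
    fit_two_gaussians(h$bin_edges, h$bin_counts)
  })
  hu_thr <- compute_threshold(fit, config$thr$omega)

  # 4. bone segmentation + cortex/marrow split
  bone <- stage("segment",
                segment_bone_volume(ct_clean, body, hu_thr, config$cv))
  seg <- stage("split", split_cortex_marrow(ct_clean, bone))

  # 5. quantification
  suv_rows <- list(); pibgm_rows <- list()
  regions <- c("whole_bone", "marrow", "cortex")
  for (mode in config$suv_modes) {
    sm <- stage("quantify", suv_map(pet_hi, meta, mode))
    for (reg in regions) {
      st <- region_suv_stats(sm, seg, reg)
      suv_rows[[length(suv_rows) + 1L]] <-
        data.frame(region = reg, mode = mode, mean = st$mean, sd = st$sd,
                   n = st$n)
      prof <- pibgm_profile(sm, seg, reg, config$t_grid)
      for (p in prof) {
        pibgm_rows[[length(pibgm_rows) + 1L]] <-
          data.frame(region = reg, mode = mode, t = p$t, value = p$value,
                     N_t = p$N_t, N_b = p$N_b)
      }
    }
  }

  report <- structure(list(
    patient_id = meta$id,
    group_label = group_label,
    threshold = list(B_f = fit$B_f, B_m = fit$B_m,
                     residual_norm = fit$residual_norm,
                     hu_threshold = hu_thr),
    counts = list(body = sum(body$labels > 0),
                  bone = sum(seg$labels > 0),
                  marrow = sum(seg$labels == MASK_LABELS[["marrow"]]),
                  cortex = sum(seg$labels == MASK_LABELS[["cortex"]])),
    suv_stats = do.call(rbind, suv_rows),
    pibgm = do.call(rbind, pibgm_rows),
    seg = seg,
    provenance = list(package_version = as.character(utils::packageVersion("pibgm")),
                      seed = config$seed)),
    class = "patient_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(seg, file.path(out_dir, sprintf("bone_%s.nii.gz", meta$id)))
    json <- report
    json$seg <- NULL
    json$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(json, file.path(out_dir,
                                         sprintf("report_%s.json", meta$id)),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE)
  }
  report
}

#' @export
print.patient_report <- function(x, ...) {
  cat(sprintf("<patient_report> %s (%s): %d bone voxels (%d marrow / %d cortex), HU threshold %.1f\n",
              x$patient_id, x$group_label, x$counts$bone, x$counts$marrow,
              x$counts$cortex, x$threshold$hu_threshold))
  invisible(x)
}

#' Run the pipeline over a cohort and evaluate diagnostics
#'
#' Runs [run_patient()] per case, assembles the cortex/marrow/whole-bone
#' PIBGM values into a [cohort_table()], then performs the DANP sweep,
#' Welch t-tests of each disease group against normals, and ROC analysis of
#' the decision biomarker (cortex PIBGM at the configured cutoff by
#' default).
#'
#' @param cases list of cases as accepted by [run_patient()] (e.g. from
#'   [make_cohort()]); at least two groups must be present.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for per-patient and cohort outputs
#'   (`cohort.csv`, `danp_sweep.csv`, `roc_points.csv`,
#'   `cohort_report.json`).
#' @return An object of class `cohort_report`: list with `cohort`
#'   ([cohort_table()]), `sweep` (the [danp_sweep()] table), `ttests`
#'   (per group x region x t), `roc` ([roc_auc()] result), `reports`
#'   (per-patient reports).
#' @export
run_cohort <- function(cases, config = pipeline_config(), out_dir = NULL) {
  stopifnot(length(cases) >= 2L)
  reports <- lapply(cases, function(cs) {
    tryCatch(run_patient(cs, config),
             error = function(e)
               stop(sprintf("patient %s: %s", cs$meta$id,
                            conditionMessage(e)), call. = FALSE))
  })
  groups <- vapply(reports, function(r) r$group_label, character(1))
  if (length(unique(groups)) < 2L)
    stop("cohort must contain at least two groups")

  rows <- do.call(rbind, lapply(reports, function(r) {
    pb <- r$pibgm
    data.frame(patient_id = r$patient_id, group = r$group_label,
               region = pb$region, mode = pb$mode, t = pb$t,
               value = pb$value, stringsAsFactors = FALSE)
  }))
  cohort <- cohort_table(rows$patient_id, rows$group, rows$region,
                         rows$mode, rows$t, rows$value)

  sweep <- danp_sweep(cohort, config$danp_grid, config$t_grid,
                      region = config$decision_region, mode = "bw")

  # Welch t-tests of each disease group vs normals, per region and cutoff
  tt_rows <- list()
  for (reg in c("cortex", "marrow")) for (t in config$t_grid) {
    sel <- cohort$region == reg & cohort$mode == "bw" &
      abs(cohort$t - t) < 1e-9
    normals <- cohort$value[sel & cohort$group == "normal"]
    for (g in setdiff(unique(groups), "normal")) {
      vals <- cohort$value[sel & cohort$group == g]
      tt <- tryCatch(welch_ttest(vals, normals), error = function(e) NULL)
      if (!is.null(tt))
        tt_rows[[length(tt_rows) + 1L]] <-
          data.frame(group = g, region = reg, t = t,
                     t_stat = tt$t, p_value = tt$p)
    }
  }
  ttests <- if (length(tt_rows)) do.call(rbind, tt_rows) else NULL

  dec <- cohort$region == config$decision_region & cohort$mode == "bw" &
    abs(cohort$t - config$decision_t) < 1e-9
  scores <- cohort$value[dec]
  truth <- cohort$group[dec] != "normal"
  roc <- roc_auc(scores, truth)

  out <- structure(list(cohort = cohort, sweep = sweep, ttests = ttests,
                        roc = roc, reports = reports),
                   class = "cohort_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(sweep, file.path(out_dir, "danp_sweep.csv"),
                     row.names = FALSE)
    utils::write.csv(roc$points, file.path(out_dir, "roc_points.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(auc = roc$auc, grade = roc$grade,
                              n_patients = length(reports)),
                         file.path(out_dir, "cohort_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d patients, AUC %.3f (%s)\n",
              length(x$reports), x$roc$auc, x$roc$grade))
  invisible(x)
}
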