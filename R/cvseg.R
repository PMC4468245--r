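# Threshold-augmented Chan-Vese segmentation of bone from CT.
#
# The two-region energy is
#   E(C) = sum_inside  (I - c1)^2 + eps (I - Th)^2
#        + sum_outside (I - c2)^2 + eps (I - Th)^2
# with c1, c2 the mean intensities inside/outside the evolving contour, Th a
# predefined local threshold and eps its weighting coefficient.  Because the
# eps-term is integrated over both regions it contributes a constant offset
# for a fixed image; the contour dynamics are therefore those of the
# classic two-phase Chan-Vese fidelity, and eps only shifts reported
# energies.  As printed the energy carries no smoothness term, so its exact
# minimizer is a per-pixel nearest-of-{c1,c2} classification; a standard
# contour-length penalty weighted by `mu` is added for noise robustness,
# with mu = 0 reproducing the literal energy.

#' Chan-Vese parameters
#'
#' @param epsilon weighting coefficient of the threshold-fidelity term
#'   (dimensionless, >= 0).
#' @param thresh predefined local threshold Th in HU; `NA` lets
#'   [segment_bone_volume()] substitute the histogram-derived bone
#'   threshold.
#' @param mu contour-length regularization weight. `NULL` (default) scales
#'   to 0.1 x (image dynamic range)^2 at evolution time so the smoothness
#'   force is commensurate with the squared-intensity data force; `0` gives
#'   the literal unregularized energy.
#' @param max_iters maximum evolution iterations (>= 1).
#' @param tol convergence tolerance: stop when the fraction of voxels
#'   changing label in an iteration falls below it; in (0, 0.1).
#' @param heaviside_width smoothed Heaviside/delta width in voxels.
#' @return An object of class `cv_params`.
#' @export
cv_params <- function(epsilon = 1.0, thresh = NA_real_, mu = NULL,
                      max_iters = 200L, tol = 1e-4, heaviside_width = 1) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (!is.null(mu) && mu < 0) stop("mu must be >= 0 (or NULL for auto)")
  max_iters <- as.integer(max_iters)
  if (max_iters < 1L) stop("max_iters must be >= 1")
  if (tol <= 0 || tol >= 0.1) stop("tol must lie in (0, 0.1)")
  if (heaviside_width <= 0) stop("heaviside_width must be > 0")
  structure(list(epsilon = epsilon, thresh = thresh, mu = mu,
                 max_iters = max_iters, tol = tol,
                 heaviside_width = heaviside_width),
            class = "cv_params")
}

.as_logical_mask <- function(mask) {
  if (inherits(mask, "region_mask")) mask <- mask$labels
  mask > 0
}

#' Mean intensities inside and outside a contour
#'
#' @param image numeric array (2D slice or 3D volume) or [volume3d()].
#' @param mask logical/0-1 array of the same shape (inside = TRUE), or a
#'   [region_mask()].
#' @param domain optional logical array restricting both regions (voxels
#'   outside the domain belong to neither region).
#' @return List with `c1` (mean inside) and `c2` (mean outside).
#' @export
region_means <- function(image, mask, domain = NULL) {
  if (inherits(image, "volume3d")) image <- image$data
  m <- .as_logical_mask(mask)
  if (is.null(domain)) domain <- array(TRUE, dim(image))
  inside <- domain & m
  outside <- domain & !m
  if (!any(inside)) stop("inside region is empty")
  if (!any(outside)) stop("outside region is empty")
  list(c1 = mean(image[inside]), c2 = mean(image[outside]))
}

#' Threshold-augmented Chan-Vese energy
#'
#' Evaluates the two-region energy of a labelling: intensity-fidelity terms
#' around the inside/outside means plus the `epsilon`-weighted squared
#' deviation from the predefined threshold, integrated over both regions.
#' With `epsilon = 0` this is the classic Chan-Vese fidelity.
#'
#' @inheritParams region_means
#' @param params a [cv_params()]; `params$thresh` must be finite when
#'   `params$epsilon > 0`.
#' @return Scalar energy.
#' @export
cv_energy <- function(image, mask, params = cv_params(), domain = NULL) {
  if (inherits(image, "volume3d")) image <- image$data
  m <- .as_logical_mask(mask)
  if (is.null(domain)) domain <- array(TRUE, dim(image))
  mom <- region_means(image, m, domain)
  eps <- params$epsilon
  th <- params$thresh
  if (eps > 0 && !is.finite(th))
    stop("params$thresh must be finite when epsilon > 0")
  inside <- domain & m
  outside <- domain & !m
  e <- sum((image[inside] - mom$c1)^2) + sum((image[outside] - mom$c2)^2)
  if (eps > 0)
    e <- e + eps * sum((image[domain] - th)^2)
  e
}

#' Evolve a contour to minimize the Chan-Vese energy on one slice
#'
#' With `mu = 0` the energy has no smoothness term and its gradient flow
#' drives each pixel's sign to the per-pixel optimum between updates of the
#' region means; the evolution is then the exact alternating minimization
#' (reassign each pixel to the nearer of c1/c2, update means), which
#' decreases the energy monotonically. With `mu > 0` a level-set gradient
#' descent is used: signed-distance initialization, smoothed
#' Heaviside/delta of width `heaviside_width`, curvature term weighted by
#' `mu`, re-initialization every 10 iterations.
#'
#' @param image numeric matrix (one slice).
#' @param init_mask logical/0-1 matrix, both regions non-empty within the
#'   domain.
#' @param params a [cv_params()].
#' @param domain optional logical matrix; pixels outside it are frozen as
#'   background and excluded from both regions.
#' @return Logical matrix (inside = TRUE) with attributes `iterations`,
#'   `converged`, and `energy_trace` (per-iteration energy, including the
#'   initial labelling; exact alternating-minimization path only).
#' @export
evolve_contour <- function(image, init_mask, params = cv_params(),
                           domain = NULL) {
  stopifnot(is.matrix(image))
  m <- .as_logical_mask(init_mask)
  stopifnot(identical(dim(m), dim(image)))
  if (is.null(domain)) domain <- matrix(TRUE, nrow(image), ncol(image))
  m <- m & domain
  if (!any(m)) stop("initial inside region is empty")
  if (!any(domain & !m)) stop("initial outside region is empty")
  mu <- params$mu
  if (is.null(mu)) mu <- 0.1 * diff(range(image[domain]))^2
  n_dom <- sum(domain)

  if (mu == 0) {
    trace <- cv_energy(image, m, params, domain)
    for (it in seq_len(params$max_iters)) {
      mom <- region_means(image, m, domain)
      new_m <- ((image - mom$c1)^2 <= (image - mom$c2)^2) & domain
      if (!any(new_m))
        stop(sprintf("contour vanished (inside region emptied) at iteration %d", it))
      if (!any(domain & !new_m))
        stop(sprintf("contour vanished (outside region emptied) at iteration %d", it))
      changed <- sum(new_m != m) / n_dom
      m <- new_m
      trace <- c(trace, cv_energy(image, m, params, domain))
      if (changed < params$tol) {
        return(structure(m, iterations = it, converged = TRUE,
                         energy_trace = trace))
      }
    }
    return(structure(m, iterations = params$max_iters, converged = FALSE,
                     energy_trace = trace))
  }

  # level-set descent with curvature regularization
  h <- params$heaviside_width
  phi <- .signed_distance2(m)
  phi[!domain] <- -max(dim(image))  # freeze non-domain pixels outside
  for (it in seq_len(params$max_iters)) {
    Hv <- 0.5 * (1 + (2 / pi) * atan(phi / h))
    Hv[!domain] <- 0
    w_in <- sum(Hv)
    w_out <- sum(domain) - w_in
    if (w_in < .Machine$double.eps || w_out < .Machine$double.eps)
      stop(sprintf("contour vanished at iteration %d", it))
    c1 <- sum(Hv * image) / w_in
    c2 <- sum((domain - Hv) * image) / w_out
    delta <- (1 / pi) * h / (h^2 + phi^2)
    force <- -(image - c1)^2 + (image - c2)^2
    dphi <- delta * (mu * .curvature2(phi) + force)
    dphi[!domain] <- 0
    step <- 0.45 / max(abs(dphi), .Machine$double.eps)
    old_sign <- phi > 0
    phi <- phi + step * dphi
    if (it %% 10L == 0L) {
      phi <- .signed_distance2((phi > 0) & domain)
      phi[!domain] <- -max(dim(image))
    }
    changed <- sum((phi > 0) != old_sign) / n_dom
    if (changed < params$tol && it > 1L) {
      m <- (phi > 0) & domain
      if (!any(m) || !any(domain & !m))
        stop(sprintf("contour vanished at iteration %d", it))
      return(structure(m, iterations = it, converged = TRUE,
                       energy_trace = NULL))
    }
  }
  m <- (phi > 0) & domain
  if (!any(m) || !any(domain & !m))
    stop(sprintf("contour vanished at iteration %d", params$max_iters))
  structure(m, iterations = params$max_iters, converged = FALSE,
            energy_trace = NULL)
}

#' Segment the bone volume by slice-wise contour evolution
#'
#' Initializes each axial slice from the HU pre-segmentation, evolves the
#' threshold-augmented Chan-Vese contour within the body, and fills
#' slice-wise holes so the marrow enclosed by the cortical shell belongs to
#' the bone mask. Slices whose pre-segmentation is empty stay empty.
#'
#' @param ct bed-removed CT [volume3d()].
#' @param body binary body [region_mask()].
#' @param fit_threshold HU bone threshold from [compute_threshold()].
#' @param params a [cv_params()]; a non-finite `thresh` is replaced by
#'   `fit_threshold`.
#' @return Binary bone [region_mask()].
#' @export
segment_bone_volume <- function(ct, body, fit_threshold,
                                params = cv_params()) {
  stopifnot(inherits(ct, "volume3d"), inherits(body, "region_mask"))
  check_same_grid(ct, body, "CT and body mask")
  if (!is.finite(params$thresh)) params$thresh <- fit_threshold
  pre <- presegment_bone(ct, body, fit_threshold, fill_holes = TRUE)
  d <- dim(ct$data)
  out <- array(0L, d)
  for (s in seq_len(d[1])) {
    init <- pre$labels[s, , ] > 0
    if (!any(init)) next
    dom <- body$labels[s, , ] > 0
    if (all(init[dom])) {
      # pre-segmentation already covers the whole domain; nothing to refine
      out[s, , ] <- as.integer(init)
      next
    }
    mask <- tryCatch(
      evolve_contour(ct$data[s, , ], init, params, domain = dom),
      error = function(e)
        stop(sprintf("slice %d: %s", s, conditionMessage(e))))
    mask <- .fill_holes_slice2(mask) & dom
    out[s, , ] <- as.integer(mask)
  }
  region_mask(out, spacing = ct$spacing)
}

# 2D hole fill on a single slice
.fill_holes_slice2 <- function(mask) {
  as.matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0.5
}

#' Split a bone mask into cortex and marrow by intensity
#'
#' Within-bone HU split: voxels at or above the cut become cortex (label 2),
#' below it marrow (label 1). The default cut is Otsu's threshold over the
#' bone-voxel HU distribution; a fixed HU cutoff can be given instead.
#'
#' @param ct CT [volume3d()].
#' @param bone_mask binary bone [region_mask()].
#' @param split_mode `"otsu"` or `"fixed"`.
#' @param cutoff_hu HU cutoff when `split_mode = "fixed"`.
#' @return [region_mask()] with labels 1 = marrow, 2 = cortex partitioning
#'   the bone mask.
#' @export
split_cortex_marrow <- function(ct, bone_mask,
                                split_mode = c("otsu", "fixed"),
                                cutoff_hu = NULL) {
  stopifnot(inherits(ct, "volume3d"), inherits(bone_mask, "region_mask"))
  check_same_grid(ct, bone_mask, "CT and bone mask")
  split_mode <- match.arg(split_mode)
  inb <- bone_mask$labels > 0
  if (!any(inb)) stop("bone mask is empty")
  vals <- ct$data[inb]
  cut <- if (split_mode == "otsu") {
    if (length(unique(vals)) < 2L)
      stop("bone mask has fewer than 2 distinct HU values; cannot split")
    .otsu_values(vals)
  } else {
    if (is.null(cutoff_hu)) stop("cutoff_hu required for fixed split")
    cutoff_hu
  }
  lab <- array(0L, dim(ct$data))
  lab[inb] <- ifelse(ct$data[inb] >= cut, MASK_LABELS[["cortex"]],
                     MASK_LABELS[["marrow"]])
  region_mask(lab, spacing = ct$spacing)
}

#' Extract PET values per mask label
#'
#' Masks the (upsampled) PET with a label volume and returns the PET voxel
#' values for each requested label; an empty label yields an empty vector.
#'
#' @param mask a [region_mask()] on the PET grid.
#' @param pet a [volume3d()] sharing the mask's grid.
#' @param labels named integer vector of labels to extract; defaults to
#'   marrow/cortex when label 2 occurs, else a single `bone = 1` entry.
#' @return Named list of numeric vectors of PET values.
#' @export
transfer_mask_to_pet <- function(mask, pet, labels = NULL) {
  stopifnot(inherits(mask, "region_mask"), inherits(pet, "volume3d"))
  check_same_grid(mask, pet, "mask and PET")
  if (is.null(labels)) {
    labels <- if (any(mask$labels == MASK_LABELS[["cortex"]]))
      MASK_LABELS[c("marrow", "cortex")] else c(bone = 1L)
  }
  out <- lapply(labels, function(l) as.numeric(pet$data[mask$labels == l]))
  names(out) <- names(labels)
  out
}

#' Segmentation overlap metrics
#'
#' True positive rate, false positive rate and Dice coefficient of a
#' predicted binary mask against a ground-truth binary mask.
#'
#' @param pred,truth binary [region_mask()]s (or logical arrays) on the
#'   same grid.
#' @return Named numeric vector `c(tpr, fpr, dice)`, each in `[0, 1]`.
#' @export
seg_metrics <- function(pred, truth) {
  p <- .as_logical_mask(pred)
  t <- .as_logical_mask(truth)
  stopifnot(identical(dim(p), dim(t)))
  if (!any(t)) stop("truth mask is empty: TPR is undefined")
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  c(tpr = tp / (tp + fn),
    fpr = if (fp + tn > 0) fp / (fp + tn) else 0,
    dice = 2 * tp / (2 * tp + fp + fn))
}
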