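# Two-Gaussian histogram auto-thresholding of body-masked CT.
#
# The whole-body CT intensity histogram is modelled as the sum of a fat and
# a muscle Gaussian,
#     y(x) = A_m exp(-((x - B_m)/c_m)^2) + A_f exp(-((x - B_f)/c_f)^2),
# bone being too small a population to form its own visible peak.  The bone
# pre-segmentation threshold is placed above the muscle centre at
#     threshold = B_m + (omega/2) (B_m - B_f),
# with omega a dimensionless weighting coefficient.  Note the width
# parameters c are the sqrt(2)-scaled Gaussian sigmas of this
# parameterization, not standard deviations.

#' Thresholding parameters
#'
#' @param omega dimensionless weighting coefficient placing the bone
#'   threshold above the muscle centre; must be > 0 to separate bone from
#'   muscle.
#' @param n_bins number of histogram bins (>= 32).
#' @param hu_range HU window `(low, high)` used for histogram fitting;
#'   chosen to exclude air and dense cortical bone, which the two-Gaussian
#'   soft-tissue model does not describe.
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(omega = 0.5, n_bins = 128L,
                             hu_range = c(-200, 300)) {
  if (omega <= 0) stop("omega must be > 0")
  n_bins <- as.integer(n_bins)
  if (n_bins < 32L) stop("n_bins must be >= 32")
  hu_range <- as.numeric(hu_range)
  if (length(hu_range) != 2L || diff(hu_range) <= 0)
    stop("hu_range must be an increasing (low, high) pair")
  structure(list(omega = omega, n_bins = n_bins, hu_range = hu_range),
            class = "threshold_params")
}

#' Histogram of body-masked CT intensities
#'
#' @param ct a [volume3d()] in HU.
#' @param body binary [region_mask()]; only voxels inside it are counted.
#' @param n_bins number of equal-width bins.
#' @param hu_range HU window; voxels outside it are dropped.
#' @return List with `bin_edges` (length `n_bins + 1`), `bin_mids` and
#'   `bin_counts` (length `n_bins`).
#' @export
build_histogram <- function(ct, body, n_bins = 128L,
                            hu_range = c(-200, 300)) {
  stopifnot(inherits(ct, "volume3d"), inherits(body, "region_mask"))
  check_same_grid(ct, body, "CT and body mask")
  if (!any(body$labels > 0)) stop("body mask is empty")
  vals <- ct$data[body$labels > 0]
  vals <- vals[vals >= hu_range[1] & vals <= hu_range[2]]
  edges <- seq(hu_range[1], hu_range[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(n_bins,
                          findInterval(vals, edges, rightmost.closed = TRUE)),
                     nbins = n_bins)
  list(bin_edges = edges,
       bin_mids = (edges[-1] + edges[-length(edges)]) / 2,
       bin_counts = counts)
}

# Initial guesses: the two tallest local maxima separated by >= 50 HU.
.init_two_peaks <- function(mids, counts, min_sep = 50) {
  n <- length(counts)
  is_peak <- counts > c(-Inf, counts[-n]) & counts >= c(counts[-1], -Inf) &
    counts > 0
  peaks <- which(is_peak)
  if (length(peaks) < 2L)
    stop("degenerate histogram: fewer than two local maxima; cannot initialize the two-Gaussian fit")
  peaks <- peaks[order(counts[peaks], decreasing = TRUE)]
  first <- peaks[1]
  rest <- peaks[abs(mids[peaks] - mids[first]) >= min_sep]
  if (length(rest) < 1L)
    stop(sprintf("degenerate histogram: no second peak at least %g HU from the first",
                 min_sep))
  second <- rest[1]
  idx <- sort(c(first, second))
  list(B = mids[idx], A = counts[idx],
       c = rep(max(abs(diff(mids[idx])) / 2, 10), 2))
}

#' Fit a two-Gaussian model to a CT histogram
#'
#' Nonlinear least squares (Levenberg-Marquardt with box constraints) of the
#' six parameters of the fat+muscle histogram model. Components are sorted
#' so that `B_f < B_m` (fat is darker than muscle in HU).
#'
#' @param bin_edges,bin_counts histogram as from [build_histogram()] (the
#'   midpoints of `bin_edges` are the abscissae).
#' @return An object of class `histogram_fit` with elements `A_m`, `B_m`,
#'   `c_m`, `A_f`, `B_f`, `c_f`, `residual_norm`, `bin_edges`, `bin_counts`.
#' @export
fit_two_gaussians <- function(bin_edges, bin_counts) {
  if (any(bin_counts < 0)) stop("bin counts must be non-negative")
  mids <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  init <- .init_two_peaks(mids, bin_counts)
  df <- data.frame(x = mids, y = bin_counts)
  lo <- c(A1 = 0, B1 = min(mids), c1 = 1e-3,
          A2 = 0, B2 = min(mids), c2 = 1e-3)
  hi <- c(A1 = Inf, B1 = max(mids), c1 = diff(range(mids)),
          A2 = Inf, B2 = max(mids), c2 = diff(range(mids)))
  start <- list(A1 = init$A[1], B1 = init$B[1], c1 = init$c[1],
                A2 = init$A[2], B2 = init$B[2], c2 = init$c[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A1 * exp(-((x - B1) / c1)^2) + A2 * exp(-((x - B2) / c2)^2),
      data = df, start = start, lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop(sprintf("two-Gaussian fit failed to converge: %s (init B = %s)",
                   conditionMessage(e),
                   paste(format(init$B), collapse = ", "))))
  p <- stats::coef(fit)
  comp <- if (p[["B1"]] <= p[["B2"]]) c(1L, 2L) else c(2L, 1L)
  f <- comp[1]; m <- comp[2]
  res <- sqrt(sum(stats::residuals(fit)^2))
  out <- structure(list(
    A_m = p[[paste0("A", m)]], B_m = p[[paste0("B", m)]],
    c_m = abs(p[[paste0("c", m)]]),
    A_f = p[[paste0("A", f)]], B_f = p[[paste0("B", f)]],
    c_f = abs(p[[paste0("c", f)]]),
    residual_norm = res,
    bin_edges = bin_edges, bin_counts = bin_counts),
    class = "histogram_fit")
  if (out$B_f >= out$B_m)
    stop("degenerate fit: fat and muscle centres coincide")
  out
}

#' @export
print.histogram_fit <- function(x, ...) {
  cat(sprintf(
    "<histogram_fit> fat: A=%.3g B=%.4g c=%.4g | muscle: A=%.3g B=%.4g c=%.4g | residual %.3g\n",
    x$A_f, x$B_f, x$c_f, x$A_m, x$B_m, x$c_m, x$residual_norm))
  invisible(x)
}

#' Bone pre-segmentation threshold from a histogram fit
#'
#' Returns `B_m + (omega/2) * (B_m - B_f)`: the threshold sits above the
#' muscle centre by a fraction of the fat-muscle separation, so it is
#' strictly increasing in `omega` and reduces to `B_m` as `omega -> 0`.
#'
#' @param fit a [fit_two_gaussians()] result.
#' @param omega weighting coefficient (> 0).
#' @return Threshold in HU.
#' @examples
#' f <- structure(list(B_m = 40, B_f = -90), class = "histogram_fit")
#' compute_threshold(f, omega = 0.5) # 72.5
#' @export
compute_threshold <- function(fit, omega = 0.5) {
  stopifnot(inherits(fit, "histogram_fit"))
  if (fit$B_m <= fit$B_f)
    stop("invalid fit: muscle centre must exceed fat centre")
  fit$B_m + omega / 2 * (fit$B_m - fit$B_f)
}

#' Pre-segment bone by HU thresholding
#'
#' Marks body voxels with HU >= `threshold`, then fills enclosed holes in
#' each axial slice so that low-HU marrow surrounded by the cortical shell
#' is part of the bone mask (set `fill_holes = FALSE` for the bare
#' threshold response).
#'
#' @param ct a [volume3d()] in HU.
#' @param body binary [region_mask()].
#' @param threshold HU threshold.
#' @param fill_holes fill slice-wise enclosed holes (default `TRUE`).
#' @return Binary [region_mask()] (1 = bone).
#' @export
presegment_bone <- function(ct, body, threshold, fill_holes = TRUE) {
  stopifnot(inherits(ct, "volume3d"), inherits(body, "region_mask"),
            is.finite(threshold))
  check_same_grid(ct, body, "CT and body mask")
  mask <- ct$data >= threshold & body$labels > 0
  if (fill_holes && any(mask))
    mask <- .fill_holes_slicewise(mask) & body$labels > 0
  region_mask(array(as.integer(mask), dim(mask)), spacing = ct$spacing)
}
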