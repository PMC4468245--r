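# Internal low-level image operations shared across modules.
# Arrays are (slice, row, col); 2D helpers operate on row x col matrices.

# Shift a 3D array by `off` voxels along `axis`, filling vacated voxels.
.shift3 <- function(a, off, axis, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(off) >= n) return(out)
  src <- dst <- lapply(d, seq_len)
  if (off >= 0) {
    src[[axis]] <- seq_len(n - off)
    dst[[axis]] <- seq_len(n - off) + off
  } else {
    src[[axis]] <- seq_len(n + off) - off
    dst[[axis]] <- seq_len(n + off)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

.gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with boundary renormalization (convolve the
# data and an all-ones array with the same kernel, then divide), so edge
# voxels are not darkened by the zero padding.
.gauss_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  k <- .gauss_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  num <- arr
  den <- array(1, dim(arr))
  for (axis in 1:3) {
    acc_n <- array(0, dim(arr))
    acc_d <- array(0, dim(arr))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      acc_n <- acc_n + k[j] * .shift3(num, off, axis)
      acc_d <- acc_d + k[j] * .shift3(den, off, axis)
    }
    num <- acc_n
    den <- acc_d
  }
  num / den
}

# 6-connected component labelling by iterative minimum-label propagation.
# Returns an array of component ids (NA outside the mask).
.label_components3 <- function(mask) {
  d <- dim(mask)
  lab <- array(Inf, d)
  lab[mask] <- as.numeric(which(mask))
  repeat {
    new <- lab
    for (axis in 1:3) {
      new <- pmin(new, .shift3(lab, 1L, axis, fill = Inf))
      new <- pmin(new, .shift3(lab, -1L, axis, fill = Inf))
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!mask] <- NA
  lab
}

.keep_largest_component3 <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- .label_components3(mask)
  counts <- table(lab[mask])
  keep <- as.numeric(names(counts)[which.max(counts)])
  arr <- !is.na(lab) & lab == keep
  arr[is.na(arr)] <- FALSE
  arr
}

# Fill 2D holes in every axial slice (frames must be EBImage's third dim).
.fill_holes_slicewise <- function(mask) {
  perm <- aperm(mask * 1, c(2, 3, 1))
  filled <- EBImage::fillHull(perm)
  aperm(filled, c(3, 1, 2)) > 0.5
}

# Otsu threshold over a plain numeric vector, returned on the original scale.
.otsu_values <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0)
    stop("cannot Otsu-split values with a single distinct level")
  scaled <- (values - rng[1]) / diff(rng)
  img <- EBImage::Image(matrix(scaled, ncol = 1))
  th <- EBImage::otsu(img, range = c(0, 1), levels = 256L)
  rng[1] + th * diff(rng)
}

# Signed distance from a binary 2D mask: positive inside, negative outside.
.signed_distance2 <- function(mask) {
  m <- EBImage::Image(mask * 1)
  inside <- EBImage::distmap(m)
  outside <- EBImage::distmap(EBImage::Image(1 - (mask * 1)))
  as.matrix(inside) - as.matrix(outside)
}

# Mean curvature div(grad phi / |grad phi|) by central differences on a 2D
# level-set function, with replicated borders.
.curvature2 <- function(phi) {
  pad <- function(m) {
    m <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
    cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
  }
  p <- pad(phi)
  nr <- nrow(phi); nc <- ncol(phi)
  ci <- 2:(nr + 1); cj <- 2:(nc + 1)
  px <- (p[ci + 1, cj] - p[ci - 1, cj]) / 2
  py <- (p[ci, cj + 1] - p[ci, cj - 1]) / 2
  pxx <- p[ci + 1, cj] - 2 * phi + p[ci - 1, cj]
  pyy <- p[ci, cj + 1] - 2 * phi + p[ci, cj - 1]
  pxy <- (p[ci + 1, cj + 1] - p[ci + 1, cj - 1] -
          p[ci - 1, cj + 1] + p[ci - 1, cj - 1]) / 4
  eps <- 1e-8
  (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) /
    (px^2 + py^2 + eps)^1.5
}

# Linear interpolation of a 3D array along one axis at new voxel-center
# coordinates (given in the source voxel index space, 1-based).
.interp_axis <- function(arr, new_coords, axis) {
  d <- dim(arr)
  old <- seq_len(d[axis])
  f <- function(v) stats::approx(old, v, xout = new_coords, rule = 2)$y
  if (axis == 1L) {
    res <- apply(arr, c(2, 3), f)
    if (is.null(dim(res))) res <- array(res, c(1, d[2], d[3]))
    res
  } else if (axis == 2L) {
    res <- apply(arr, c(1, 3), f)
    if (is.null(dim(res))) res <- array(res, c(1, d[1], d[3]))
    aperm(res, c(2, 1, 3))
  } else {
    res <- apply(arr, c(1, 2), f)
    if (is.null(dim(res))) res <- array(res, c(1, d[1], d[2]))
    aperm(res, c(2, 3, 1))
  }
}
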