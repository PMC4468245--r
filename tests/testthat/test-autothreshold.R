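test_that("histograms count exactly the body voxels inside the HU window", {
  d <- c(1, 40, 25)
  ct <- volume3d(array(40, d), unit = "HU")
  body <- region_mask(array(1L, d))
  h <- build_histogram(ct, body, n_bins = 50, hu_range = c(-200, 300))
  expect_equal(sum(h$bin_counts), prod(d))
  expect_equal(sum(h$bin_counts > 0), 1)     # single occupied bin
  expect_equal(max(h$bin_counts), prod(d))
  # voxels outside the window are dropped
  ct2 <- ct; ct2$data[1, 1, 1] <- 5000
  h2 <- build_histogram(ct2, body, 50, c(-200, 300))
  expect_equal(sum(h2$bin_counts), prod(d) - 1)
  expect_error(build_histogram(ct, region_mask(array(0L, d)), 50,
                               c(-200, 300)), "empty")
})

test_that("phantom histogram shows modes at the fat and muscle means", {
  case <- make_phantom(phantom_spec(seed = 3))
  body <- body_mask_from_pet(case$pet)
  h <- build_histogram(remove_bed(case$ct, body), body, 128, c(-200, 300))
  bin_w <- diff(h$bin_edges[1:2])
  top2 <- order(h$bin_counts, decreasing = TRUE)
  # the two dominant well-separated modes sit near -100 (fat) and 40 (muscle)
  peak1 <- h$bin_mids[top2[1]]
  peak2 <- h$bin_mids[top2[top2 %in% which(abs(h$bin_mids - peak1) > 50)][1]]
  peaks <- sort(c(peak1, peak2))
  expect_lt(abs(peaks[1] - (-100)), 2 * bin_w)
  expect_lt(abs(peaks[2] - 40), 2 * bin_w)
})

test_that("two-Gaussian fit recovers its own model to high precision", {
  x <- seq(-200, 300, length.out = 129)
  mids <- (x[-1] + x[-129]) / 2
  truth <- list(A_f = 900, B_f = -105, c_f = 30, A_m = 600, B_m = 42,
                c_m = 22)
  y <- truth$A_f * exp(-((mids - truth$B_f) / truth$c_f)^2) +
       truth$A_m * exp(-((mids - truth$B_m) / truth$c_m)^2)
  fit <- fit_two_gaussians(x, y)
  for (p in names(truth))
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-6 * max(y))
})

test_that("fit recovers generator centres from sampled mixtures", {
  set.seed(42)
  n <- 1e5
  draws <- c(rnorm(0.6 * n, -100, 20), rnorm(0.4 * n, 40, 15))
  edges <- seq(-200, 120, length.out = 161)
  counts <- tabulate(findInterval(draws, edges, rightmost.closed = TRUE),
                     nbins = 160)
  fit <- fit_two_gaussians(edges, counts)
  expect_lt(abs(fit$B_f - (-100)), 2)
  expect_lt(abs(fit$B_m - 40), 2)
  # the sqrt(2)-scaled widths correspond to the generator sigmas
  expect_equal(fit$c_f / sqrt(2), 20, tolerance = 0.1)
  expect_equal(fit$c_m / sqrt(2), 15, tolerance = 0.1)
})

test_that("degenerate histograms are rejected with informative errors", {
  edges <- seq(0, 100, length.out = 51)
  expect_error(fit_two_gaussians(edges, rep(5, 50)), "degenerate")
  one_peak <- dnorm((edges[-1] + edges[-51]) / 2, 50, 5)
  expect_error(fit_two_gaussians(edges, one_peak), "degenerate")
  expect_error(fit_two_gaussians(edges, rep(-1, 50)), "non-negative")
})

test_that("threshold formula, limits and monotonicity", {
  f <- structure(list(B_m = 40, B_f = -90), class = "histogram_fit")
  expect_equal(compute_threshold(f, omega = 0.5), 72.5)
  expect_equal(compute_threshold(f, omega = 1e-12), 40, tolerance = 1e-6)
  omegas <- seq(0.1, 2, by = 0.1)
  th <- vapply(omegas, function(w) compute_threshold(f, w), numeric(1))
  expect_true(all(diff(th) > 0))
  bad <- structure(list(B_m = -90, B_f = 40), class = "histogram_fit")
  expect_error(compute_threshold(bad), "exceed")
})

test_that("bone pre-segmentation thresholds and fills as specified", {
  case <- make_phantom(noiseless_spec(seed = 1))
  body <- case$truth_body
  # threshold between muscle and marrow captures the whole bone
  pre <- presegment_bone(case$ct, body, 75)
  expect_identical(pre$labels, array(as.integer(case$truth_bone$labels > 0),
                                     dim(pre$labels)))
  # threshold above marrow captures only the cortical shell, which hole
  # filling closes back to the full bone
  pre300 <- presegment_bone(case$ct, body, 300)
  expect_identical(pre300$labels,
                   array(as.integer(case$truth_bone$labels > 0),
                         dim(pre300$labels)))
  raw300 <- presegment_bone(case$ct, body, 300, fill_holes = FALSE)
  expect_identical(raw300$labels,
                   array(as.integer(case$truth_bone$labels == 2),
                         dim(raw300$labels)))
  # extreme thresholds: empty mask / whole body
  expect_equal(sum(presegment_bone(case$ct, body, 1e5)$labels), 0)
  allb <- presegment_bone(case$ct, body, -2000)
  expect_identical(allb$labels, body$labels)
  # masks shrink monotonically with the threshold
  sizes <- vapply(c(-2000, 0, 100, 400, 1e5), function(th)
    sum(presegment_bone(case$ct, body, th, fill_holes = FALSE)$labels),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("fit residual vanishes as sampling noise vanishes", {
  edges <- seq(-200, 150, length.out = 141)
  mids <- (edges[-1] + edges[-141]) / 2
  clean <- 800 * exp(-((mids + 100) / 28)^2) + 500 * exp(-((mids - 40) / 21)^2)
  res <- vapply(c(20, 5, 0), function(sd) {
    set.seed(1)
    y <- pmax(0, clean + rnorm(length(clean), 0, sd))
    fit_two_gaussians(edges, y)$residual_norm
  }, numeric(1))
  expect_true(all(diff(res) < 0))
  expect_lt(res[3], 1e-6)
})

test_that("centre recovery is within one bin width over seeded replicates", {
  errs <- t(vapply(1:20, function(s) {
    set.seed(s)
    n <- 2e4
    draws <- c(rnorm(0.6 * n, -100, 20), rnorm(0.4 * n, 40, 15))
    edges <- seq(-200, 120, length.out = 129)
    counts <- tabulate(findInterval(draws, edges, rightmost.closed = TRUE),
                       nbins = 128)
    fit <- fit_two_gaussians(edges, counts)
    c(abs(fit$B_f + 100), abs(fit$B_m - 40))
  }, numeric(2)))
  bin_w <- 320 / 128
  expect_lt(median(errs[, 1]), bin_w)
  expect_lt(median(errs[, 2]), bin_w)
})
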