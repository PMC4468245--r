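test_that("region means are exact and symmetric", {
  img <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  inside <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2, byrow = TRUE)
  m <- region_means(img, inside)
  expect_equal(m$c1, 1.5)
  expect_equal(m$c2, 3.5)
  swapped <- region_means(img, !inside)
  expect_equal(swapped$c1, m$c2)
  expect_equal(swapped$c2, m$c1)
  expect_error(region_means(img, matrix(TRUE, 2, 2)), "outside region")
  expect_error(region_means(img, matrix(FALSE, 2, 2)), "inside region")
})

test_that("the augmented energy evaluates as defined", {
  # true partition of a two-level image has zero fidelity at epsilon = 0
  img <- matrix(c(0, 0, 700, 700), 1, 4)
  inside <- matrix(c(FALSE, FALSE, TRUE, TRUE), 1, 4)
  expect_equal(cv_energy(img, inside, cv_params(epsilon = 0)), 0)
  # one misassigned pixel raises it
  bad <- matrix(c(FALSE, TRUE, TRUE, TRUE), 1, 4)
  expect_gt(cv_energy(img, bad, cv_params(epsilon = 0)), 0)
  # hand evaluation with the threshold term: image [0,0,10,10], inside the
  # two tens, eps = 1, Th = 5 -> fidelity 0 + 1 * sum (I - 5)^2 = 4 * 25
  img2 <- matrix(c(0, 0, 10, 10), 1, 4)
  in2 <- matrix(c(FALSE, FALSE, TRUE, TRUE), 1, 4)
  expect_equal(cv_energy(img2, in2, cv_params(epsilon = 1, thresh = 5)), 100)
  expect_error(cv_energy(img2, in2, cv_params(epsilon = 1)), "thresh")
})

test_that("contour evolution descends the energy and fixes true partitions", {
  set.seed(2)
  img <- matrix(c(rnorm(8, 0, 0.1), rnorm(8, 10, 0.1)), 4, 4)
  truth <- matrix(c(rep(FALSE, 8), rep(TRUE, 8)), 4, 4)
  p0 <- cv_params(epsilon = 0, mu = 0)
  # init = truth is a fixed point
  out <- evolve_contour(img, truth, p0)
  expect_identical(unclass(out)[, ], truth)
  expect_true(attr(out, "converged"))
  # init = perturbed truth converges back, with non-increasing energy
  init <- truth; init[1, 4] <- TRUE; init[4, 1] <- TRUE
  out2 <- evolve_contour(img, init, p0)
  expect_identical(unclass(out2)[, ], truth)
  tr <- attr(out2, "energy_trace")
  expect_true(all(diff(tr) <= 1e-9))
  expect_lte(tr[length(tr)], tr[1])
})

test_that("evolution with mu = 0 attains the exhaustive-search minimum", {
  p0 <- cv_params(epsilon = 0, mu = 0)
  set.seed(7)
  for (rep in 1:6) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    lowhigh <- sample(c(0, 10), nr * nc, replace = TRUE)
    if (length(unique(lowhigh)) < 2) lowhigh[1] <- 10 - lowhigh[1]
    img <- matrix(lowhigh + rnorm(nr * nc, 0, 0.3), nr, nc)
    init <- img > median(img)
    if (!any(init) || all(init)) next
    out <- evolve_contour(img, init, p0)
    expect_equal(cv_energy(img, out, p0), brute_force_cv_min(img),
                 tolerance = 1e-9)
  }
})

test_that("with mu = 0 the converged mask is the nearest-mean classification", {
  set.seed(11)
  img <- matrix(rnorm(25, 5, 4), 5, 5)
  init <- img > median(img)
  out <- evolve_contour(img, init, cv_params(epsilon = 0, mu = 0))
  m <- region_means(img, out)
  expect_identical(unclass(out)[, ], (img - m$c1)^2 <= (img - m$c2)^2)
})

test_that("curvature-regularized evolution smooths away salt noise", {
  set.seed(3)
  img <- matrix(0, 24, 24)
  img[8:17, 8:17] <- 10
  img <- img + rnorm(576, 0, 1)
  truth <- matrix(FALSE, 24, 24); truth[8:17, 8:17] <- TRUE
  init <- img > 5
  out <- evolve_contour(img, init, cv_params(epsilon = 0, mu = NULL,
                                             max_iters = 100))
  agreement <- mean(out == truth)
  expect_gt(agreement, 0.97)
})

test_that("vanishing contours raise errors carrying the iteration", {
  # constant image: both regions fit equally, ties collapse into one region
  img <- matrix(10, 2, 2)
  init <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_error(evolve_contour(img, init, cv_params(epsilon = 0, mu = 0)),
               "iteration")
})

test_that("slice-wise bone segmentation recovers phantom truth", {
  case <- make_phantom(noiseless_spec(seed = 1))
  body <- body_mask_from_pet(case$pet)
  ct <- remove_bed(case$ct, body)
  bone <- segment_bone_volume(ct, body, 75, cv_params())
  m <- seg_metrics(bone, case$truth_bone)
  expect_equal(m[["dice"]], 1.0)
  # deterministic
  bone2 <- segment_bone_volume(ct, body, 75, cv_params())
  expect_identical(bone$labels, bone2$labels)
  # empty body -> empty bone
  empty <- region_mask(array(0L, dim(ct$data)), ct$spacing)
  expect_equal(sum(segment_bone_volume(ct, empty, 75)$labels), 0)
})

test_that("bone segmentation stays accurate under CT noise", {
  case <- make_phantom(phantom_spec(
    seed = 5, tissue_sds = c(fat = 20, muscle = 20, marrow = 20,
                             cortex = 20)))
  body <- body_mask_from_pet(case$pet)
  ct <- remove_bed(case$ct, body)
  h <- build_histogram(ct, body, 128, c(-200, 300))
  fit <- fit_two_gaussians(h$bin_edges, h$bin_counts)
  thr <- compute_threshold(fit, 0.5)
  bone <- segment_bone_volume(ct, body, thr, cv_params())
  expect_gte(seg_metrics(bone, case$truth_bone)[["dice"]], 0.95)
})

test_that("cortex/marrow splitting is exact on noiseless phantoms", {
  case <- make_phantom(noiseless_spec(seed = 2))
  seg <- split_cortex_marrow(case$ct, case$truth_bone)
  truth <- case$truth_bone$labels
  expect_identical(seg$labels, truth)
  # labels partition the bone mask
  expect_equal(sum(seg$labels == 1) + sum(seg$labels == 2),
               sum(truth > 0))
  # fixed cutoff above all bone HU -> everything marrow
  allm <- split_cortex_marrow(case$ct, case$truth_bone, "fixed",
                              cutoff_hu = 5000)
  expect_equal(sum(allm$labels == 2), 0)
  expect_equal(sum(allm$labels == 1), sum(truth > 0))
  # single-valued bone cannot be Otsu-split
  flat <- volume3d(array(100, dim(case$ct$data)), case$ct$spacing, "HU")
  expect_error(split_cortex_marrow(flat, case$truth_bone), "distinct")
})

test_that("mask transfer extracts per-label PET values faithfully", {
  case <- make_phantom(noiseless_spec(seed = 3))
  suv <- suv_map(case$pet, case$meta, "bw")
  vals <- transfer_mask_to_pet(case$truth_bone, suv$volume)
  expect_named(vals, c("marrow", "cortex"))
  expect_length(vals$cortex, sum(case$truth_bone$labels == 2))
  expect_equal(unique(round(vals$cortex, 10)), 0.86)
  expect_equal(unique(round(vals$marrow, 10)), 0.93)
  # uniform PET -> every extracted value equals it; empty label -> empty
  unif <- volume3d(array(4.2, dim(case$pet$data)), case$pet$spacing, "SUV")
  v2 <- transfer_mask_to_pet(case$truth_bone, unif,
                             labels = c(cortex = 2L, unused = 9L))
  expect_true(all(v2$cortex == 4.2))
  expect_length(v2$unused, 0)
  small <- volume3d(array(0, c(2, 2, 2)), unit = "SUV")
  expect_error(transfer_mask_to_pet(case$truth_bone, small), "mismatch")
})

test_that("segmentation metrics match their definitions", {
  d <- c(1, 10, 1)
  truth <- vector_mask(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0))
  pred_same <- truth
  expect_equal(seg_metrics(pred_same, truth),
               c(tpr = 1, fpr = 0, dice = 1))
  pred_disjoint <- vector_mask(c(0, 0, 1, 1, 0, 0, 0, 0, 0, 0))
  m <- seg_metrics(pred_disjoint, truth)
  expect_equal(m[["tpr"]], 0)
  expect_equal(m[["dice"]], 0)
  # |pred| = |truth| = 2 with overlap 1 -> Dice 0.5
  pred_half <- vector_mask(c(1, 0, 1, 0, 0, 0, 0, 0, 0, 0))
  m2 <- seg_metrics(pred_half, truth)
  expect_equal(m2[["dice"]], 0.5)
  expect_equal(m2[["fpr"]], 1 / 8)
  # Dice is symmetric
  expect_equal(seg_metrics(pred_half, truth)[["dice"]],
               seg_metrics(truth, pred_half)[["dice"]])
  empty <- vector_mask(rep(0, 10))
  expect_error(seg_metrics(pred_half, empty), "undefined")
})
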