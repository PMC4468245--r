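test_that("DANP cutoff is the ceiling order statistic of the normals", {
  expect_equal(danp_cutoff(1:100, 0.95), 95)
  expect_equal(sum(classify_abnormal(1:100, danp_cutoff(1:100, 0.95))), 5)
  # danp = 1 uses the maximum, giving perfect specificity on the normals
  expect_equal(danp_cutoff(1:100, 1), 100)
  expect_false(any(classify_abnormal(1:100, danp_cutoff(1:100, 1))))
  # tied normals: cutoff is the common value and all are classified normal
  tied <- rep(0.7, 30)
  expect_equal(danp_cutoff(tied, 0.5), 0.7)
  expect_false(any(classify_abnormal(tied, danp_cutoff(tied, 0.5))))
  expect_error(danp_cutoff(numeric(0), 0.95), "non-empty")
  expect_error(danp_cutoff(1:10, 0), "danp")
})

test_that("classification is strict and rank-invariant", {
  expect_false(classify_abnormal(1.2, 1.2))      # value == cutoff -> normal
  expect_true(classify_abnormal(1.2 + 1e-12, 1.2))
  expect_false(any(classify_abnormal(c(0.1, 0.5, 0.9), 1)))
  # invariance under a strictly monotone transform of values and cutoff
  set.seed(1)
  vals <- rnorm(50); cut <- 0.3
  expect_identical(classify_abnormal(vals, cut),
                   classify_abnormal(exp(vals), exp(cut)))
})

test_that("confusion metrics match hand-computed rates", {
  # 43 detected of 67 diseased, 3 false positives among 40 controls
  pred <- c(rep(TRUE, 43), rep(FALSE, 24), rep(TRUE, 3), rep(FALSE, 37))
  truth <- c(rep(TRUE, 67), rep(FALSE, 40))
  r <- confusion_metrics(pred, truth)
  expect_equal(round(100 * r$sensitivity, 2), 64.18)
  expect_equal(round(100 * r$ppv, 2), 93.48)
  expect_equal(r$tp + r$fp + r$tn + r$fn, 107)
  expect_equal(r$accuracy, (43 + 37) / 107)
  # perfect prediction
  p <- confusion_metrics(truth, truth)
  expect_equal(c(p$sensitivity, p$specificity, p$ppv, p$npv, p$accuracy),
               rep(1, 5))
  # undefined rates are NA, not zero
  none <- confusion_metrics(rep(FALSE, 5), rep(FALSE, 5))
  expect_true(is.na(none$sensitivity))
  expect_true(is.na(none$ppv))
  expect_error(confusion_metrics(TRUE, c(TRUE, FALSE)), "length")
})

test_that("Welch t-test agrees with the direct formula", {
  welch_direct <- function(a, b) {
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    list(t = t, p = 2 * pt(-abs(t), df))
  }
  set.seed(5)
  for (rep in 1:10) {
    a <- rnorm(sample(5:30, 1), 0, 1.5)
    b <- rnorm(sample(5:30, 1), 0.8, 0.7)
    got <- welch_ttest(a, b)
    want <- welch_direct(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  # identical samples
  x <- c(1, 2, 3)
  same <- welch_ttest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # shift changes t but antisymmetrically; p unchanged
  ab <- welch_ttest(x, x + 10)
  ba <- welch_ttest(x + 10, x)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  expect_error(welch_ttest(1, c(1, 2)), "n >= 2")
})

test_that("ROC/AUC equals the pairwise concordance oracle", {
  concordance <- function(scores, truth) {
    pos <- scores[truth]; neg <- scores[!truth]
    gr <- outer(pos, neg, ">"); eq <- outer(pos, neg, "==")
    mean(gr + 0.5 * eq)
  }
  set.seed(6)
  for (rep in 1:15) {
    n <- sample(6:50, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(truth) || all(truth)) next
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties sometimes
    r <- roc_auc(scores, truth)
    expect_equal(r$auc, concordance(scores, truth), tolerance = 1e-12)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_true(all(diff(r$points$fpr) >= 0))
  }
  # separable and degenerate cases
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13),
                       c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both")
})

test_that("null cohorts average to AUC one-half; AUC bands grade correctly", {
  aucs <- vapply(1:100, function(s) {
    set.seed(s)
    roc_auc(rnorm(40), rep(c(TRUE, FALSE), each = 20))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
  # cross-check against an independent ROC implementation
  skip_if_not_installed("pROC")
  set.seed(99)
  sc <- rnorm(60); tr <- rep(c(TRUE, FALSE), 30)
  ref <- as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(sc, tr)$auc, ref, tolerance = 1e-12)
  expect_identical(auc_grade(0.84), "Good")
  expect_identical(auc_grade(0.95), "Excellent")
  expect_identical(auc_grade(0.75), "Worthless")
  expect_identical(auc_grade(0.65), "Not good")
  expect_identical(auc_grade(0.2), "Fail")
})

test_that("cohort tables enforce unique patient-group assignment", {
  tab <- cohort_table(c("a", "a", "b"), c("normal", "normal", "infection"),
                      "cortex", "bw", c(1.0, 1.2, 1.0), c(0.1, 0.05, 0.4))
  expect_s3_class(tab, "cohort_table")
  expect_error(cohort_table(c("a", "a"), c("normal", "infection"),
                            "cortex", "bw", c(1, 1.2), c(0.1, 0.2)),
               "more than one group")
  expect_error(cohort_table("a", "sick", "cortex", "bw", 1, 0.1), "labels")
})

test_that("the DANP sweep achieves its specificity by construction", {
  set.seed(8)
  n_norm <- 100; n_fuo <- 30
  t_grid <- seq(0.4, 1.2, by = 0.2)
  make_rows <- function(ids, group, shift) {
    do.call(rbind, lapply(ids, function(i) {
      vals <- plogis(rnorm(length(t_grid), shift, 1))  # distinct, in (0,1)
      data.frame(patient_id = sprintf("%s%03d", group, i), group = group,
                 region = "cortex", mode = "bw", t = t_grid,
                 value = sort(vals, decreasing = TRUE))
    }))
  }
  rows <- rbind(make_rows(1:n_norm, "normal", 0),
                make_rows(1:n_fuo, "infection", 1.5))
  tab <- cohort_table(rows$patient_id, rows$group, rows$region, rows$mode,
                      rows$t, rows$value)
  sw <- danp_sweep(tab, danp_grid = c(1, 0.95, 0.9), t_grid = t_grid)
  expect_true(all(sw$specificity >= rep(c(1, 0.95, 0.9),
                                        each = length(t_grid)) - 1e-12))
  # with continuous distinct values the 0.95 level is attained exactly
  expect_true(all(abs(sw$specificity[sw$danp == 0.95] - 0.95) < 1e-12))
  expect_true(all(sw$tp + sw$fp + sw$tn + sw$fn == n_norm + n_fuo))
  expect_true("detect_infection" %in% names(sw))
  expect_equal(sw$detect_infection, sw$sensitivity)  # single disease group
})

test_that("sensitivity grows as DANP relaxes when disease dominates normals", {
  set.seed(10)
  t_grid <- c(0.8, 1.0)
  rows <- rbind(
    do.call(rbind, lapply(1:40, function(i)
      data.frame(patient_id = paste0("n", i), group = "normal",
                 region = "cortex", mode = "bw", t = t_grid,
                 value = sort(runif(2), decreasing = TRUE)))),
    do.call(rbind, lapply(1:20, function(i)
      data.frame(patient_id = paste0("d", i), group = "neoplasm",
                 region = "cortex", mode = "bw", t = t_grid,
                 value = sort(runif(2) + 0.5, decreasing = TRUE)))))
  tab <- cohort_table(rows$patient_id, rows$group, rows$region, rows$mode,
                      rows$t, rows$value)
  sw <- danp_sweep(tab, danp_grid = c(1, 0.95, 0.9, 0.85, 0.8),
                   t_grid = t_grid)
  for (t in t_grid) {
    sens <- sw$sensitivity[abs(sw$t - t) < 1e-9]
    expect_true(all(diff(sens) >= 0))  # danp_grid is decreasing
  }
})
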