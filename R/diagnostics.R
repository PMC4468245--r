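# Diagnostic evaluation: DANP cutoff selection, classification,
# confusion-matrix metrics, Welch t-tests, ROC/AUC with qualitative grading.
#
# DANP ("discriminative ability for the normal person") is the fraction of
# normal subjects a cutoff classifies correctly.  The cutoff is the
# ceil(danp * n)-th order statistic of the normal subjects' biomarker
# values, and a subject is called abnormal iff its value is strictly
# greater than the cutoff, so exactly ceil(danp * n) of the defining
# normals are classified normal when their values are distinct.

#' DANP classification cutoff
#'
#' Returns the k-th order statistic of the normal subjects' biomarker
#' values with `k = ceiling(danp * n)`, so that (with distinct values)
#' exactly `k` normals satisfy `value <= cutoff` and are classified normal
#' under the strict-greater abnormality rule.
#'
#' @param normal_values biomarker values of the normal subjects (non-empty).
#' @param danp target fraction of correctly identified normals, in (0, 1].
#' @return The cutoff value.
#' @examples
#' danp_cutoff(1:100, 0.95) # 95
#' @export
danp_cutoff <- function(normal_values, danp = 0.95) {
  if (length(normal_values) == 0L) stop("normal_values must be non-empty")
  if (danp <= 0 || danp > 1) stop("danp must lie in (0, 1]")
  k <- ceiling(danp * length(normal_values))
  sort(normal_values)[k]
}

#' Classify subjects against a cutoff
#'
#' A subject is abnormal iff its biomarker value is strictly greater than
#' the cutoff; a value equal to the cutoff is normal.
#'
#' @param values biomarker values.
#' @param cutoff finite cutoff.
#' @return Logical vector, `TRUE` = abnormal.
#' @export
classify_abnormal <- function(values, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  values > cutoff
}

#' Confusion-matrix metrics for a binary diagnosis
#'
#' Computes TP/FP/TN/FN counts and sensitivity, specificity, positive and
#' negative predictive values and accuracy. A rate whose denominator is
#' zero is reported as `NA` (absent), not as zero.
#'
#' @param pred logical vector, `TRUE` = predicted diseased (abnormal).
#' @param truth logical vector of the same length, `TRUE` = diseased.
#' @return An object of class `diagnostic_report`: list with `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`
#'   (fractions in `[0, 1]` or `NA`).
#' @examples
#' # 43 of 67 diseased detected, all 40 controls negative
#' r <- confusion_metrics(c(rep(TRUE, 43), rep(FALSE, 24 + 40)),
#'                        c(rep(TRUE, 67), rep(FALSE, 40)))
#' round(100 * r$sensitivity, 2) # 64.18
#' @export
confusion_metrics <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 ppv = rate(tp, tp + fp),
                 npv = rate(tn, tn + fn),
                 accuracy = rate(tp + tn, tp + fp + tn + fn)),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("<diagnostic_report> tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sens %.2f%%  spec %.2f%%  ppv %.2f%%  npv %.2f%%  acc %.2f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$ppv,
              100 * x$npv, 100 * x$accuracy))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) t statistic with Satterthwaite degrees of
#' freedom and a two-sided p-value.
#'
#' @param sample_a,sample_b numeric samples, each with n >= 2 and nonzero
#'   variance.
#' @return List with `t`, `df`, `p`.
#' @export
welch_ttest <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("each sample needs n >= 2")
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b))
      return(list(t = 0, df = length(sample_a) + length(sample_b) - 2, p = 1))
    stop("both samples are constant with different means; t is undefined")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Qualitative AUC grade
#'
#' Bands: AUC at or above 0.9 "Excellent", 0.8 "Good", 0.7 "Worthless",
#' 0.6 "Not good", below that "Fail".
#'
#' @param auc AUC value in `[0, 1]`.
#' @return Character grade.
#' @export
auc_grade <- function(auc) {
  stopifnot(auc >= 0, auc <= 1)
  if (auc >= 0.9) "Excellent"
  else if (auc >= 0.8) "Good"
  else if (auc >= 0.7) "Worthless"
  else if (auc >= 0.6) "Not good"
  else "Fail"
}

#' ROC curve and AUC
#'
#' Builds the ROC curve over all distinct score thresholds (abnormal iff
#' score > threshold), computes the AUC by the trapezoid rule -- equal to
#' the tie-corrected Mann-Whitney concordance probability -- and attaches
#' the qualitative grade.
#'
#' @param scores numeric biomarker scores.
#' @param truth logical vector, `TRUE` = diseased; both classes must occur.
#' @return An object of class `roc_curve`: list with `points` (data frame
#'   of `fpr`, `tpr` from (0,0) to (1,1)), `auc`, `grade`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  if (!any(truth) || all(truth))
    stop("truth must contain both diseased and normal subjects")
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  tpr <- vapply(thr, function(th) sum(scores >= th & truth) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & !truth) / n_neg,
                numeric(1))
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, grade = auc_grade(auc)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%s), %d points\n",
              x$auc, x$grade, nrow(x$points)))
  invisible(x)
}

#' Build a cohort biomarker table
#'
#' Long-format table of per-patient biomarker values keyed by region, SUV
#' normalization mode and PIBGM cutoff.
#'
#' @param patient_id character vector.
#' @param group group label per patient, from `normal`, `inflammatory`,
#'   `infection`, `neoplasm`.
#' @param region,mode,t keys of each biomarker value.
#' @param value biomarker value (e.g. PIBGM or mean SUV).
#' @return A `data.frame` of class `cohort_table`.
#' @export
cohort_table <- function(patient_id, group, region, mode, t, value) {
  groups <- c("normal", "inflammatory", "infection", "neoplasm")
  if (!all(group %in% groups))
    stop("group labels must be among: ", paste(groups, collapse = ", "))
  df <- data.frame(patient_id = as.character(patient_id),
                   group = as.character(group),
                   region = as.character(region),
                   mode = as.character(mode),
                   t = as.numeric(t), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  key <- unique(df[, c("patient_id", "group")])
  if (anyDuplicated(key$patient_id))
    stop("a patient id appears with more than one group label")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' DANP sweep over cutoff grids
#'
#' For each `(danp, t)` pair: derive the classification cutoff from the
#' normal subjects' biomarker values at that `t`, classify the whole
#' cohort, and report confusion metrics plus per-etiology detection rates.
#' By construction specificity is at least `danp` on the defining normals.
#'
#' @param cohort a [cohort_table()] containing normals and at least one
#'   disease group.
#' @param danp_grid DANP levels in (0, 1].
#' @param t_grid PIBGM cutoffs present in the cohort table.
#' @param region,mode which biomarker rows to use.
#' @return Data frame with one row per `(danp, t)`: cutoff, counts, the
#'   five rates, and detection rates for each disease group present.
#' @export
danp_sweep <- function(cohort, danp_grid = c(1, 0.95, 0.9, 0.85),
                       t_grid = default_t_grid(),
                       region = "cortex", mode = "bw") {
  stopifnot(inherits(cohort, "cohort_table"))
  sub <- cohort[cohort$region == region & cohort$mode == mode, ]
  if (!any(sub$group == "normal"))
    stop("cohort contains no normal subjects")
  if (all(sub$group == "normal"))
    stop("cohort contains no disease group")
  disease_groups <- setdiff(unique(sub$group), "normal")
  rows <- list()
  for (danp in danp_grid) for (t in t_grid) {
    at_t <- sub[abs(sub$t - t) < 1e-9, ]
    if (nrow(at_t) == 0L)
      stop(sprintf("no biomarker values at t = %g", t))
    normals <- at_t$value[at_t$group == "normal"]
    cut <- danp_cutoff(normals, danp)
    pred <- classify_abnormal(at_t$value, cut)
    truth <- at_t$group != "normal"
    cm <- confusion_metrics(pred, truth)
    det <- vapply(disease_groups, function(g) {
      idx <- at_t$group == g
      if (!any(idx)) return(NA_real_)
      mean(pred[idx])
    }, numeric(1))
    row <- data.frame(danp = danp, t = t, cutoff = cut,
                      tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
                      sensitivity = cm$sensitivity,
                      specificity = cm$specificity,
                      ppv = cm$ppv, npv = cm$npv, accuracy = cm$accuracy)
    for (g in disease_groups) row[[paste0("detect_", g)]] <- det[[g]]
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
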