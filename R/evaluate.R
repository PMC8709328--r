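#' Confusion-matrix performance metrics
#'
#' Standard binary-classification metrics from the four confusion counts.
#' Undefined ratios (empty denominators) are reported as `NA`, never as 0.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return list of class `confusion_metrics`: `tp`, `fp`, `tn`, `fn`, `n`,
#'   `sensitivity`, `specificity`, `ppv` (precision), `npv`, `accuracy`,
#'   `f1`, all as proportions in `[0, 1]`.
#' @export
#' @examples
#' m <- confusion_metrics(tp = 44, fp = 11, tn = 27, fn = 8)
#' m$ppv       # 0.8
#' m$accuracy  # 71/90
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
              sensitivity = ratio(tp, tp + fn),
              specificity = ratio(tn, tn + fp),
              ppv = ratio(tp, tp + fp),
              npv = ratio(tn, tn + fn),
              accuracy = (tp + tn) / n,
              f1 = ratio(2 * tp, 2 * tp + fp + fn))
  class(out) <- "confusion_metrics"
  out
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("Confusion counts: TP %d  FP %d  TN %d  FN %d  (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n))
  fmt <- function(v) if (is.na(v)) "  --" else format_pct(v)
  cat(sprintf("  Se %s  Sp %s  PPV %s  NPV %s  accuracy %s  F1 %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv),
              fmt(x$npv), fmt(x$accuracy), fmt(x$f1)))
  invisible(x)
}

#' Area under the ROC curve by pairwise concordance
#'
#' The Mann-Whitney estimator: the probability that a randomly chosen
#' positive scores on the positive side of a randomly chosen negative, ties
#' counted one half. This equals trapezoidal integration of the empirical
#' ROC curve over all thresholds. For the AREA statistic malignant lesions
#' score LOWER (more negative) than benign ones, so use
#' `direction = "lower"` there.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) class labels, `TRUE` = positive.
#' @param direction `"higher"` if positives are expected to score higher
#'   (default), `"lower"` otherwise.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE))          # 0.75
#' auroc(c(-25, -7), c(TRUE, FALSE), direction = "lower")     # 1
auroc <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("missing values in ROC input")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (direction == "lower") scores <- -scores
  r <- rank(scores)                       # midranks handle ties as 1/2
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve and Youden-optimal cutoff
#'
#' Sweeps every observed score as a candidate threshold. With
#' `direction = "lower"` (the AREA convention) a lesion is called positive
#' when its score is at or below the threshold; with `"higher"`, at or
#' above. The operating cutoff maximizes the Youden index `Se + Sp - 1`;
#' ties are broken towards the higher-sensitivity threshold.
#'
#' @inheritParams auroc
#' @return list of class `roc_result`: `thresholds`, `se`, `sp` (parallel
#'   vectors), `auroc`, `youden_cutoff`, `direction`.
#' @export
#' @examples
#' r <- roc_curve(c(-30, -25, -10, -2), c(TRUE, TRUE, FALSE, FALSE),
#'                direction = "lower")
#' r$youden_cutoff
roc_curve <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  thr <- sort(unique(scores))
  pos_call <- if (direction == "lower") {
    function(t) scores <= t
  } else {
    function(t) scores >= t
  }
  se <- vapply(thr, function(t) sum(pos_call(t) & labels) / n1, numeric(1))
  sp <- vapply(thr, function(t) sum(!pos_call(t) & !labels) / n0, numeric(1))
  j <- se + sp - 1
  best <- which(j == max(j))
  best <- best[which.max(se[best])]       # ties -> higher sensitivity
  structure(list(thresholds = thr, se = se, sp = sp,
                 auroc = auroc(scores, labels, direction),
                 youden_cutoff = thr[best], direction = direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d thresholds (positives score %s)\n",
              length(x$thresholds), x$direction))
  i <- match(x$youden_cutoff, x$thresholds)
  cat(sprintf("  AUROC %.3f; Youden cutoff %.2f (Se %s, Sp %s)\n",
              x$auroc, x$youden_cutoff, format_pct(x$se[i]),
              format_pct(x$sp[i])))
  invisible(x)
}

#' Youden-optimal cutoff
#'
#' @param roc a [roc_curve()] result.
#' @return the threshold maximizing `Se + Sp - 1`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  roc$youden_cutoff
}

#' Compare two groups of continuous measurements
#'
#' The conventional clinical-statistics gate: each group is tested for
#' normality (Shapiro-Wilk at the 0.05 level); if both pass, Student's
#' t-test (pooled variance) is used, otherwise the Mann-Whitney (Wilcoxon
#' rank-sum) test. Two-sided throughout.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return list: `p_value`, `test` (`"t"` or `"mann-whitney"`), `statistic`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))$p_value  # exact rank test: 0.1
compare_groups <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  normal <- function(v) {
    # below n = 4 the Shapiro test has essentially no power; treat such
    # groups as non-normal and fall through to the rank test
    if (length(v) < 4 || stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value >= 0.05
  }
  if (normal(values_a) && normal(values_b)) {
    ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
    list(p_value = ht$p.value, test = "t",
         statistic = unname(ht$statistic))
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = NULL))
    list(p_value = ht$p.value, test = "mann-whitney",
         statistic = unname(ht$statistic))
  }
}

#' Compare two proportions
#'
#' Two-sided pooled-variance z test, computed as the chi-square test without
#' continuity correction (the two are identical). A Fisher exact test is
#' available for small counts.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @param method `"z"` (default) or `"fisher"`.
#' @return two-sided p-value.
#' @export
#' @examples
#' two_proportion_test(66, 91, 71, 91)  # ~0.39
two_proportion_test <- function(k1, n1, k2, n2, method = c("z", "fisher")) {
  method <- match.arg(method)
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  if (method == "fisher") {
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2)
    return(stats::fisher.test(tab)$p.value)
  }
  if (k1 / n1 == k2 / n2) return(1)       # identical proportions
  suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = FALSE)$p.value)
}

#' Lesion-on-parenchyma AREA regression
#'
#' Ordinary least squares of lesion AREA on parenchyma AREA with the
#' two-sided t-test on the slope, the association the TIC analysis uses to
#' show that lesion washout tracks background perfusion.
#'
#' @param x parenchyma AREA values, dB.
#' @param y lesion AREA values, dB.
#' @return list: `intercept` (dB), `slope`, `p_slope`, `se_intercept`,
#'   `se_slope`, and the underlying `lm` fit.
#' @export
#' @examples
#' area_regression(c(0, 2), c(1, 5))[c("intercept", "slope")]  # 1, 2
area_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0) stop("'x' is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)$coefficients
  list(intercept = unname(s[1, 1]), slope = unname(s[2, 1]),
       p_slope = unname(s[2, 4]),
       se_intercept = unname(s[1, 2]), se_slope = unname(s[2, 2]),
       fit = fit)
}

#' Lesion-type detection rate
#'
#' Among lesions whose malignancy status was called correctly, the fraction
#' whose specific lesion type was also identified.
#'
#' @param n_type_correct lesions with the correct type call.
#' @param n_malignancy_correct lesions with the correct malignancy call.
#' @return list: `rate` (exact fraction), `percent` (integer-rounded
#'   percentage).
#' @export
#' @examples
#' detection_rate(20, 71)$percent  # 28
detection_rate <- function(n_type_correct, n_malignancy_correct) {
  if (n_malignancy_correct <= 0) stop("zero denominator")
  if (n_type_correct > n_malignancy_correct)
    stop("more correct types than correct malignancy calls")
  rate <- n_type_correct / n_malignancy_correct
  list(rate = rate, percent = round(100 * rate))
}

#' Score cohort predictions against the reference diagnoses
#'
#' Builds the malignancy confusion matrix and the type-detection summary for
#' a classified cohort, plus the AUROC of the AREA statistic (more negative
#' AREA scoring as more malignant).
#'
#' @param results a [classify_cohort()] result.
#' @param truth the cohort's `lesions` data frame (needs `lesion_id`,
#'   `true_malignant`, `true_type`).
#' @return object of class `mpus_report`: list with `confusion`
#'   ([confusion_metrics()]), `detection` ([detection_rate()]),
#'   `auroc_area`, `n`, `n_malignancy_correct`, `n_type_correct`.
#' @export
evaluate_results <- function(results, truth) {
  truth <- truth[setdiff(names(truth),
                         setdiff(intersect(names(truth), names(results)),
                                 "lesion_id"))]
  m <- merge(results, truth, by = "lesion_id")
  if (nrow(m) != nrow(results))
    stop("lesion_id mismatch between results and truth")
  conf <- confusion_metrics(
    tp = sum(m$predicted_malignant & m$true_malignant),
    fp = sum(m$predicted_malignant & !m$true_malignant),
    tn = sum(!m$predicted_malignant & !m$true_malignant),
    fn = sum(!m$predicted_malignant & m$true_malignant))
  mal_ok <- m$predicted_malignant == m$true_malignant
  type_ok <- mal_ok & m$predicted_type == m$true_type
  det <- if (sum(mal_ok) > 0) detection_rate(sum(type_ok), sum(mal_ok))
         else list(rate = NA_real_, percent = NA_real_)
  auc <- if (length(unique(m$true_malignant)) == 2)
    auroc(m$area_lesion, m$true_malignant, direction = "lower")
  else NA_real_
  structure(list(confusion = conf, detection = det, auroc_area = auc,
                 n = nrow(m), n_malignancy_correct = sum(mal_ok),
                 n_type_correct = sum(type_ok)),
            class = "mpus_report")
}

#' @export
print.mpus_report <- function(x, ...) {
  cat(sprintf("MPUS evaluation over %d lesions\n", x$n))
  print(x$confusion)
  cat(sprintf("  AREA AUROC (lower = malignant): %s\n",
              ifelse(is.na(x$auroc_area), "--",
                     sprintf("%.3f", x$auroc_area))))
  cat(sprintf("  type detection: %d of %d correctly-classified lesions (%d%%)\n",
              x$n_type_correct, x$n_malignancy_correct,
              x$detection$percent))
  invisible(x)
}
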