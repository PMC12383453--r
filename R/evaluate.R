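#' Regression assessment of predicted vs measured GPR
#'
#' Residuals use the convention measured minus predicted, so overestimation
#' of low GPR values shows up as negative residuals.
#'
#' @param measured,predicted numeric vectors, percent.
#' @return list with `mae`, `r2`, `residual_quartiles` (25/50/75%),
#'   `abs_error_percentiles` (75/90/95/98%), `frac_within` (abs error <= 3,
#'   5, 10%), `n`.
#' @export
regression_report <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted), length(measured) >= 2)
  res <- measured - predicted
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot <= 0) stop("measured values have zero variance; R2 undefined")
  list(mae = mean(abs(res)),
       r2 = 1 - sum(res^2) / ss_tot,
       residual_quartiles = stats::quantile(res, c(0.25, 0.5, 0.75),
                                            names = TRUE, type = 7),
       abs_error_percentiles = stats::quantile(abs(res),
                                               c(0.75, 0.90, 0.95, 0.98),
                                               names = TRUE, type = 7),
       frac_within = c(`3` = mean(abs(res) <= 3), `5` = mean(abs(res) <= 5),
                       `10` = mean(abs(res) <= 10)),
       n = length(measured))
}

#' Confusion counts at a threshold limit
#'
#' "Fail" is the positive class: an arc is a true failure when its measured
#' GPR is below the action limit, and is flagged when its predicted GPR is
#' below the TL.
#'
#' @param predicted,measured numeric vectors, percent.
#' @param tl threshold limit on predicted GPR, percent.
#' @param action_limit action limit on measured GPR, percent.
#' @return named integer vector `true_fail`, `false_pass`, `true_pass`,
#'   `false_fail`.
#' @export
confusion_counts <- function(predicted, measured, tl = 97,
                             action_limit = 95) {
  flag <- predicted < tl
  fail <- measured < action_limit
  c(true_fail = sum(flag & fail), false_pass = sum(!flag & fail),
    true_pass = sum(!flag & !fail), false_fail = sum(flag & !fail))
}

#' Sensitivity, specificity and precision from confusion counts
#'
#' sensitivity = TF / (TF + FP); specificity = TP / (TP + FF);
#' precision = TF / (TF + FF), with TF/FP/TP/FF as in [confusion_counts()].
#' A zero denominator yields `NA` for that metric.
#'
#' @param counts named vector from [confusion_counts()].
#' @return named numeric `sensitivity`, `specificity`, `precision`.
#' @export
classification_metrics <- function(counts) {
  tf <- counts[["true_fail"]]; fp <- counts[["false_pass"]]
  tp <- counts[["true_pass"]]; ff <- counts[["false_fail"]]
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = safe(tf, tf + fp),
    specificity = safe(tp, tp + ff),
    precision = safe(tf, tf + ff))
}

#' ROC and precision-recall curves over all possible threshold limits
#'
#' The classification score is the negated predicted GPR (lower prediction =
#' more fail-like). ROC-AUC is computed by trapezoid; average precision by
#' the step interpolation `sum (R_n - R_{n-1}) P_n`, the convention under
#' which an always-fail classifier scores the fail prevalence.
#'
#' @param predicted predicted GPR, percent.
#' @param fail logical vector, TRUE for measured failures (positive class).
#' @return list with `roc` (data.frame fpr/tpr/threshold), `auc`, `pr`
#'   (data.frame recall/precision), `ap`, and `baselines` (`auc` 0.5, `ap` =
#'   prevalence, for a chance / always-fail classifier).
#' @export
roc_pr_curves <- function(predicted, fail) {
  fail <- as.logical(fail)
  if (!any(fail) || all(fail))
    stop("both classes must be present")
  score <- -predicted
  o <- order(score, decreasing = TRUE)
  s <- score[o]; y <- fail[o]
  np <- sum(y); nn <- sum(!y)
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # collapse tied scores
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / np
  rec0 <- c(0, rec[-length(rec)])
  ap <- sum((rec - rec0) * prec)
  list(roc = data.frame(fpr = fpr, tpr = tpr,
                        threshold = c(Inf, -s[last])),
       auc = auc,
       pr = data.frame(recall = rec, precision = prec),
       ap = ap,
       baselines = c(auc = 0.5, ap = np / (np + nn)))
}

#' Partial dependence of the predicted GPR on one feature
#'
#' For each grid value `g` (by default 20 points spanning the 5th-95th
#' percentile of the feature in `rows`), every row's feature is overwritten
#' with `g` and the mean prediction is recorded.
#'
#' @param bundle a [train_model()] bundle.
#' @param rows data.frame of evaluation rows.
#' @param feature feature name in the bundle.
#' @param grid optional explicit grid; otherwise `grid_size` points.
#' @param grid_size number of grid points.
#' @return data.frame with columns `value` and `prediction`.
#' @export
partial_dependence <- function(bundle, rows, feature, grid = NULL,
                               grid_size = 20) {
  if (!feature %in% bundle$features)
    stop("feature ", feature, " is not in the model")
  if (is.null(grid)) {
    r <- stats::quantile(rows[[feature]], c(0.05, 0.95), type = 7,
                         names = FALSE)
    grid <- seq(r[1], r[2], length.out = grid_size)
  }
  pred <- vapply(grid, function(g) {
    rr <- rows
    rr[[feature]] <- g
    mean(predict_gpr(bundle, rr))
  }, 0)
  data.frame(value = grid, prediction = pred)
}

#' Expected QA-workload reduction of the virtual-QA triage model
#'
#' Baseline practice spends `t_replan` minutes on every true failure
#' (replanning and re-measurement). With the model, every flagged arc
#' (true or false alarm) is reoptimized in `t_reopt` minutes, and missed
#' true failures still cost `t_replan`. The reduction is relative to the
#' baseline failure-handling workload:
#' \deqn{100 \left[1 - \frac{t_{reopt}(p\,Se + (1-p)(1-Sp)) +
#'   t_{replan}\, p (1 - Se)}{t_{replan}\, p}\right]}
#' Negative values mean the triage adds workload.
#'
#' @param p fail prevalence in \[0, 1\] (must be > 0).
#' @param sensitivity,specificity operating point of the classifier.
#' @param t_reopt minutes per reoptimization of a flagged arc.
#' @param t_replan minutes per replanning-and-measurement of a missed
#'   failure (and per failure under baseline practice).
#' @return workload reduction, percent.
#' @export
workload_reduction <- function(p, sensitivity, specificity,
                               t_reopt = 10, t_replan = 60) {
  if (p <= 0) stop("fail prevalence must be positive")
  flagged <- p * sensitivity + (1 - p) * (1 - specificity)
  missed <- p * (1 - sensitivity)
  100 * (1 - (t_reopt * flagged + t_replan * missed) / (t_replan * p))
}

#' Full evaluation report for a fitted model on a test set
#'
#' @param bundle a [train_model()] bundle with calibrated `tl` (or pass
#'   `tl` explicitly).
#' @param rows test rows with features and `measured_gpr`.
#' @param tl threshold limit, percent; defaults to the bundle's.
#' @param action_limit measured-GPR action limit, percent.
#' @return list of class `evaluation_report`: `regression`, `counts`,
#'   `classification`, `curves`, `tl`, `action_limit`, `n`.
#' @export
evaluation_report <- function(bundle, rows, tl = bundle$tl,
                              action_limit = 95) {
  if (is.null(tl)) stop("no threshold limit: calibrate or pass tl")
  pred <- predict_gpr(bundle, rows)
  meas <- rows$measured_gpr
  counts <- confusion_counts(pred, meas, tl = tl,
                             action_limit = action_limit)
  structure(list(regression = regression_report(meas, pred),
                 counts = counts,
                 classification = classification_metrics(counts),
                 curves = roc_pr_curves(pred, meas < action_limit),
                 tl = tl, action_limit = action_limit, n = length(meas)),
            class = "evaluation_report")
}
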