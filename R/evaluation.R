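#' Confusion matrix counts
#' @param pred Predicted 0/1 classes.
#' @param truth True 0/1 labels (positive class = survival >= 1 year).
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  stopifnot(length(pred) == length(truth))
  c(tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
    tn = sum(pred == 0 & truth == 0), fn = sum(pred == 0 & truth == 1))
}

#' Confusion-matrix-derived indicators
#'
#' Accuracy, precision (positive predictive value), sensitivity (recall),
#' specificity, F-score, Youden index (`sensitivity + specificity - 1`) and
#' the classification-error count. Ratios with a zero denominator are
#' undefined and reported as `NA`, never silently 0.
#'
#' @param cm Named counts from [confusion_counts()].
#' @return Named list of indicators.
#' @export
confusion_metrics <- function(cm) {
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; tn <- cm[["tn"]]; fn <- cm[["fn"]]
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
       else 2 * prec * sens / (prec + sens)
  list(accuracy = (tp + tn) / total, precision = prec, sensitivity = sens,
       specificity = spec, f_score = f,
       youden = if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1,
       errors = fp + fn, total = total)
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) form with tie correction:
#' `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param scores Continuous classifier scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUROC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param z Normal quantile (default 1.96 for 95% coverage).
#' @return Named vector `c(lower, upper)`, clamped to `[0, 1]`.
#' @export
wilson_interval <- function(successes, n, z = 1.96) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Full performance report from scores and labels
#'
#' Classes are assigned at the probability threshold; the report carries the
#' confusion-matrix indicators, AUROC from the continuous scores, and Wilson
#' intervals for the indicators that are binomial proportions (accuracy,
#' precision, sensitivity, specificity).
#'
#' @param scores Positive-class probabilities.
#' @param labels Binary 0/1 labels.
#' @param threshold Class-assignment threshold (default 0.5).
#' @param z Wilson interval quantile (default 1.96).
#' @return A list of class `performance_report`.
#' @export
performance_report <- function(scores, labels, threshold = 0.5, z = 1.96) {
  labels <- as.integer(labels)
  cm <- confusion_counts(as.integer(scores >= threshold), labels)
  m <- confusion_metrics(cm)
  m$auroc <- if (length(unique(labels)) == 2) auroc(scores, labels) else NA_real_
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; tn <- cm[["tn"]]; fn <- cm[["fn"]]
  wi <- function(s, n) if (n == 0) c(lower = NA_real_, upper = NA_real_)
                       else wilson_interval(s, n, z)
  m$wilson <- list(accuracy = wi(tp + tn, m$total),
                   precision = wi(tp, tp + fp),
                   sensitivity = wi(tp, tp + fn),
                   specificity = wi(tn, tn + fp))
  m$confusion <- cm
  structure(m, class = "performance_report")
}

#' @exportS3Method base::print
print.performance_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.3f", v))
  cat("accuracy ", fmt(x$accuracy), "  precision ", fmt(x$precision),
      "  sensitivity ", fmt(x$sensitivity), "  specificity ",
      fmt(x$specificity), "\nF-score ", fmt(x$f_score), "  Youden ",
      fmt(x$youden), "  AUROC ", fmt(x$auroc), "  errors ", x$errors, "/",
      x$total, "\n", sep = "")
  invisible(x)
}

report_row <- function(report) {
  data.frame(accuracy = report$accuracy, precision = report$precision,
             sensitivity = report$sensitivity, specificity = report$specificity,
             f_score = report$f_score, youden = report$youden,
             auroc = report$auroc, errors = report$errors,
             total = report$total)
}

#' Render experiment results to files
#'
#' Writes a tidy CSV of all indicators per (feature-vector, classifier)
#' combination, sorted by descending Youden index then ascending error count,
#' plus a JSON summary with Wilson intervals. Undefined indicators are
#' written as explicit `NA`. An optional heatmap (requires the pheatmap
#' package) mirrors the sorted table.
#'
#' @param results A results data.frame from [run_experiment()] (element
#'   `results`), or a compatible data.frame.
#' @param dir Output directory.
#' @param heatmap Render `heatmap.png` if pheatmap is installed.
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(results, dir, heatmap = FALSE) {
  stopifnot(nrow(results) > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  o <- order(-results$youden, results$errors)
  results <- results[o, , drop = FALSE]
  csv <- file.path(dir, "performance.csv")
  utils::write.csv(results, csv, row.names = FALSE, na = "NA")
  js <- file.path(dir, "performance.json")
  jsonlite::write_json(results, js, dataframe = "rows", na = "string",
                       auto_unbox = TRUE, digits = NA)
  paths <- c(csv, js)
  if (heatmap && requireNamespace("pheatmap", quietly = TRUE)) {
    ind <- as.matrix(results[, c("accuracy", "precision", "sensitivity",
                                 "specificity", "f_score", "youden", "auroc")])
    rownames(ind) <- paste(results$spec_id, results$classifier, sep = " / ")
    png <- file.path(dir, "heatmap.png")
    pheatmap::pheatmap(ind, cluster_rows = FALSE, cluster_cols = FALSE,
                       filename = png)
    paths <- c(paths, png)
  }
  invisible(paths)
}
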