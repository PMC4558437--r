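# Diagnostic evaluation: ROC analysis, cutoff classification, McNemar's test,
# and the two-sample t-test from summary statistics.
#
# Orientation is fixed throughout: a LOWER SRR indicates disease (striatal
# dopamine-transporter loss), and a subject is called diseased when its score
# is at or below the cutoff.

#' ROC analysis of a lower-is-diseased score
#'
#' Sweeps every observed score as a cutoff (diseased when score <= cutoff) and
#' computes the AUC as the tie-adjusted Mann-Whitney statistic
#' P(control > diseased) + 0.5 P(tie). The optimal cutoff maximizes the Youden
#' index J = sensitivity + specificity - 1 (ties broken toward the higher
#' cutoff); an accuracy-maximizing criterion is available as an option.
#'
#' @param diseased_scores,control_scores numeric score vectors (SRR).
#' @param criterion `"youden"` (default) or `"accuracy"`.
#' @return an object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `optimal_cutoff`, and `sensitivity_at_cutoff`,
#'   `specificity_at_cutoff`, `accuracy_at_cutoff`.
#' @export
roc_analysis <- function(diseased_scores, control_scores,
                         criterion = c("youden", "accuracy")) {
  criterion <- match.arg(criterion)
  if (length(diseased_scores) == 0 || length(control_scores) == 0)
    stop("both score vectors must be non-empty")
  nd <- length(diseased_scores); nc <- length(control_scores)
  pooled <- c(control_scores, diseased_scores)
  if (length(unique(pooled)) == 1L) {
    warning("constant pooled scores: AUC defined as 0.5")
    auc <- 0.5
  } else {
    # tie-adjusted Mann-Whitney via midranks of the controls in the pool
    r <- rank(pooled)
    auc <- (sum(r[seq_len(nc)]) - nc * (nc + 1) / 2) / (nc * nd)
  }
  thresholds <- sort(unique(pooled))
  sens <- vapply(thresholds, function(t) mean(diseased_scores <= t), 0)
  spec <- vapply(thresholds, function(t) mean(control_scores > t), 0)
  acc <- (nd * sens + nc * spec) / (nd + nc)
  obj <- switch(criterion, youden = sens + spec - 1, accuracy = acc)
  best <- max(thresholds[obj == max(obj)])
  i <- match(best, thresholds)
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc, optimal_cutoff = best,
                 sensitivity_at_cutoff = sens[i],
                 specificity_at_cutoff = spec[i],
                 accuracy_at_cutoff = acc[i],
                 criterion = criterion,
                 orientation = "lower_is_diseased",
                 n_diseased = nd, n_control = nc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("<roc_result> AUC %.3f; optimal cutoff %.3f (%s): ",
                     "sens %.1f%%, spec %.1f%%, acc %.1f%%\n"),
              x$auc, x$optimal_cutoff, x$criterion,
              100 * x$sensitivity_at_cutoff, 100 * x$specificity_at_cutoff,
              100 * x$accuracy_at_cutoff))
  invisible(x)
}

#' Classification metrics at a fixed cutoff
#'
#' A subject is called diseased when its score is at or below the cutoff.
#'
#' @param scores numeric scores.
#' @param truth logical (or 0/1) vector, `TRUE` = diseased.
#' @param cutoff decision threshold.
#' @return list with `sensitivity`, `specificity`, `accuracy`.
#' @export
classify_at_cutoff <- function(scores, truth, cutoff) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("scores and truth lengths differ")
  if (!any(truth) || all(truth))
    stop("truth must contain both diseased and control subjects")
  called <- scores <= cutoff
  list(sensitivity = mean(called[truth]),
       specificity = mean(!called[!truth]),
       accuracy = mean(called == truth))
}

#' McNemar's chi-square test for paired classifiers
#'
#' Compares two methods on the same subjects from their per-subject
#' correctness indicators, using the continuity-corrected statistic
#' `chi2 = (max(0, |b - c| - 1))^2 / (b + c)` on the discordant counts; when
#' there is no discordance, `chi2 = 0` and `p = 1`.
#'
#' @param correct_method_a,correct_method_b logical vectors, `TRUE` where the
#'   method classified the subject correctly.
#' @return list with `chi2`, `p`, and discordant counts `b`, `c`.
#' @export
mcnemar_test <- function(correct_method_a, correct_method_b) {
  a <- as.logical(correct_method_a); b2 <- as.logical(correct_method_b)
  if (length(a) != length(b2)) stop("paired vectors must have equal length")
  b <- sum(a & !b2)
  cc <- sum(!a & b2)
  if (b + cc == 0) return(list(chi2 = 0, p = 1, b = b, c = cc))
  chi2 <- max(0, abs(b - cc) - 1)^2 / (b + cc)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       b = b, c = cc)
}

#' Welch two-sample t-test from summary statistics
#'
#' @param mean1,sd1,n1 summary of the first sample.
#' @param mean2,sd2,n2 summary of the second sample.
#' @return list with `t`, `df` (Welch-Satterthwaite), and two-sided `p`.
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each sample needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    stop("zero pooled variance with unequal means")
  }
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
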