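# Base-graphics summaries of the diagnostic and duration analyses.

#' Plot an ROC curve
#'
#' @param x a [roc_analysis()] result.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.roc_result <- function(x, ...) {
  fpr <- c(0, rev(1 - x$specificity), 1)
  tpr <- c(0, rev(x$sensitivity), 1)
  graphics::plot(fpr, tpr, type = "l", lwd = 2,
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  i <- match(x$optimal_cutoff, x$thresholds)
  graphics::points(1 - x$specificity[i], x$sensitivity[i], pch = 19)
  invisible(x)
}

#' Plot the duration-SRR fit
#'
#' Per-year bin means with SD error bars and the fitted quadratic curve.
#'
#' @param bins data frame from [bin_by_year()].
#' @param model a [quadratic_model()].
#' @param healthy_mean_srr optional healthy-control mean drawn as a dashed
#'   horizontal line, with the extrapolated preclinical root marked.
#' @return invisibly, `model`.
#' @export
plot_duration_fit <- function(bins, model, healthy_mean_srr = NULL) {
  xfit <- seq(if (is.null(healthy_mean_srr)) 0 else
                -estimate_preclinical_duration(model, healthy_mean_srr)$years,
              max(bins$year), length.out = 200)
  yfit <- predict_srr(model, xfit)
  ylim <- range(c(bins$mean_srr + bins$sd_srr, bins$mean_srr - bins$sd_srr,
                  yfit))
  graphics::plot(bins$year, bins$mean_srr, pch = 19,
                 xlim = range(xfit), ylim = ylim,
                 xlab = "Clinical duration (years)", ylab = "Mean SRR",
                 main = sprintf("y = %.4f x^2 %+.4f x %+.3f  (R^2 = %.2f)",
                                model$a, model$b, model$c, model$r_squared))
  graphics::arrows(bins$year, bins$mean_srr - bins$sd_srr,
                   bins$year, bins$mean_srr + bins$sd_srr,
                   angle = 90, code = 3, length = 0.03)
  graphics::lines(xfit, yfit, lwd = 2)
  if (!is.null(healthy_mean_srr)) {
    graphics::abline(h = healthy_mean_srr, lty = 2)
    root <- estimate_preclinical_duration(model, healthy_mean_srr)$root
    graphics::points(root, healthy_mean_srr, pch = 4, cex = 1.5)
  }
  invisible(model)
}
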