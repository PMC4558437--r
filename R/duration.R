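# Clinical-duration analysis: yearly binning, quadratic regression of the
# mean SRR on duration, and preclinical-duration extrapolation.

#' Bin PD subjects by clinical duration
#'
#' Bin `k` (for `k = 1..max_year`) contains subjects with duration in
#' `(k - 1, k]` years; duration 0 falls in bin 1. Bins with fewer than `min_n`
#' subjects are dropped. The bin abscissa is the integer year label `k`.
#'
#' @param records data frame with columns `duration_years` and `srr`.
#' @param min_n minimum subjects per surviving bin.
#' @param max_year last year considered.
#' @return data frame with columns `year`, `n`, `mean_srr`, `sd_srr`.
#' @export
bin_by_year <- function(records, min_n = 10, max_year = 15) {
  if (!all(c("duration_years", "srr") %in% names(records)))
    stop("records must have columns duration_years and srr")
  dur <- records$duration_years
  if (any(is.na(dur))) stop("all records must carry a clinical duration")
  year <- pmax(1L, as.integer(ceiling(dur)))
  keep <- year <= max_year
  year <- year[keep]; srr <- records$srr[keep]
  bins <- lapply(sort(unique(year)), function(k) {
    v <- srr[year == k]
    data.frame(year = k, n = length(v), mean_srr = mean(v),
               sd_srr = stats::sd(v))
  })
  out <- do.call(rbind, bins)
  out <- out[out$n >= min_n, , drop = FALSE]
  if (is.null(out) || nrow(out) == 0)
    stop("no year bin survives the minimum-count filter (min_n = ", min_n, ")")
  rownames(out) <- NULL
  out
}

#' Fit the quadratic duration model
#'
#' Ordinary (unweighted) least squares of the per-bin mean SRR on
#' `(year^2, year, 1)`: `y = a x^2 + b x + c`, with R-squared computed over
#' the bin means.
#'
#' @param bins data frame from [bin_by_year()] (columns `year`, `mean_srr`).
#' @return a [quadratic_model()].
#' @export
fit_quadratic <- function(bins) {
  if (nrow(bins) < 3 || length(unique(bins$year)) < 3)
    stop("need at least 3 bins with distinct years to fit a quadratic")
  fit <- stats::lm(mean_srr ~ I(year^2) + year, data = bins)
  cf <- stats::coef(fit)
  pred <- stats::fitted(fit)
  ss_res <- sum((bins$mean_srr - pred)^2)
  ss_tot <- sum((bins$mean_srr - mean(bins$mean_srr))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  quadratic_model(a = unname(cf["I(year^2)"]), b = unname(cf["year"]),
                  c = unname(cf["(Intercept)"]), r_squared = r2)
}

#' Quadratic duration-SRR model
#'
#' `y = a x^2 + b x + c` with `y` the mean SRR and `x` the clinical duration
#' in years.
#'
#' @param a,b,c coefficients.
#' @param r_squared coefficient of determination of the fit (optional).
#' @return an object of class `quadratic_model`.
#' @export
quadratic_model <- function(a, b, c, r_squared = NA_real_) {
  structure(list(a = a, b = b, c = c, r_squared = r_squared),
            class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("<quadratic_model> y = %.4g x^2 + %.4g x + %.4g (R^2 = %.3g)\n",
              x$a, x$b, x$c, x$r_squared))
  invisible(x)
}

#' Evaluate a quadratic model
#'
#' @param model a [quadratic_model()].
#' @param x duration(s) in years.
#' @return predicted mean SRR.
#' @export
predict_srr <- function(model, x) {
  stopifnot(inherits(model, "quadratic_model"))
  model$a * x^2 + model$b * x + model$c
}

#' Estimate the preclinical duration
#'
#' Solves `a x^2 + b x + c = healthy_mean_srr` and selects the negative root
#' nearest zero: the preclinical period is the extrapolated time before
#' symptom onset at which striatal uptake still matched the healthy-control
#' mean. Returns the magnitude of that root.
#'
#' @param model a [quadratic_model()].
#' @param healthy_mean_srr mean SRR of the healthy controls; must exceed the
#'   model value at onset (`x = 0`) for the extrapolation to be well posed.
#' @return list with `years` (unrounded magnitude), `years_rounded`
#'   (to 0.1 year), and `root` (the signed solution).
#' @export
estimate_preclinical_duration <- function(model, healthy_mean_srr) {
  stopifnot(inherits(model, "quadratic_model"))
  if (healthy_mean_srr <= predict_srr(model, 0))
    stop("healthy mean SRR does not exceed the model value at onset; ",
         "extrapolation toward negative durations is ill-posed")
  a <- model$a; b <- model$b; cc <- model$c - healthy_mean_srr
  if (abs(a) < 1e-15) {
    if (abs(b) < 1e-15) stop("degenerate model: no real root")
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("no real root: the model never reaches the healthy mean")
    roots <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
  }
  neg <- roots[roots < 0]
  if (length(neg) == 0)
    stop("both roots are non-negative: extrapolation is ill-posed")
  root <- neg[which.min(abs(neg))]
  list(years = abs(root), years_rounded = round(abs(root), 1), root = root)
}
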