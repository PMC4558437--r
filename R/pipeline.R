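# End-to-end orchestration: template building, per-subject quantification,
# diagnostic evaluation, and the duration model, with provenance and
# idempotent per-subject caching. The thin command-line wrapper in
# inst/cli/striatr dispatches to these functions.

pkg_provenance <- function(extra = list()) {
  c(list(package = "striatr",
         version = as.character(utils::packageVersion("striatr"))),
    extra)
}

write_provenance <- function(path, extra = list()) {
  yaml::write_yaml(pkg_provenance(extra), path)
  invisible(path)
}

#' Build and persist a template bundle from control volumes
#'
#' Registers the controls to the reference, averages them into the normal
#' template, thresholds the template at `threshold_fraction` of its maximum
#' to define the striatal VOIs, and builds the cortical reference VOI from
#' the label volume.
#'
#' @param controls list of native-space control `volume`s.
#' @param reference template-space registration reference (must include a
#'   scalp shell, as TRODAT shows scalp uptake).
#' @param labels template-space integer label `volume` for the reference VOI.
#' @param included_labels labels forming the cortical reference.
#' @param slice_range inclusive axial slice range for the reference VOI.
#' @param threshold_fraction striatal threshold as a fraction of the template
#'   maximum.
#' @param params a [registration_params()].
#' @param out_dir if non-NULL the bundle is saved there.
#' @return a [template_bundle()].
#' @export
build_template_pipeline <- function(controls, reference, labels,
                                    included_labels = 1,
                                    slice_range = NULL,
                                    threshold_fraction = 0.6,
                                    params = registration_params(),
                                    out_dir = NULL) {
  template <- build_normal_template(controls, reference, params)
  striatal <- define_striatal_vois(template, threshold_fraction)
  reference_voi <- define_reference_voi(labels, included_labels,
                                        slice_range, striatal)
  bundle <- template_bundle(template, striatal$striatum_left,
                            striatal$striatum_right, reference_voi,
                            provenance = pkg_provenance(list(
                              n_controls = length(controls),
                              threshold_fraction = threshold_fraction,
                              params = unclass(params))))
  if (!is.null(out_dir)) save_template_bundle(bundle, out_dir)
  bundle
}

#' Quantify a cohort of subjects
#'
#' Runs the selected SRR pipeline(s) for every subject. With
#' `method = "both"` each subject yields two records (one per method), paired
#' for McNemar comparison. Per-subject failures are logged and skipped; the
#' returned data frame has an attribute `n_failed`. When `out_dir` is given,
#' per-subject results are cached as JSON and reused on re-runs, so an
#' interrupted run resumes to an identical final table.
#'
#' @param subjects list of per-subject lists with elements `volume` (a native
#'   `volume`) and `record` (one-row data frame with `id`, `group`, `side`,
#'   `duration_years`), e.g. from [make_cohort_images()]; or a data frame with
#'   a `path` column of NIfTI files plus those metadata columns.
#' @param bundle a [template_bundle()].
#' @param method `"inverse_voi"`, `"conventional"`, or `"both"`.
#' @param params a [registration_params()].
#' @param out_dir optional output/cache directory.
#' @return data frame with columns `id`, `group`, `side`, `duration_years`,
#'   `srr`, `method`.
#' @export
quantify_cohort <- function(subjects, bundle,
                            method = c("inverse_voi", "conventional", "both"),
                            params = registration_params(), out_dir = NULL) {
  method <- match.arg(method)
  methods <- if (method == "both") c("inverse_voi", "conventional") else method
  if (is.data.frame(subjects)) {
    for (p in subjects$path)
      if (!file.exists(p)) stop("subject volume not found: ", p)
    subjects <- lapply(seq_len(nrow(subjects)), function(i) {
      list(volume = read_volume(subjects$path[i]),
           record = subjects[i, setdiff(names(subjects), "path"), drop = FALSE])
    })
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  n_failed <- 0L
  for (s in subjects) {
    rec <- s$record
    side <- rec$side %||% "bilateral"
    if (side == "none") side <- "bilateral"
    for (m in methods) {
      cache <- if (!is.null(out_dir))
        file.path(out_dir, sprintf("%s_%s.json", rec$id, m))
      res <- NULL
      if (!is.null(cache) && file.exists(cache)) {
        res <- jsonlite::read_json(cache, simplifyVector = TRUE)
      } else {
        res <- tryCatch({
          out <- if (m == "inverse_voi")
            run_subject_pipeline(s$volume, bundle, side = side,
                                 params = params)
          else
            run_conventional_pipeline(s$volume, bundle, side = side,
                                      params = params)
          list(srr = out$srr, method = m)
        }, error = function(e) {
          message("subject ", rec$id, " (", m, ") failed: ",
                  conditionMessage(e))
          NULL
        })
        if (is.null(res)) { n_failed <- n_failed + 1L; next }
        if (!is.null(cache))
          jsonlite::write_json(res, cache, auto_unbox = TRUE, digits = NA)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = rec$id, group = rec$group %||% NA_character_,
        side = rec$side %||% NA_character_,
        duration_years = rec$duration_years %||% NA_real_,
        srr = res$srr, method = res$method,
        srr_true = rec$srr_true %||% NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    stop("no subject could be quantified (", n_failed, " failure(s))")
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- n_failed
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "cohort_srr.csv"),
                     row.names = FALSE)
    write_provenance(file.path(out_dir, "cohort_srr.provenance.yaml"),
                     list(method = method, n_subjects = length(subjects),
                          n_failed = n_failed))
  }
  out
}

#' Evaluate diagnostic performance of a quantified cohort
#'
#' Runs the ROC analysis of PD versus non-PD SRR values; when the cohort
#' contains paired records from both pipelines, the methods are compared with
#' McNemar's test on correctness at the chosen cutoff.
#'
#' @param cohort data frame from [quantify_cohort()] (or with columns `id`,
#'   `group`, `srr`, optionally `method`).
#' @param diseased_group group label treated as diseased.
#' @param cutoff decision cutoff; `NULL` uses the ROC-optimal cutoff.
#' @param criterion optimal-cutoff criterion, see [roc_analysis()].
#' @param out_dir optional directory for the ROC table CSV + summary JSON.
#' @return list with `roc` (`roc_result`), `cutoff`, `metrics`, and (for
#'   paired cohorts) `mcnemar`.
#' @export
evaluate_diagnostics <- function(cohort, diseased_group = "PD", cutoff = NULL,
                                 criterion = "youden", out_dir = NULL) {
  meth <- unique(cohort$method %||% "inverse_voi")
  primary <- if ("inverse_voi" %in% meth) "inverse_voi" else meth[1]
  prim <- if (is.null(cohort$method)) cohort else cohort[cohort$method == primary, ]
  diseased <- prim$srr[prim$group == diseased_group]
  control <- prim$srr[prim$group != diseased_group]
  roc <- roc_analysis(diseased, control, criterion = criterion)
  use_cutoff <- cutoff %||% roc$optimal_cutoff
  metrics <- classify_at_cutoff(prim$srr, prim$group == diseased_group,
                                use_cutoff)
  result <- list(roc = roc, cutoff = use_cutoff, metrics = metrics,
                 method = primary)
  if (length(meth) == 2) {
    a <- cohort[cohort$method == meth[1], ]
    b <- cohort[cohort$method == meth[2], ]
    common <- intersect(a$id, b$id)
    a <- a[match(common, a$id), ]; b <- b[match(common, b$id), ]
    correct_a <- (a$srr <= use_cutoff) == (a$group == diseased_group)
    correct_b <- (b$srr <= use_cutoff) == (b$group == diseased_group)
    result$mcnemar <- mcnemar_test(correct_a, correct_b)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(
      data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity,
                 specificity = roc$specificity),
      file.path(out_dir, "roc_curve.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(list(auc = roc$auc, cutoff = use_cutoff,
             sensitivity = metrics$sensitivity,
             specificity = metrics$specificity,
             accuracy = metrics$accuracy),
        if (!is.null(result$mcnemar))
          list(mcnemar_chi2 = result$mcnemar$chi2,
               mcnemar_p = result$mcnemar$p),
        list(provenance = pkg_provenance())),
      file.path(out_dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Duration-model analysis of a quantified PD cohort
#'
#' Bins PD subjects by clinical duration, fits the quadratic mean-SRR model,
#' and extrapolates the preclinical duration at the healthy-control mean SRR.
#'
#' @param cohort data frame with columns `group`, `duration_years`, `srr`.
#' @param healthy_mean_srr healthy-control mean SRR used for extrapolation.
#' @param min_n,max_year binning parameters, see [bin_by_year()].
#' @param out_dir optional directory for `duration_bins.csv` +
#'   `duration_model.json`.
#' @return list with `bins`, `model`, `preclinical`.
#' @export
duration_analysis <- function(cohort, healthy_mean_srr, min_n = 10,
                              max_year = 15, out_dir = NULL) {
  pd <- cohort[cohort$group == "PD", ]
  bins <- bin_by_year(pd, min_n = min_n, max_year = max_year)
  model <- fit_quadratic(bins)
  pre <- estimate_preclinical_duration(model, healthy_mean_srr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(bins, file.path(out_dir, "duration_bins.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(a = model$a, b = model$b, c = model$c,
           r_squared = model$r_squared,
           preclinical_years = pre$years,
           preclinical_years_rounded = pre$years_rounded,
           healthy_mean_srr = healthy_mean_srr,
           provenance = pkg_provenance()),
      file.path(out_dir, "duration_model.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(bins = bins, model = model, preclinical = pre)
}
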