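#' Run the full pattern-prediction pipeline
#'
#' Executes the end-to-end workflow for each requested early time window W:
#' cohort generation (or ingestion), feature extraction over the first W
#' days, stratified 80:20 train/test split, min-max normalisation, SU-based
#' feature selection on the training rows, classifier-suite training with
#' stratified 5-fold cross-validation, and test-set evaluation. The split is
#' drawn once and shared by all windows, as the windows describe the same
#' patients. No stage sees test-set labels before evaluation: normalisation
#' constants and the feature subset are fitted on training rows only (a
#' `normalize_scope = "all"` switch reproduces whole-cohort scaling).
#'
#' One master seed drives every stochastic stage through fixed per-stage
#' offsets, so an identical call is bit-identical in all outputs. When the
#' selection comes back empty (no feature clears the SU threshold) the stage
#' falls back to all features; the fallback is recorded per window.
#'
#' @param cohort An `activity_cohort`; generated from `spec` when `NULL`.
#' @param spec A [cohort_spec()] used when `cohort` is `NULL`.
#' @param windows Window lengths in days; subset of 5:8.
#' @param threshold SU selection threshold (default 0.9).
#' @param train_fraction Training fraction for the stratified split.
#' @param include_clinical Include BI/FMS/FAC/MoCA features?
#' @param normalize_scope Fit min-max constants on `"train"` rows (default)
#'   or on `"all"` rows.
#' @param selection_mode Redundancy rule for [cfs_select()]: `"all"` or
#'   `"fcbf"`.
#' @param discretization Discretization for [cfs_select()].
#' @param folds Cross-validation folds.
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, per-window feature tables
#'   (CSV), selections, CV tables and evaluation reports (JSON) are written.
#' @return An object of class `pipeline_result`: per-window list with
#'   `window`, `selection`, `features_used`, `selection_fallback`, `cv`,
#'   `winner`, `report`, plus a `manifest` (seeds, split ids, exclusions,
#'   settings).
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(spec = cohort_spec(n_patients = 24, seed = 1),
#'                     windows = 7, seed = 1)
#' res$windows[["7"]]$report$micro_f1
#' }
run_pipeline <- function(cohort = NULL, spec = cohort_spec(), windows = 5:8,
                         threshold = 0.9, train_fraction = 0.8,
                         include_clinical = TRUE,
                         normalize_scope = c("train", "all"),
                         selection_mode = c("all", "fcbf"),
                         discretization = c("entropy", "frequency"),
                         folds = 5, seed = 1, out_dir = NULL) {
  normalize_scope <- match.arg(normalize_scope)
  selection_mode <- match.arg(selection_mode)
  discretization <- match.arg(discretization)
  if (!all(windows %in% 5:8)) {
    stop("'windows' must be a subset of 5:8", call. = FALSE)
  }
  if (is.null(cohort)) {
    if (is.null(spec$seed)) {
      spec$seed <- seed
    }
    cohort <- generate_cohort(spec)
  }

  results <- list()
  split_manifest <- NULL
  exclusions <- list()
  for (W in windows) {
    ft <- assemble_feature_table(cohort, W, include_clinical = include_clinical)
    exclusions[[as.character(W)]] <- attr(ft, "exclusions")
    split <- stratified_split(ft, train_fraction, seed = stage_seed(seed, "split"))
    split_manifest <- attr(split, "manifest")

    if (normalize_scope == "train") {
      train <- minmax_normalize(split$train)
      test <- minmax_normalize(split$test, ranges = attr(train, "ranges"))
    } else {
      whole <- minmax_normalize(ft)
      ids <- split_manifest
      train <- whole[whole$patient_id %in% ids$train_ids, ]
      test <- whole[whole$patient_id %in% ids$test_ids, ]
    }

    selection <- withCallingHandlers(
      cfs_select(train, threshold = threshold, mode = selection_mode,
                 discretization = discretization),
      warning = function(w) invokeRestart("muffleWarning"))
    fallback <- length(selection$selected) == 0
    features_used <- if (fallback) feature_names(train) else selection$selected

    cv <- train_suite(train, features_used, folds = folds,
                      seed = stage_seed(seed, "cv"))
    report <- evaluate_model(cv$model, test)

    results[[as.character(W)]] <- list(
      window = W, selection = selection, features_used = features_used,
      selection_fallback = fallback, cv = cv, winner = cv$winner,
      report = report)
  }

  out <- structure(list(
    windows = results,
    manifest = list(seed = seed, split = split_manifest,
                    exclusions = exclusions,
                    settings = list(windows = windows, threshold = threshold,
                                    train_fraction = train_fraction,
                                    include_clinical = include_clinical,
                                    normalize_scope = normalize_scope,
                                    selection_mode = selection_mode,
                                    discretization = discretization,
                                    folds = folds))),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, cohort, out_dir)
  out
}

write_pipeline_outputs <- function(result, cohort, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_cohort(cohort, out_dir)
  for (W in names(result$windows)) {
    r <- result$windows[[W]]
    jsonlite::write_json(
      list(window = r$window,
           selected = r$features_used,
           selection_fallback = r$selection_fallback,
           su_to_class = as.list(r$selection$scores),
           cv = r$cv$table, winner = r$winner,
           confusion = as.data.frame(r$report$confusion),
           metrics = r$report$metrics,
           micro_f1 = r$report$micro_f1),
      file.path(out_dir, paste0("report_window_", W, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed", x$manifest$seed, "\n")
  for (r in x$windows) {
    cat(sprintf("  window %d: winner %-18s micro-F1 %.3f  features: %s%s\n",
                r$window, r$winner, r$report$micro_f1,
                paste(utils::head(r$features_used, 4), collapse = ", "),
                if (length(r$features_used) > 4) ", ..." else ""))
  }
  invisible(x)
}
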