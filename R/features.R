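#' Statistical features of an early-window daily series
#'
#' Summary statistics of the first-W-days intensity window: mean, median,
#' sample SD, IQR (Q3 - Q1, linear-interpolation quantiles), maximum,
#' minimum-maximum range and root mean square.
#'
#' @param window Numeric vector of the first W daily intensities (W >= 2, no
#'   missing values).
#' @return Named numeric vector `mean, median, sd, iqr, max, minmax_range, rms`.
#' @export
#' @examples
#' statistical_features(c(1, 2, 3, 4, 5))
statistical_features <- function(window) {
  check_window(window, min_len = 2)
  c(mean = mean(window),
    median = stats::median(window),
    sd = stats::sd(window),
    iqr = stats::IQR(window, type = 7),
    max = max(window),
    minmax_range = max(window) - min(window),
    rms = sqrt(mean(window^2)))
}

#' Amplitude features of an early-window daily series
#'
#' The overall intensity on rehabilitation day 1 and the mean amplitude
#' deviation \eqn{\frac{1}{W}\sum_i |x_i - \bar x|} of the window values.
#'
#' @inheritParams statistical_features
#' @return Named numeric vector `intensity_day1, mean_amplitude_deviation`.
#' @export
amplitude_features <- function(window) {
  check_window(window, min_len = 2)
  c(intensity_day1 = window[1],
    mean_amplitude_deviation = mean(abs(window - mean(window))))
}

#' Morphological (shape) features of an early-window daily series
#'
#' Shape descriptors of the trajectory over rehabilitation days
#' \eqn{x = 1..W}: the ordinary-least-squares slope of intensity on day
#' index, the leading coefficients of the least-squares cubic
#' \eqn{y = a x^3 + b x^2 + c x + d} (the constant `d` is fitted but not a
#' feature), and the mean first- and second-order differences.
#'
#' @inheritParams statistical_features
#' @return Named numeric vector `slope, coef_a, coef_b, coef_c,
#'   mean_first_order_diff, mean_second_order_diff`.
#' @export
#' @examples
#' x <- 1:7; morphological_features(2 * x^3 - x^2 + 3 * x + 1)
morphological_features <- function(window) {
  check_window(window, min_len = 4)
  W <- length(window)
  day <- seq_len(W)
  slope <- stats::cov(day, window) / stats::var(day)
  cubic <- cubic_fit(day, window)
  c(slope = slope,
    coef_a = cubic[["a"]], coef_b = cubic[["b"]], coef_c = cubic[["c"]],
    mean_first_order_diff = mean(diff(window)),
    mean_second_order_diff = mean(diff(window, differences = 2)))
}

# Least-squares cubic y = a x^3 + b x^2 + c x + d.
cubic_fit <- function(x, y) {
  co <- stats::lm.fit(cbind(1, x, x^2, x^3), y)$coefficients
  c(a = unname(co[4]), b = unname(co[3]), c = unname(co[2]), d = unname(co[1]))
}

check_window <- function(window, min_len) {
  if (anyNA(window)) stop("window contains missing values", call. = FALSE)
  if (length(window) < min_len) {
    stop(sprintf("window needs at least %d days", min_len), call. = FALSE)
  }
  invisible(window)
}

# Canonical feature column order: statistical, amplitude, morphological, clinical.
signal_feature_names <- function() {
  c("mean", "median", "sd", "iqr", "max", "minmax_range", "rms",
    "intensity_day1", "mean_amplitude_deviation",
    "slope", "coef_a", "coef_b", "coef_c",
    "mean_first_order_diff", "mean_second_order_diff")
}

clinical_feature_names <- function() c("BI", "FMS", "FAC", "MoCA")

#' Assemble the patients-by-features table for one time window
#'
#' Computes all statistical, amplitude and morphological features on the
#' first `W` rehabilitation days of every patient, optionally appends the
#' clinical scores (BI, FMS, FAC, MoCA), and attaches the pattern label.
#' Patients without `W` complete (non-missing) leading days are excluded;
#' their ids are recorded in the `"exclusions"` attribute, mirroring the
#' exclusion of incompletely monitored patients from the analysis set.
#'
#' @param cohort An `activity_cohort` (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param W Window length in days, one of 5, 6, 7, 8.
#' @param include_clinical Append the four clinical score columns?
#' @return Data frame with `patient_id`, one column per feature (fixed
#'   documented order: 7 statistical, 2 amplitude, 6 morphological, then 4
#'   clinical) and `label`; class `feature_table`, attribute `exclusions`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 10, seed = 1))
#' ft <- assemble_feature_table(cohort, W = 7)
#' dim(ft)
assemble_feature_table <- function(cohort, W, include_clinical = TRUE) {
  if (!W %in% 5:8) stop("'W' must be one of 5, 6, 7, 8", call. = FALSE)
  patients <- cohort$patients
  rows <- vector("list", nrow(patients))
  excluded <- character(0)
  for (i in seq_len(nrow(patients))) {
    id <- patients$patient_id[i]
    day <- cohort$daily[cohort$daily$patient_id == id, ]
    day <- day[order(day$rehab_day), ]
    win <- day$intensity[match(seq_len(W), day$rehab_day)]
    if (length(win) < W || anyNA(win)) {
      excluded <- c(excluded, id)
      next
    }
    feats <- c(statistical_features(win), amplitude_features(win),
               morphological_features(win))
    row <- data.frame(patient_id = id, t(feats), stringsAsFactors = FALSE)
    if (include_clinical) {
      row <- cbind(row, patients[i, clinical_feature_names(), drop = FALSE])
    }
    row$label <- patients$label[i]
    rownames(row) <- NULL
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no patient has ", W, " complete leading days", call. = FALSE)
  out <- do.call(rbind, rows)
  cols <- c("patient_id", signal_feature_names(),
            if (include_clinical) clinical_feature_names(), "label")
  out <- out[, cols]
  attr(out, "exclusions") <- excluded
  attr(out, "window") <- W
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature columns of a feature table
#'
#' @param table A feature table (from [assemble_feature_table()]).
#' @return Character vector of feature column names (everything except
#'   `patient_id` and `label`).
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("patient_id", "label"))
}

#' Min-max normalisation of a feature table
#'
#' Rescales every feature with \eqn{x' = (x - \min x) / (\max x - \min x)},
#' where the minimum and maximum are taken over `fit_rows` only (by default
#' all rows). Rows outside `fit_rows` are transformed with the same
#' constants and may legitimately fall outside \eqn{[0, 1]}. Fitting on the
#' training rows only and applying to test rows avoids information leaking
#' from the test set into the scaling. Features constant on the fit rows are
#' dropped with a warning.
#'
#' @param table A feature table.
#' @param fit_rows Integer/logical row index used to fit the per-feature
#'   (min, max); default all rows.
#' @param ranges Optional precomputed ranges (as returned in the `"ranges"`
#'   attribute) to apply instead of fitting.
#' @return The normalised table; attribute `"ranges"` holds the per-feature
#'   `min` and `max` actually used.
#' @export
#' @examples
#' ft <- data.frame(patient_id = 1:3, f = c(2, 4, 6), label = "x")
#' minmax_normalize(ft)$f
minmax_normalize <- function(table, fit_rows = seq_len(nrow(table)), ranges = NULL) {
  feats <- feature_names(table)
  if (is.null(ranges)) {
    fit <- table[fit_rows, feats, drop = FALSE]
    ranges <- data.frame(feature = feats,
                         min = vapply(fit, min, numeric(1)),
                         max = vapply(fit, max, numeric(1)),
                         stringsAsFactors = FALSE)
    constant <- ranges$max - ranges$min <= 0
    if (any(constant)) {
      warning("dropping constant feature(s): ",
              paste(ranges$feature[constant], collapse = ", "), call. = FALSE)
      drop <- ranges$feature[constant]
      ranges <- ranges[!constant, ]
      table <- table[, setdiff(names(table), drop)]
      feats <- setdiff(feats, drop)
    }
  } else {
    keep <- intersect(feats, ranges$feature)
    table <- table[, c("patient_id"[!is.na(match("patient_id", names(table)))],
                       keep, "label"[!is.na(match("label", names(table)))])]
    feats <- keep
  }
  for (f in feats) {
    r <- ranges[ranges$feature == f, ]
    table[[f]] <- (table[[f]] - r$min) / (r$max - r$min)
  }
  attr(table, "ranges") <- ranges
  table
}
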