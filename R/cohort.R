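#' Specification of a synthetic rehabilitation cohort
#'
#' Bundles every parameter the cohort generator needs: cohort size, pattern
#' mix, length-of-stay distribution, day-level noise, per-class archetype
#' parameter distributions and per-class clinical-score distributions. The
#' defaults emulate the analysis cohort of the exploratory clinical study the
#' pipeline re-implements: 37 patients, 41% upward-linear / 59% S-shape, mean
#' stay 29 (SD 15) days truncated at 8 days, and a 3-point Barthel Index gap
#' favouring the upward-linear class.
#'
#' Archetype parameters are drawn per patient from truncated normal
#' distributions, each given as `c(mean, sd)`; clinical scores are truncated
#' normals rounded to integers within their legal ranges (BI 0-20, FMS 0-5,
#' FAC 0-5, MoCA 0-30).
#'
#' @param n_patients Number of patients.
#' @param class_proportions Named proportions for `upward_linear` and
#'   `s_shape`; must sum to 1. Class counts use largest-remainder rounding.
#' @param stay_mean,stay_sd,stay_min Length-of-stay distribution (days);
#'   normal truncated below at `stay_min`, which must be at least 8.
#' @param noise_scale Day-level lognormal noise scale (log-SD), see
#'   [generate_trajectory()].
#' @param archetype_params Per-class list of `c(mean, sd)` parameter
#'   distributions (see Details for the parameter names).
#' @param clinical_params Per-class list of `c(mean, sd)` for BI, FMS, FAC
#'   and MoCA.
#' @param dropout_rate Per-day probability that a day's intensity is missing;
#'   default 0 (off).
#' @param seed Integer seed; the same spec always yields the same cohort.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec(n_patients = 10, class_proportions = c(upward_linear = 0.5, s_shape = 0.5))
cohort_spec <- function(n_patients = 37,
                        class_proportions = c(upward_linear = 0.41, s_shape = 0.59),
                        stay_mean = 29, stay_sd = 15, stay_min = 8,
                        noise_scale = 0.15,
                        archetype_params = list(
                          upward_linear = list(i0 = c(5, 0.8), s = c(0.3, 0.1)),
                          s_shape = list(L0 = c(1, 0.25), L1 = c(10, 2),
                                         t0 = c(9, 3), k = c(0.7, 0.2))
                        ),
                        clinical_params = list(
                          upward_linear = list(BI = c(14, 3), FMS = c(2, 1),
                                               FAC = c(3, 1), MoCA = c(25, 3)),
                          s_shape = list(BI = c(11, 3), FMS = c(3, 1),
                                         FAC = c(2, 1), MoCA = c(23, 3))
                        ),
                        dropout_rate = 0,
                        seed = NULL) {
  if (!setequal(names(class_proportions), c("upward_linear", "s_shape"))) {
    stop("'class_proportions' must be named upward_linear and s_shape", call. = FALSE)
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("'class_proportions' must sum to 1", call. = FALSE)
  }
  if (stay_min < 8) stop("'stay_min' must be >= 8 (all feature windows must exist)", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) stop("'dropout_rate' must be in [0, 1)", call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients),
    class_proportions = class_proportions[c("upward_linear", "s_shape")],
    stay_mean = stay_mean, stay_sd = stay_sd, stay_min = as.integer(stay_min),
    noise_scale = noise_scale,
    archetype_params = archetype_params,
    clinical_params = clinical_params,
    dropout_rate = dropout_rate,
    seed = seed
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_patients, "patients;",
      paste(sprintf("%s %.0f%%", names(x$class_proportions),
                    100 * x$class_proportions), collapse = ", "), "\n")
  cat("  stay ~ N(", x$stay_mean, ",", x$stay_sd, ") truncated at >=",
      x$stay_min, "days; noise scale", x$noise_scale, "\n")
  invisible(x)
}

# Largest-remainder apportionment of n into proportions p.
largest_remainder <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    idx <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[idx] <- counts[idx] + 1
  }
  as.integer(counts)
}

# Truncated-normal draws by rejection; fine for the mild truncations used here.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

draw_archetype <- function(label, pars) {
  p <- pars[[label]]
  if (label == "upward_linear") {
    trajectory_archetype("upward_linear",
      i0 = rtnorm(1, p$i0[1], p$i0[2], lower = 0),
      s  = rtnorm(1, p$s[1], p$s[2], lower = 0.02))
  } else {
    L0 <- rtnorm(1, p$L0[1], p$L0[2], lower = 0.1)
    trajectory_archetype("s_shape",
      L0 = L0,
      L1 = rtnorm(1, p$L1[1], p$L1[2], lower = L0 + 1),
      t0 = rtnorm(1, p$t0[1], p$t0[2], lower = 4),
      k  = rtnorm(1, p$k[1], p$k[2], lower = 0.15))
  }
}

draw_clinical <- function(label, pars) {
  p <- pars[[label]]
  ranges <- list(BI = c(0, 20), FMS = c(0, 5), FAC = c(0, 5), MoCA = c(0, 30))
  vapply(names(ranges), function(sc) {
    as.integer(round(rtnorm(1, p[[sc]][1], p[[sc]][2],
                            lower = ranges[[sc]][1], upper = ranges[[sc]][2])))
  }, integer(1))
}

#' Generate a synthetic cohort
#'
#' Draws a full synthetic cohort from a [cohort_spec()]: per-patient pattern
#' labels (largest-remainder class counts), lengths of stay, archetype
#' parameters, daily intensity trajectories and clinical scores. With a fixed
#' `seed` in the spec the cohort is bit-identical across runs.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `activity_cohort`: a list with
#'   \describe{
#'     \item{patients}{data frame `patient_id, label, BI, FMS, FAC, MoCA, stay_days`}
#'     \item{daily}{data frame `patient_id, rehab_day, intensity` (1-based days;
#'       dropped-out days carry `NA` intensity)}
#'     \item{spec}{the generating spec}
#'   }
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 12, seed = 1))
#' table(cohort$patients$label)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec", call. = FALSE)
  if (!is.null(spec$seed)) set.seed(stage_seed(spec$seed, "cohort"))
  counts <- largest_remainder(spec$n_patients, spec$class_proportions)
  if (any(counts < 2)) {
    stop("each class needs at least 2 patients for a stratified split", call. = FALSE)
  }
  labels <- rep(names(spec$class_proportions), counts)

  patients <- vector("list", spec$n_patients)
  daily <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    id <- sprintf("P%03d", i)
    stay <- as.integer(round(rtnorm(1, spec$stay_mean, spec$stay_sd,
                                    lower = spec$stay_min - 0.49)))
    arch <- draw_archetype(labels[i], spec$archetype_params)
    traj <- generate_trajectory(arch, stay, spec$noise_scale)
    if (spec$dropout_rate > 0) {
      traj[stats::runif(stay) < spec$dropout_rate] <- NA_real_
    }
    clin <- draw_clinical(labels[i], spec$clinical_params)
    patients[[i]] <- data.frame(patient_id = id, label = labels[i],
                                BI = clin[["BI"]], FMS = clin[["FMS"]],
                                FAC = clin[["FAC"]], MoCA = clin[["MoCA"]],
                                stay_days = stay, stringsAsFactors = FALSE)
    daily[[i]] <- data.frame(patient_id = id, rehab_day = seq_len(stay),
                             intensity = traj, stringsAsFactors = FALSE)
  }
  structure(list(patients = do.call(rbind, patients),
                 daily = do.call(rbind, daily),
                 spec = spec),
            class = "activity_cohort")
}

#' @export
print.activity_cohort <- function(x, ...) {
  tab <- table(x$patients$label)
  cat("<activity_cohort>", nrow(x$patients), "patients (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n")
  cat("  stay", min(x$patients$stay_days), "-", max(x$patients$stay_days),
      "days;", nrow(x$daily), "patient-days\n")
  invisible(x)
}

#' Write / read a cohort as CSV files
#'
#' `write_cohort()` writes `daily_intensity.csv` (`patient_id, rehab_day,
#' intensity`) and `patients.csv` (`patient_id, label, BI, FMS, FAC, MoCA,
#' stay_days`) into `dir`; `read_cohort()` reads them back. The daily file
#' schema matches the output of [daily_intensity()], so measured and
#' simulated inputs are interchangeable downstream.
#'
#' @param cohort An `activity_cohort` (or a list with `patients` and `daily`
#'   data frames).
#' @param dir Directory to write to / read from.
#' @return `write_cohort()` returns the file paths invisibly;
#'   `read_cohort()` returns an `activity_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fd <- file.path(dir, "daily_intensity.csv")
  fp <- file.path(dir, "patients.csv")
  utils::write.csv(cohort$daily, fd, row.names = FALSE)
  utils::write.csv(cohort$patients, fp, row.names = FALSE)
  invisible(c(daily = fd, patients = fp))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  daily <- utils::read.csv(file.path(dir, "daily_intensity.csv"),
                           stringsAsFactors = FALSE)
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE)
  structure(list(patients = patients, daily = daily, spec = NULL),
            class = "activity_cohort")
}
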