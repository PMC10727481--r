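#' Trajectory archetypes for daily activity intensity
#'
#' Constructs one of the two recovery-trajectory archetypes observed in
#' hip-fracture rehabilitation cohorts: an upward-linear rise of daily
#' overall activity intensity, or a logistic "S-shape" with a slow start, a
#' steep mid-stay rise and an end-of-stay plateau.
#'
#' The expected intensity on rehabilitation day \eqn{t} (1-based) is
#' \itemize{
#'   \item upward_linear: \eqn{i_0 + s t}, with intercept \eqn{i_0 \ge 0} and
#'     slope \eqn{s > 0};
#'   \item s_shape: \eqn{L_0 + (L_1 - L_0) / (1 + e^{-k (t - t_0)})}, with
#'     lower asymptote \eqn{L_0}, upper asymptote \eqn{L_1 > L_0}, inflection
#'     day \eqn{t_0} and steepness \eqn{k > 0}.
#' }
#' Both curves are non-decreasing in expectation.
#'
#' @param name `"upward_linear"` or `"s_shape"`.
#' @param i0,s Intercept and slope of the linear archetype.
#' @param L0,L1,t0,k Lower/upper asymptote, inflection day and steepness of
#'   the S-shape archetype.
#' @return An object of class `trajectory_archetype`.
#' @seealso [generate_trajectory()], [generate_cohort()]
#' @export
#' @examples
#' trajectory_archetype("upward_linear", i0 = 1, s = 0.5)
#' trajectory_archetype("s_shape", L0 = 1, L1 = 10, t0 = 7, k = 1)
trajectory_archetype <- function(name = c("upward_linear", "s_shape"),
                                 i0 = NULL, s = NULL,
                                 L0 = NULL, L1 = NULL, t0 = NULL, k = NULL) {
  name <- match.arg(name)
  if (name == "upward_linear") {
    stopifnot_scalar(i0, "i0"); stopifnot_scalar(s, "s")
    if (i0 < 0) stop("intercept 'i0' must be >= 0", call. = FALSE)
    if (s <= 0) stop("slope 's' must be > 0", call. = FALSE)
    params <- list(i0 = i0, s = s)
  } else {
    stopifnot_scalar(L0, "L0"); stopifnot_scalar(L1, "L1")
    stopifnot_scalar(t0, "t0"); stopifnot_scalar(k, "k")
    if (L1 <= L0) stop("'L1' must exceed 'L0'", call. = FALSE)
    if (L0 < 0) stop("'L0' must be >= 0", call. = FALSE)
    if (k <= 0) stop("steepness 'k' must be > 0", call. = FALSE)
    params <- list(L0 = L0, L1 = L1, t0 = t0, k = k)
  }
  structure(list(name = name, params = params), class = "trajectory_archetype")
}

#' @export
print.trajectory_archetype <- function(x, ...) {
  cat("<trajectory_archetype>", x$name, "\n")
  cat(" ", paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# Expected (noise-free) intensity on days 1..stay_days.
archetype_curve <- function(archetype, days) {
  p <- archetype$params
  switch(archetype$name,
    upward_linear = p$i0 + p$s * days,
    s_shape = p$L0 + (p$L1 - p$L0) / (1 + exp(-p$k * (days - p$t0)))
  )
}

#' Simulate one daily-intensity trajectory
#'
#' Draws a per-day intensity series around an archetype curve with
#' multiplicative lognormal day-level noise. The noise term
#' \eqn{e^{\sigma Z - \sigma^2/2}} has unit mean, so the expectation of the
#' simulated series equals the archetype curve for any noise scale; with
#' `noise_scale = 0` the curve is returned exactly. Intensities are clipped
#' at zero (lognormal noise keeps them positive anyway).
#'
#' @param archetype A [trajectory_archetype()].
#' @param stay_days Length of stay in days; at least 8 so that all feature
#'   windows (first 5-8 days) exist.
#' @param noise_scale Standard deviation \eqn{\sigma} of the lognormal noise
#'   on the log scale; nonnegative.
#' @return Numeric vector of `stay_days` nonnegative intensities, one per
#'   rehabilitation day (day 1 first).
#' @export
#' @examples
#' generate_trajectory(trajectory_archetype("upward_linear", i0 = 1, s = 0.5), 10, 0)
generate_trajectory <- function(archetype, stay_days, noise_scale = 0) {
  if (!inherits(archetype, "trajectory_archetype")) {
    stop("'archetype' must be a trajectory_archetype", call. = FALSE)
  }
  if (stay_days < 8) {
    stop("'stay_days' must be >= 8 (feature windows of 5-8 days must exist)",
         call. = FALSE)
  }
  if (noise_scale < 0) stop("'noise_scale' must be >= 0", call. = FALSE)
  mu <- archetype_curve(archetype, seq_len(stay_days))
  if (noise_scale > 0) {
    mu <- mu * exp(stats::rnorm(stay_days, 0, noise_scale) - noise_scale^2 / 2)
  }
  pmax(mu, 0)
}
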