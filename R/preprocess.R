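#' Preprocessing configuration for raw accelerometer streams
#'
#' Holds the filter chain and daytime-window settings used to turn a raw
#' 25 Hz triaxial stream into one overall-intensity value per day: a short
#' moving-average filter to suppress measurement noise, a high-pass
#' Butterworth filter to remove the gravity component, and the daytime window
#' over which the signal magnitude area is accumulated.
#'
#' @param fs_hz Sampling frequency in Hz.
#' @param ma_window_s Moving-average window in seconds; rounded to the
#'   nearest odd number of samples (0.12 s at 25 Hz = 3 samples).
#' @param hp_order Butterworth high-pass filter order.
#' @param hp_cutoff_hz High-pass cutoff frequency in Hz; must be below the
#'   Nyquist frequency `fs_hz / 2`.
#' @param day_start,day_end Daytime window bounds as `"HH:MM"` strings;
#'   samples outside `[day_start, day_end)` are ignored.
#' @return An object of class `filter_config`.
#' @export
#' @examples
#' filter_config()
filter_config <- function(fs_hz = 25, ma_window_s = 0.12,
                          hp_order = 4, hp_cutoff_hz = 1,
                          day_start = "07:00", day_end = "22:00") {
  if (fs_hz <= 0) stop("'fs_hz' must be positive", call. = FALSE)
  if (hp_cutoff_hz >= fs_hz / 2) {
    stop("'hp_cutoff_hz' must be below the Nyquist frequency fs_hz/2", call. = FALSE)
  }
  w <- ma_samples(ma_window_s, fs_hz)
  if (w < 1) stop("'ma_window_s' must span at least one sample", call. = FALSE)
  start_min <- parse_hhmm(day_start)
  end_min <- parse_hhmm(day_end)
  if (end_min <= start_min) stop("'day_end' must be after 'day_start'", call. = FALSE)
  structure(list(fs_hz = fs_hz, ma_window_s = ma_window_s,
                 hp_order = as.integer(hp_order), hp_cutoff_hz = hp_cutoff_hz,
                 day_start = day_start, day_end = day_end),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config> fs", x$fs_hz, "Hz; MA", x$ma_window_s, "s (",
      ma_samples(x$ma_window_s, x$fs_hz), "samples ); HP Butterworth order",
      x$hp_order, ", cutoff", x$hp_cutoff_hz, "Hz; daytime",
      x$day_start, "-", x$day_end, "\n")
  invisible(x)
}

parse_hhmm <- function(s) {
  parts <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
  if (length(parts) != 2 || anyNA(parts)) stop("time must be 'HH:MM'", call. = FALSE)
  parts[1] * 60 + parts[2]
}

# Window length in samples, rounded to the nearest odd integer (>= 1).
ma_samples <- function(window_s, fs_hz) {
  w <- max(1L, as.integer(round(window_s * fs_hz)))
  if (w %% 2L == 0L) w + 1L else w
}

#' Centred moving-average filter
#'
#' Averages each sample with its neighbours over a centred window; windows
#' shrink symmetrically-as-possible at the edges so the output has the same
#' length as the input and a constant signal is left unchanged.
#'
#' @param x Numeric signal (one axis).
#' @param config A [filter_config()]; its `ma_window_s` and `fs_hz` set the
#'   window length.
#' @return Filtered signal of the same length.
#' @export
moving_average <- function(x, config = filter_config()) {
  if (length(x) == 0) stop("empty signal", call. = FALSE)
  w <- ma_samples(config$ma_window_s, config$fs_hz)
  if (w == 1L) return(x)
  n <- length(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' High-pass Butterworth filter (gravity removal)
#'
#' Applies a causal Butterworth high-pass filter, designed with
#' [signal::butter()], forward-only. The filter state is initialised at the
#' steady state corresponding to the first sample's level, so a constant
#' (gravity-only) input maps to zero output with no start-up transient; each
#' day segment is filtered independently.
#'
#' @param x Numeric signal (one axis).
#' @param config A [filter_config()].
#' @return Filtered signal of the same length.
#' @export
butterworth_highpass <- function(x, config = filter_config()) {
  if (length(x) == 0) stop("empty signal", call. = FALSE)
  if (config$hp_cutoff_hz >= config$fs_hz / 2) {
    stop("cutoff must be below Nyquist", call. = FALSE)
  }
  bf <- signal::butter(config$hp_order, config$hp_cutoff_hz / (config$fs_hz / 2),
                       type = "high")
  b <- bf$b; a <- bf$a
  # steady state for constant input x[1]: past inputs x[1], past outputs x[1]*H(1)
  y_ss <- x[1] * sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1L),
                            init.y = rep(y_ss, length(a) - 1L)))
}

# |H(e^{j 2 pi f / fs})| of a digital filter with coefficients b, a.
digital_filter_gain <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  zb <- exp(-1i * w * (seq_along(b) - 1))
  za <- exp(-1i * w * (seq_along(a) - 1))
  Mod(sum(b * zb) / sum(a * za))
}

# Combined gain of the moving-average + Butterworth chain at frequency f.
preprocess_chain_gain <- function(f, config) {
  w <- ma_samples(config$ma_window_s, config$fs_hz)
  bf <- signal::butter(config$hp_order, config$hp_cutoff_hz / (config$fs_hz / 2),
                       type = "high")
  digital_filter_gain(rep(1 / w, w), 1, f, config$fs_hz) *
    digital_filter_gain(bf$b, bf$a, f, config$fs_hz)
}

#' Signal magnitude area
#'
#' The overall physical-activity intensity of an epoch: the area under the
#' rectified acceleration curves of all three axes, normalised by the epoch
#' duration,
#' \deqn{SMA = \frac{1}{T} \sum_{axes} \sum_t |a(t)| \Delta t
#'          = \mathrm{mean}_t (|a_x| + |a_y| + |a_z|),}
#' in units of g. Normalising by duration keeps days with different in-window
#' durations comparable; the un-normalised area is `SMA * T`.
#'
#' @param ax,ay,az Filtered per-axis acceleration (g), equal lengths.
#' @param fs_hz Sampling frequency in Hz.
#' @param epoch_s Epoch length in seconds; `NULL` (default) treats the whole
#'   input as one epoch. Must not exceed the stream duration.
#' @return Numeric vector of per-epoch SMA values (one value when
#'   `epoch_s = NULL`).
#' @export
#' @examples
#' t <- seq(0, 10, by = 1/25)
#' signal_magnitude_area(sin(2 * pi * t), 0 * t, 0 * t, fs_hz = 25)  # ~ 2/pi
signal_magnitude_area <- function(ax, ay, az, fs_hz = 25, epoch_s = NULL) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n) {
    stop("all three axes must have the same length", call. = FALSE)
  }
  if (n == 0) stop("empty signal", call. = FALSE)
  total <- abs(ax) + abs(ay) + abs(az)
  if (is.null(epoch_s)) return(mean(total))
  ne <- as.integer(round(epoch_s * fs_hz))
  if (ne > n) stop("epoch is longer than the stream", call. = FALSE)
  n_epochs <- n %/% ne
  idx <- rep(seq_len(n_epochs), each = ne)
  as.numeric(tapply(total[seq_len(n_epochs * ne)], idx, mean))
}

#' Per-day activity intensity from a raw stream
#'
#' Runs the full preprocessing chain per calendar day: restrict to the
#' daytime window, moving-average filter, high-pass Butterworth filter
#' (each axis, each day independently), then one signal-magnitude-area value
#' over the in-window samples. Days between the first and last date with no
#' in-window samples are kept as explicit `NA` (missing), never as zero.
#'
#' @param stream Data frame with columns `time` (POSIXct), `ax`, `ay`, `az`
#'   (acceleration in g).
#' @param config A [filter_config()].
#' @return Data frame `rehab_day` (1-based, contiguous), `date`, `intensity`
#'   of class `daily_intensity`; a `patient_id` column is carried through
#'   when present in `stream`.
#' @export
daily_intensity <- function(stream, config = filter_config()) {
  stopifnot(all(c("time", "ax", "ay", "az") %in% names(stream)))
  if (nrow(stream) == 0) stop("empty stream", call. = FALSE)
  lt <- as.POSIXlt(stream$time)
  date <- as.Date(stream$time, tz = attr(as.POSIXct(stream$time), "tzone") %||% "UTC")
  tod_min <- lt$hour * 60 + lt$min + lt$sec / 60
  in_window <- tod_min >= parse_hhmm(config$day_start) &
    tod_min < parse_hhmm(config$day_end)

  all_days <- seq(min(date), max(date), by = "day")
  intensity <- vapply(all_days, function(d) {
    sel <- in_window & date == d
    if (!any(sel)) return(NA_real_)
    f <- function(x) butterworth_highpass(moving_average(x, config), config)
    signal_magnitude_area(f(stream$ax[sel]), f(stream$ay[sel]), f(stream$az[sel]),
                          fs_hz = config$fs_hz)
  }, numeric(1))

  out <- data.frame(rehab_day = seq_along(all_days), date = all_days,
                    intensity = intensity)
  if (!is.null(stream$patient_id)) out$patient_id <- stream$patient_id[1]
  class(out) <- c("daily_intensity", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a)) || identical(a, "")) b else a

#' Gaussian-weighted moving-average smoothing of a daily series
#'
#' Smooths a daily intensity series with a normalised Gaussian kernel over a
#' centred window, renormalising the weights at the edges so a constant
#' series is preserved exactly. Used for visualising and rating trajectory
#' shapes; the feature path operates on the unsmoothed series by default.
#'
#' @param x Numeric daily series.
#' @param window_days Odd window length in days (default 5).
#' @param sigma Kernel standard deviation in days; default `(window_days - 1) / 4`.
#' @return Smoothed series, same length as `x`.
#' @export
gaussian_smooth <- function(x, window_days = 5, sigma = (window_days - 1) / 4) {
  if (window_days < 1) stop("'window_days' must be >= 1", call. = FALSE)
  window_days <- as.integer(window_days)
  if (window_days %% 2L == 0L) window_days <- window_days + 1L
  if (window_days == 1L) return(x)
  h <- (window_days - 1L) %/% 2L
  offsets <- -h:h
  w <- exp(-offsets^2 / (2 * sigma^2))
  n <- length(x)
  vapply(seq_len(n), function(i) {
    j <- i + offsets
    ok <- j >= 1 & j <= n
    sum(w[ok] * x[j[ok]]) / sum(w[ok])
  }, numeric(1))
}
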