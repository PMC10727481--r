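#' Synthesise a raw triaxial accelerometer stream from daily targets
#'
#' Emits a 25 Hz-style triaxial stream whose per-day overall intensity,
#' after the full preprocessing chain ([moving_average()] ->
#' [butterworth_highpass()] -> [signal_magnitude_area()] inside
#' [daily_intensity()]), matches each day's target value. Activity is a
#' sinusoid of frequency `freq_hz` on the x axis; the amplitude for a day
#' with target \eqn{T} is calibrated from the closed-form mean of a rectified
#' sinusoid, \eqn{\mathrm{mean} |A \sin|= 2A/\pi}, corrected by the measured
#' gain of the filter chain at `freq_hz`, so the round trip is exact up to
#' edge effects. A constant +1 g gravity component sits on the z axis, so
#' high-pass filtering is genuinely exercised. The generator is
#' deterministic: the same targets and configuration always produce the same
#' stream.
#'
#' Samples are only emitted inside the daytime window of `config`; a day with
#' target 0 carries gravity only.
#'
#' @param daily_targets Nonnegative per-day intensity targets (g), day 1 first.
#' @param config A [filter_config()]; sets the sampling frequency and the
#'   daytime window.
#' @param freq_hz Activity sinusoid frequency (Hz); must sit well inside the
#'   high-pass passband and below Nyquist.
#' @param start_date First calendar date of the stream.
#' @return Data frame `time` (POSIXct, UTC), `ax`, `ay`, `az` (g).
#' @export
#' @examples
#' cfg <- filter_config(day_start = "08:00", day_end = "08:02")
#' stream <- generate_raw_stream(c(0.4, 0.8), config = cfg)
#' daily_intensity(stream, cfg)
generate_raw_stream <- function(daily_targets, config = filter_config(),
                                freq_hz = 2, start_date = as.Date("2024-01-01")) {
  if (config$fs_hz <= 0) stop("sampling frequency must be positive", call. = FALSE)
  if (any(daily_targets < 0)) stop("'daily_targets' must be >= 0", call. = FALSE)
  if (freq_hz <= config$hp_cutoff_hz || freq_hz >= config$fs_hz / 2) {
    stop("'freq_hz' must lie between the high-pass cutoff and Nyquist", call. = FALSE)
  }
  fs <- config$fs_hz
  start_s <- parse_hhmm(config$day_start) * 60
  end_s <- parse_hhmm(config$day_end) * 60
  n_per_day <- as.integer(floor((end_s - start_s) * fs))
  gain <- preprocess_chain_gain(freq_hz, config)

  t_rel <- (seq_len(n_per_day) - 1L) / fs
  days <- lapply(seq_along(daily_targets), function(d) {
    amp <- daily_targets[d] * pi / (2 * gain)
    day_origin <- as.POSIXct(start_date, tz = "UTC") + (d - 1L) * 86400 + start_s
    data.frame(time = day_origin + t_rel,
               ax = amp * sin(2 * pi * freq_hz * t_rel),
               ay = 0,
               az = 1)
  })
  do.call(rbind, days)
}
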