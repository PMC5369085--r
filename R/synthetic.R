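#' Generate a synthetic hourly pollutant concentration series
#'
#' Emulates the qualitative shape of urban hourly pollutant data: a positive
#' baseline, a 24-hour diurnal cycle, AR(1)-autocorrelated Gaussian noise,
#' and occasional exponential-magnitude pollution spikes, with the result
#' clipped at zero so concentrations stay physical. The marginal is
#' right-skewed (clipping plus one-sided spikes), which is the regime the
#' parametric distribution fits in [fit_distribution()] target.
#'
#' @param n_hours Series length (hours), at least 48.
#' @param baseline Mean concentration level, in ug/m3 (> 0).
#' @param diurnal_amplitude Amplitude of the 24-hour sinusoid, ug/m3.
#' @param ar_coefficient Lag-1 autocorrelation of the noise term, in `[0, 1)`.
#' @param noise_scale Marginal standard deviation of the AR(1) noise, ug/m3.
#' @param spike_rate Probability per hour of an additive spike.
#' @param spike_scale Mean spike magnitude (exponential), ug/m3.
#' @param start Timestamp of the first observation.
#' @param criterion Pollutant label attached to the series.
#' @param seed Optional integer; when supplied the series is reproducible
#'   and the ambient RNG state is left untouched.
#'
#' @return A tibble with columns `timestamp` (POSIXct, hourly), `value`
#'   (ug/m3, finite and non-negative) and `criterion`.
#'
#' @examples
#' x <- generate_series(n_hours = 72, baseline = 40, seed = 1)
#' range(x$value)
#' @export
generate_series <- function(n_hours = 2000,
                            baseline = 45,
                            diurnal_amplitude = 8,
                            ar_coefficient = 0.85,
                            noise_scale = 12,
                            spike_rate = 0.01,
                            spike_scale = 30,
                            start = as.POSIXct("2015-01-01 00:00:00", tz = "UTC"),
                            criterion = "PM2.5",
                            seed = NULL) {
  check_number(n_hours, "n_hours", min = 48)
  check_number(baseline, "baseline", min = 0, strict = TRUE)
  check_number(diurnal_amplitude, "diurnal_amplitude", min = 0)
  check_number(noise_scale, "noise_scale", min = 0)
  check_number(spike_rate, "spike_rate", min = 0)
  check_number(spike_scale, "spike_scale", min = 0)
  if (!is.numeric(ar_coefficient) || length(ar_coefficient) != 1L ||
      ar_coefficient < 0 || ar_coefficient >= 1) {
    abort("`ar_coefficient` must be a single number in [0, 1).")
  }
  n_hours <- as.integer(n_hours)

  values <- with_seed_or_stream(seed, {
    hours <- seq_len(n_hours) - 1L
    diurnal <- diurnal_amplitude * sin(2 * pi * hours / 24)
    # AR(1) with stationary marginal sd = noise_scale, started in
    # stationarity so early hours are not systematically calmer.
    innov_sd <- noise_scale * sqrt(1 - ar_coefficient^2)
    noise <- numeric(n_hours)
    if (noise_scale > 0) {
      noise[1L] <- rnorm(1L, 0, noise_scale)
      eps <- rnorm(n_hours - 1L, 0, innov_sd)
      for (t in seq_len(n_hours - 1L)) {
        noise[t + 1L] <- ar_coefficient * noise[t] + eps[t]
      }
    }
    spikes <- rexp(n_hours, rate = 1 / max(spike_scale, .Machine$double.eps)) *
      (runif(n_hours) < spike_rate)
    if (spike_scale == 0) spikes <- numeric(n_hours)
    pmax(baseline + diurnal + noise + spikes, 0)
  })

  tibble::tibble(
    timestamp = start + 3600 * (seq_len(n_hours) - 1L),
    value = values,
    criterion = criterion
  )
}
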