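#' One well-phase fluorescence recording
#'
#' Thin container pairing a numeric sample vector with its sampling rate.
#' Ground-truth beat peak times are attached by [generate_trace()] as the
#' attribute `"true_peak_times"` for testing; analysis code never reads it.
#'
#' @param samples Numeric vector of fluorescence samples (a.u.).
#' @param sampling_rate Sampling rate in Hz.
#' @param phase Optional phase tag (`"baseline"`, `"post15"`, `"post30"`).
#' @return An object of class `trace_recording`.
#' @export
trace_recording <- function(samples, sampling_rate, phase = NULL) {
  if (!is.numeric(samples) || length(samples) == 0) {
    ct_stop("`samples` must be a non-empty numeric vector", "cthazard_invalid_argument")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    ct_stop("`sampling_rate` must be > 0", "cthazard_invalid_argument")
  }
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate, phase = phase),
    class = "trace_recording"
  )
}

#' @export
print.trace_recording <- function(x, ...) {
  cat(sprintf(
    "<trace_recording> %d samples @ %.1f Hz (%.1f s)%s\n",
    length(x$samples), x$sampling_rate, length(x$samples) / x$sampling_rate,
    if (is.null(x$phase)) "" else paste0(" [", x$phase, "]")
  ))
  invisible(x)
}

# Evaluate the per-beat kernel on absolute times `t` (ms) for a beat whose
# peak is at `peak_ms`. Logistic rise (normalized to hit `amplitude` exactly
# at the peak) then exponential decay.
beat_kernel <- function(t, peak_ms, amplitude, tau_up, tau_decay) {
  out <- numeric(length(t))
  pre <- t <= peak_ms
  out[pre] <- amplitude *
    stats::plogis((t[pre] - (peak_ms - .rise_centre_tc * tau_up)) / tau_up) / .rise_norm
  out[!pre] <- amplitude * exp(-(t[!pre] - peak_ms) / tau_decay)
  out
}

#' Generate a synthetic calcium-transient recording
#'
#' Renders a [transient_shape()] into a sampled fluorescence trace: periodic
#' beat kernels (logistic upstroke, exponential decay) on a constant baseline
#' with additive Gaussian noise. Optional abnormal phenotypes can be
#' synthesized: EAD-like secondary spikes injected during the decay phase of
#' randomly chosen beats, a fibrillation-like terminal segment of small
#' rapid-rate transients, or beating arrest (flat noise) after a stop time.
#'
#' Identical arguments (including `seed`) give bitwise-identical traces.
#'
#' @param shape A [transient_shape()].
#' @param duration_s Recording length in seconds; at least 60 s so a one-
#'   minute analysis window fits.
#' @param sampling_rate Sampling rate in Hz (instrument default 66.7).
#' @param seed Optional integer seed for noise, beat phase and event
#'   placement; `NULL` uses the current RNG stream.
#' @param n_eads Number of beats that receive an injected EAD-like secondary
#'   spike (20-60% of beat amplitude, placed 30-60% of a period after the
#'   peak).
#' @param fibrillation If `TRUE`, the final `fib_duration_s` seconds are
#'   replaced by transients at `fib_rate_factor` times the native rate and
#'   `fib_amp_factor` times the native amplitude.
#' @param fib_duration_s,fib_rate_factor,fib_amp_factor Fibrillation-segment
#'   parameters (defaults 35 s, 3.5x rate, 0.25x amplitude).
#' @param arrest_at_s If non-`NULL`, no beats occur after this time (seconds);
#'   the trace is flat noise from there on.
#' @param start_offset_s Time of the first beat peak (seconds). `NULL` draws
#'   it uniformly from one period so wells are not phase-locked.
#' @return A [trace_recording()].
#' @export
#' @examples
#' tr <- generate_trace(transient_shape(noise_sd = 0), duration_s = 60,
#'                      sampling_rate = 66.7, seed = 1)
#' tr
generate_trace <- function(shape, duration_s = 75, sampling_rate = 66.7,
                           seed = NULL,
                           n_eads = 0, fibrillation = FALSE,
                           fib_duration_s = 35, fib_rate_factor = 3.5,
                           fib_amp_factor = 0.25,
                           arrest_at_s = NULL, start_offset_s = NULL) {
  stopifnot(inherits(shape, "transient_shape"))
  if (!is.numeric(duration_s) || duration_s < 60) {
    ct_stop("`duration_s` must be at least 60 s (a 1-min analysis window must fit)",
            "cthazard_invalid_argument")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    ct_stop("`sampling_rate` must be > 0", "cthazard_invalid_argument")
  }
  if (!is.null(seed)) set.seed(seed)

  dt_ms <- 1000 / sampling_rate
  n <- floor(duration_s * sampling_rate)
  t_ms <- (seq_len(n) - 1) * dt_ms
  dur_ms <- duration_s * 1000

  if (is.null(start_offset_s)) {
    first_peak <- stats::runif(1, 0, shape$period)
  } else {
    first_peak <- start_offset_s * 1000
  }
  peaks <- seq(first_peak, dur_ms, by = shape$period)

  stop_ms <- if (!is.null(arrest_at_s)) arrest_at_s * 1000 else Inf
  fib_start_ms <- if (fibrillation) max(0, dur_ms - fib_duration_s * 1000) else Inf
  normal_peaks <- peaks[peaks < min(stop_ms, fib_start_ms)]

  x <- rep(shape$baseline_level, n)
  add_beat <- function(x, peak_ms, amplitude, tau_up, tau_decay) {
    lo <- max(1L, floor((peak_ms - 9 * tau_up) / dt_ms) + 1L)
    hi <- min(n, ceiling((peak_ms + 12 * tau_decay) / dt_ms) + 1L)
    if (hi < lo) return(x)
    idx <- lo:hi
    x[idx] <- x[idx] +
      beat_kernel(t_ms[idx], peak_ms, amplitude, tau_up, tau_decay)
    x
  }
  for (p in normal_peaks) {
    x <- add_beat(x, p, shape$amplitude,
                  shape$upstroke_time_constant, shape$decay_time_constant)
  }

  true_peaks <- normal_peaks

  # EAD-like secondary spikes during the decay phase of randomly chosen beats
  if (n_eads > 0 && length(normal_peaks) > 2) {
    eligible <- normal_peaks[normal_peaks + 0.9 * shape$period < dur_ms]
    k <- min(n_eads, length(eligible))
    host <- sort(sample(eligible, k))
    ctd <- implied_ctd90(shape)
    for (p in host) {
      frac <- stats::runif(1, 0.2, 0.6)      # 20-60% of beat amplitude
      at <- p + min(stats::runif(1, 0.4, 0.75) * ctd, 0.75 * shape$period)
      x <- add_beat(x, at, frac * shape$amplitude, 6, 50)
    }
  }

  # fibrillation-like segment: small, rapid-rate transients
  if (fibrillation) {
    fib_period <- shape$period / fib_rate_factor
    fib_tau_decay <- 0.55 * fib_period / log(10)
    fib_tau_up <- min(shape$upstroke_time_constant, 0.04 * fib_period)
    fib_peaks <- seq(fib_start_ms + fib_period / 2, dur_ms, by = fib_period)
    for (p in fib_peaks) {
      x <- add_beat(x, p, fib_amp_factor * shape$amplitude, fib_tau_up, fib_tau_decay)
    }
  }

  if (shape$noise_sd > 0) {
    x <- x + stats::rnorm(n, sd = shape$noise_sd)
  }

  tr <- trace_recording(x, sampling_rate)
  attr(tr, "true_peak_times") <- true_peaks / 1000
  tr
}
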