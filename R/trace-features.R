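#' Analysis settings for feature extraction
#'
#' Collects the tunable thresholds of beat detection and phenotype calling.
#' Defaults are chosen for well-integrated fluorescence signals at ~66.7 Hz.
#'
#' @param window_s Length of the analysis window (s). Parameter medians and
#'   the beat rate are computed over the final `window_s` seconds of each
#'   recording phase.
#' @param refractory_s Minimum spacing between primary beat peaks (s).
#' @param beat_prominence_frac Minimum peak prominence as a fraction of the
#'   robust trace amplitude (2nd-98th percentile span) for a local maximum to
#'   count as a beat. At 0.5, EAD-like secondary spikes (<= 60% amplitude,
#'   riding on the decay) are not double-counted while true beats are.
#' @param noise_mult Noise floor: prominences must also exceed
#'   `noise_mult` times the robust noise estimate, so flat wells yield no
#'   beats.
#' @param ctd_fraction Decay fraction defining transient duration (0.9 =
#'   CTD90: first post-peak crossing of baseline + 10% of amplitude).
#' @param rise_fraction Upstroke reference: the time the signal rises through
#'   this fraction of beat amplitude before the peak (default 0.1).
#' @param ead_prominence_frac Minimum prominence of a secondary (EAD-like)
#'   spike as a fraction of the host beat's amplitude.
#' @param ead_noise_mult Noise floor multiplier for EAD prominences.
#' @param beat_stop_br Beat-rate threshold (beats/min) below which a well at
#'   the 30-min time point is called "beat stop" (strict `<`).
#' @param fib_rate_factor,fib_amp_factor,fib_min_duration_s Fibrillation
#'   call: a sustained segment of at least `fib_min_duration_s` seconds whose
#'   local rate is at least `fib_rate_factor` times baseline while the local
#'   transient amplitude is at most `fib_amp_factor` times baseline.
#' @return A list of class `ct_feature_config`.
#' @export
feature_config <- function(window_s = 60,
                           refractory_s = 0.15,
                           beat_prominence_frac = 0.5,
                           noise_mult = 10,
                           ctd_fraction = 0.9,
                           rise_fraction = 0.1,
                           ead_prominence_frac = 0.15,
                           ead_noise_mult = 8,
                           beat_stop_br = 5,
                           fib_rate_factor = 3,
                           fib_amp_factor = 0.3,
                           fib_min_duration_s = 20) {
  structure(as.list(environment()), class = "ct_feature_config")
}

# Robust noise scale from successive differences. The 10th percentile of
# |diff| is drawn from the quiescent (inter-beat) portion of the trace, so
# the estimate is not inflated by decay slopes; 0.1777 is the Gaussian
# scaling constant (P(|N(0, sd*sqrt(2))| <= 0.1777*sd) = 0.1).
estimate_noise_sd <- function(x) {
  d <- abs(diff(x))
  stats::quantile(d, 0.1, names = FALSE) / 0.1777
}

# Indices of strict local maxima (plateaus resolved to their first sample).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

# Prominence of candidate peaks relative to the deeper of the two minima
# separating each peak from its neighbouring candidates (trace ends count
# as boundaries). For quasi-periodic transient signals this equals the
# height above the higher adjacent col, and it is computable in O(n).
peak_prominence <- function(x, peaks) {
  m <- length(peaks)
  if (m == 0) return(numeric(0))
  bounds <- c(1L, peaks, length(x))
  # minimum of x between consecutive candidates (m + 1 gaps)
  gap_min <- vapply(seq_len(m + 1L), function(g) {
    min(x[bounds[g]:bounds[g + 1L]])
  }, numeric(1))
  x[peaks] - pmax(gap_min[seq_len(m)], gap_min[2:(m + 1L)])
}

# Candidate maxima filtered by prominence. Two stages: noise-scale local
# maxima sitting high on a transient's flank would otherwise act as
# neighbours with a high col and erode the true peak's prominence, so
# candidates below a small noise-referenced prominence are pruned first and
# prominence is recomputed on the survivors.
prominent_peaks <- function(x, threshold, noise_sd) {
  cand <- local_maxima(x)
  if (length(cand) == 0) return(list(peaks = integer(0), prominence = numeric(0)))
  prom <- peak_prominence(x, cand)
  prune <- min(5 * noise_sd, threshold)
  keep <- prom >= prune
  cand <- cand[keep]
  if (length(cand) == 0) return(list(peaks = integer(0), prominence = numeric(0)))
  prom <- peak_prominence(x, cand)
  keep <- prom >= threshold
  list(peaks = cand[keep], prominence = prom[keep])
}

#' Detect beats in a calcium-transient recording
#'
#' Finds primary calcium transients as local maxima whose topographic
#' prominence exceeds both a fraction of the robust trace amplitude and a
#' noise floor, then enforces a refractory period (keeping the more
#' prominent peak of any too-close pair). For each beat the upstroke time
#' (rise through 10% of amplitude), local baseline (minimum since the
#' previous peak), amplitude and CTD90 are measured; see [compute_ctd90()].
#'
#' @param trace A [trace_recording()] of at least 10 s.
#' @param config A [feature_config()].
#' @return A data frame with one row per beat: `peak_index`, `peak_time`
#'   (s), `peak_value`, `upstroke_time` (s), `local_baseline`, `amplitude`
#'   and `ctd90` (ms; `NA` when the decay never reaches the 90% level before
#'   the next beat).
#' @export
detect_beats <- function(trace, config = feature_config()) {
  stopifnot(inherits(trace, "trace_recording"))
  x <- trace$samples
  if (anyNA(x) || any(!is.finite(x))) {
    ct_stop("trace contains NA or non-finite samples", "cthazard_input_error")
  }
  fs <- trace$sampling_rate
  if (length(x) < 10 * fs) {
    ct_stop("trace must contain at least 10 s of samples", "cthazard_input_error")
  }

  noise_sd <- estimate_noise_sd(x)
  amp_robust <- diff(stats::quantile(x, c(0.02, 0.98), names = FALSE))
  threshold <- max(config$beat_prominence_frac * amp_robust,
                   config$noise_mult * noise_sd,
                   .Machine$double.eps)

  pk <- prominent_peaks(x, threshold, noise_sd)
  cand <- pk$peaks
  prom <- pk$prominence
  if (length(cand) == 0) return(empty_beats())

  # refractory period: greedy keep-most-prominent
  ord <- order(prom, decreasing = TRUE)
  min_gap <- config$refractory_s * fs
  accepted <- integer(0)
  for (i in ord) {
    if (all(abs(cand[i] - accepted) >= min_gap)) accepted <- c(accepted, cand[i])
  }
  peaks <- sort(accepted)

  measure_beats(x, fs, peaks, config)
}

empty_beats <- function() {
  data.frame(
    peak_index = integer(0), peak_time = numeric(0), peak_value = numeric(0),
    upstroke_time = numeric(0), local_baseline = numeric(0),
    amplitude = numeric(0), ctd90 = numeric(0)
  )
}

# Per-beat geometry given accepted peak indices.
measure_beats <- function(x, fs, peaks, config) {
  n <- length(x)
  k <- length(peaks)
  local_baseline <- upstroke_time <- amplitude <- ctd90 <- numeric(k)

  for (b in seq_len(k)) {
    i <- peaks[b]
    prev_end <- if (b == 1) 1L else peaks[b - 1]
    lb <- min(x[prev_end:i])
    amp <- x[i] - lb

    # upstroke reference: last rise through baseline + rise_fraction * amp
    lvl_up <- lb + config$rise_fraction * amp
    below <- which(x[prev_end:(i - 1)] <= lvl_up)
    if (length(below) == 0) {
      up_t <- (i - 1) / fs   # degenerate: peak hugs previous beat
    } else {
      j <- prev_end + below[length(below)] - 1L   # last sample at/below level
      frac <- if (x[j + 1] == x[j]) 0 else (lvl_up - x[j]) / (x[j + 1] - x[j])
      up_t <- (j - 1 + frac) / fs
    }

    next_up <- if (b < k) peaks[b + 1] else n
    local_baseline[b] <- lb
    amplitude[b] <- amp
    upstroke_time[b] <- up_t
    ctd90[b] <- ctd90_from_indices(x, fs, i, next_up, lb, amp, up_t, config)
  }
  data.frame(
    peak_index = peaks, peak_time = (peaks - 1) / fs, peak_value = x[peaks],
    upstroke_time = upstroke_time, local_baseline = local_baseline,
    amplitude = amplitude, ctd90 = ctd90
  )
}

# Time (ms) from the upstroke reference to the first post-peak crossing of
# baseline + (1 - ctd_fraction) * amplitude, linearly interpolated; NA when
# the decay never reaches the level before the search limit.
ctd90_from_indices <- function(x, fs, peak_i, limit_i, local_baseline, amp,
                               upstroke_time, config) {
  lvl <- local_baseline + (1 - config$ctd_fraction) * amp
  if (limit_i <= peak_i + 1) return(NA_real_)
  seg <- x[(peak_i + 1):limit_i]
  hit <- which(seg <= lvl)
  if (length(hit) == 0) return(NA_real_)
  j <- peak_i + hit[1]          # first sample at/below level
  x0 <- x[j - 1]; x1 <- x[j]
  frac <- if (x1 == x0) 0 else (x0 - lvl) / (x0 - x1)
  cross_t <- (j - 2 + frac) / fs
  (cross_t - upstroke_time) * 1000
}

#' Calcium transient duration at 90% decay for one beat
#'
#' Measures the time from the beat's upstroke reference (rise through 10% of
#' amplitude) to the first post-peak sample at or below
#' `local_baseline + 0.1 * amplitude`, with linear interpolation between
#' samples. Returns `NA` (the beat is excluded from well medians) when the
#' decay never reaches the level before the next beat's upstroke.
#'
#' @param trace A [trace_recording()].
#' @param beat One row of the data frame returned by [detect_beats()].
#' @param next_peak_index Search limit (index of the next beat's peak, or
#'   the end of the trace).
#' @param config A [feature_config()].
#' @return CTD90 in milliseconds, or `NA`.
#' @export
compute_ctd90 <- function(trace, beat, next_peak_index = length(trace$samples),
                          config = feature_config()) {
  stopifnot(inherits(trace, "trace_recording"))
  ctd90_from_indices(trace$samples, trace$sampling_rate, beat$peak_index,
                     next_peak_index, beat$local_baseline, beat$amplitude,
                     beat$upstroke_time, config)
}

#' Detect EAD-like secondary calcium spikes
#'
#' Counts secondary local maxima occurring between a beat's peak and the
#' next beat's upstroke, before that beat's decay completes (i.e. before the
#' 90%-decay crossing when one exists), whose prominence exceeds a
#' configured fraction of the host beat's amplitude (and a noise floor).
#'
#' @param trace A [trace_recording()].
#' @param beats Data frame from [detect_beats()].
#' @param config A [feature_config()].
#' @return A list with `flag` (any EAD found) and `count`.
#' @export
detect_eads <- function(trace, beats, config = feature_config()) {
  stopifnot(inherits(trace, "trace_recording"))
  if (nrow(beats) < 1) return(list(flag = FALSE, count = 0L))
  x <- trace$samples
  fs <- trace$sampling_rate
  noise_sd <- estimate_noise_sd(x)
  count <- 0L
  for (b in seq_len(nrow(beats))) {
    i <- beats$peak_index[b]
    lim <- if (b < nrow(beats)) {
      max(i + 2L, floor(beats$upstroke_time[b + 1] * fs) + 1L)
    } else {
      length(x)
    }
    if (lim <= i + 2L) next
    # decay-completion limit: stop at the 90%-decay crossing when reached
    if (!is.na(beats$ctd90[b])) {
      cross_i <- floor((beats$upstroke_time[b] + beats$ctd90[b] / 1000) * fs) + 2L
      lim <- min(lim, cross_i)
    }
    if (lim <= i + 2L) next
    span <- (i + 1L):lim
    loc <- local_maxima(x[span])
    if (length(loc) == 0) next
    cand <- span[loc]
    thr <- max(config$ead_prominence_frac * beats$amplitude[b],
               config$ead_noise_mult * noise_sd)
    # prominence within the inter-beat span only
    for (j in cand) {
      left_min <- min(x[(i + 1L):j])
      right_min <- min(x[j:lim])
      prom <- x[j] - max(left_min, right_min)
      if (prom >= thr) count <- count + 1L
    }
  }
  list(flag = count >= 1L, count = count)
}

#' Detect fibrillation-like activity
#'
#' Scans the recording in sliding windows and flags the well when a
#' sustained segment (default at least 20 s) shows a transient rate of at
#' least `fib_rate_factor` times the well's baseline beat rate while the
#' local transient amplitude is at most `fib_amp_factor` times the baseline
#' amplitude. Peaks inside each window are detected against the local signal
#' range, so the small rapid transients of a fibrillating segment are seen
#' even when they would fall below the primary beat threshold. A flat
#' (arrested) trace yields no transients and is never called fibrillation.
#'
#' @param trace A [trace_recording()] (a post-compound phase).
#' @param baseline_summary The well's baseline summary (a row with
#'   `beat_rate` and `amplitude_median`), from [summarize_phase()].
#' @param config A [feature_config()].
#' @return `TRUE` or `FALSE`.
#' @export
detect_fibrillation <- function(trace, baseline_summary, config = feature_config()) {
  stopifnot(inherits(trace, "trace_recording"))
  if (is.null(baseline_summary) ||
      is.na(baseline_summary$beat_rate) || is.na(baseline_summary$amplitude_median)) {
    ct_stop("baseline summary with beat_rate and amplitude_median is required",
            "cthazard_input_error")
  }
  base_br <- baseline_summary$beat_rate
  base_amp <- baseline_summary$amplitude_median
  if (base_br <= 0 || base_amp <= 0) return(FALSE)

  x <- trace$samples
  fs <- trace$sampling_rate
  win <- floor(config$fib_min_duration_s * fs)
  if (win < 2 || length(x) < win) return(FALSE)
  step <- max(1L, floor(win / 4))
  noise_sd <- estimate_noise_sd(x)

  starts <- unique(c(seq(1L, length(x) - win + 1L, by = step),
                     length(x) - win + 1L))
  for (s in starts) {
    seg <- x[s:(s + win - 1L)]
    # light smoothing for candidate selection only: at fibrillation-scale
    # amplitudes, single-sample noise reversals would otherwise fragment
    # the prominence of genuine transients
    sm <- stats::filter(seg, rep(1 / 3, 3), sides = 2)
    sm[c(1, length(seg))] <- seg[c(1, length(seg))]
    seg <- as.numeric(sm)
    amp_local <- diff(stats::quantile(seg, c(0.02, 0.98), names = FALSE))
    # the 3-point smoothing shrinks the noise scale by sqrt(3); the floor
    # follows so that small rapid transients stay above it
    thr <- max(0.5 * amp_local, config$noise_mult * noise_sd / sqrt(3))
    found <- prominent_peaks(seg, thr, noise_sd / sqrt(3))
    pk <- found$peaks
    if (length(pk) < 3) next
    rate <- length(pk) / config$fib_min_duration_s * 60
    med_prom <- stats::median(found$prominence)
    if (rate >= config$fib_rate_factor * base_br &&
        med_prom <= config$fib_amp_factor * base_amp) {
      return(TRUE)
    }
  }
  FALSE
}

#' Summarize one recording phase of a well
#'
#' Detects beats in the final `window_s` seconds of the recording and
#' reduces them to the per-well parameters: the median CTD90 and amplitude
#' over all beats in the window, and the beat rate as the number of beats in
#' the window per minute. Beats whose decay never reaches the 90% level are
#' excluded from the CTD90 median.
#'
#' @param trace A [trace_recording()].
#' @param config A [feature_config()].
#' @param phase Optional phase label stored in the result.
#' @return A one-row data frame: `phase`, `ctd90_median` (ms), `beat_rate`
#'   (beats/min), `amplitude_median` (a.u.), `n_beats`, `ead_detected`,
#'   `ead_count`.
#' @export
summarize_phase <- function(trace, config = feature_config(), phase = NA_character_) {
  stopifnot(inherits(trace, "trace_recording"))
  fs <- trace$sampling_rate
  n <- length(trace$samples)
  win_n <- min(n, floor(config$window_s * fs))
  window <- trace_recording(trace$samples[(n - win_n + 1L):n], fs)
  beats <- detect_beats(window, config)
  eads <- detect_eads(window, beats, config)
  minutes <- win_n / fs / 60
  data.frame(
    phase = phase,
    ctd90_median = if (nrow(beats)) stats::median(beats$ctd90, na.rm = TRUE) else NA_real_,
    beat_rate = nrow(beats) / minutes,
    amplitude_median = if (nrow(beats)) stats::median(beats$amplitude) else NA_real_,
    n_beats = nrow(beats),
    ead_detected = eads$flag,
    ead_count = eads$count,
    stringsAsFactors = FALSE
  )
}

#' Summarize a well across its recording phases
#'
#' Applies [summarize_phase()] to the baseline and post-compound recordings
#' of one well and derives the well-level flags:
#' * `beat_stop`: the 30-min beat rate is strictly below `beat_stop_br`
#'   (default 5 beats/min). A well with no beating at 15 min that has
#'   recovered by 30 min is *not* a beat stop; the 15-min recording is used
#'   only for observing EADs and fibrillation-like events.
#' * `ead_detected` / `ead_count`: OR (sum) over the 15- and 30-min phases.
#' * `fibrillation_detected`: OR of [detect_fibrillation()] over the 15- and
#'   30-min phases, referenced to the well's own baseline.
#'
#' @param traces Named list of [trace_recording()]s with elements `baseline`
#'   and `post30` (required) and `post15` (optional).
#' @param config A [feature_config()].
#' @return A list of class `well_summary`: per-phase summaries plus the
#'   well-level flags.
#' @export
summarize_well <- function(traces, config = feature_config()) {
  for (ph in c("baseline", "post30")) {
    if (is.null(traces[[ph]])) {
      ct_stop(paste0("missing required phase: ", ph), "cthazard_input_error")
    }
  }
  phases <- list(baseline = summarize_phase(traces$baseline, config, "baseline"))
  if (!is.null(traces$post15)) {
    phases$post15 <- summarize_phase(traces$post15, config, "post15")
  }
  phases$post30 <- summarize_phase(traces$post30, config, "post30")

  beat_stop <- phases$post30$beat_rate < config$beat_stop_br

  ead_count <- phases$post30$ead_count +
    if (!is.null(phases$post15)) phases$post15$ead_count else 0L
  fib <- FALSE
  if (phases$baseline$n_beats > 0) {
    for (ph in intersect(c("post15", "post30"), names(traces))) {
      if (detect_fibrillation(traces[[ph]], phases$baseline, config)) fib <- TRUE
    }
  }

  structure(
    list(
      phases = do.call(rbind, phases),
      beat_stop = beat_stop,
      ead_detected = ead_count >= 1L,
      ead_count = as.integer(ead_count),
      fibrillation_detected = fib
    ),
    class = "well_summary"
  )
}

#' @export
print.well_summary <- function(x, ...) {
  cat("<well_summary>\n")
  print(x$phases, row.names = FALSE)
  cat(sprintf(
    "beat_stop: %s | EADs: %d | fibrillation: %s\n",
    x$beat_stop, x$ead_count, x$fibrillation_detected
  ))
  invisible(x)
}
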