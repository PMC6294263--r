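#' Parametric description of one well's calcium-transient waveform
#'
#' A `transient_shape` describes the stereotyped calcium transient of a
#' spontaneously beating hiPSC-CM syncytium as a per-beat kernel: a fast
#' logistic upstroke followed by a single-exponential decay, repeated with a
#' fixed inter-beat period on top of a constant fluorescence baseline with
#' additive Gaussian noise.
#'
#' The kernel reaches its peak a fixed rise time (`6 * upstroke_time_constant`)
#' after onset and then decays as `exp(-t / decay_time_constant)`. Under this
#' model the calcium transient duration at 90% decay (CTD90), measured from
#' the 10%-of-amplitude upstroke crossing to the 90%-decay crossing, has the
#' closed form returned by [implied_ctd90()].
#'
#' @param baseline_level Resting fluorescence (arbitrary units).
#' @param amplitude Peak height above baseline (a.u.); must be positive.
#' @param upstroke_time_constant Logistic rise time constant (ms). The
#'   upstroke from 10% to peak lasts about `5.25` time constants.
#' @param decay_time_constant Exponential decay time constant (ms); the
#'   decay contributes `log(10) * decay_time_constant` to CTD90.
#' @param period Inter-beat period (ms); `60000 / period` is the beat rate
#'   in beats/min.
#' @param noise_sd Standard deviation of additive Gaussian sample noise (a.u.).
#'
#' @return An object of class `transient_shape`.
#' @seealso [implied_ctd90()], [generate_trace()]
#' @export
#' @examples
#' sh <- transient_shape(period = 1000, decay_time_constant = 200)
#' implied_ctd90(sh)
transient_shape <- function(baseline_level = 100,
                            amplitude = 50,
                            upstroke_time_constant = 8,
                            decay_time_constant = 217,
                            period = 1000,
                            noise_sd = 0.5) {
  if (!is.numeric(amplitude) || amplitude <= 0) {
    ct_stop("`amplitude` must be > 0", "cthazard_invalid_argument")
  }
  if (period <= 0 || decay_time_constant <= 0 || upstroke_time_constant <= 0) {
    ct_stop("`period`, `decay_time_constant` and `upstroke_time_constant` must be > 0",
            "cthazard_invalid_argument")
  }
  if (noise_sd < 0) {
    ct_stop("`noise_sd` must be >= 0", "cthazard_invalid_argument")
  }
  shape <- structure(
    list(
      baseline_level = baseline_level,
      amplitude = amplitude,
      upstroke_time_constant = upstroke_time_constant,
      decay_time_constant = decay_time_constant,
      period = period,
      noise_sd = noise_sd
    ),
    class = "transient_shape"
  )
  if (implied_ctd90(shape) >= period) {
    ct_warn(sprintf(
      "implied CTD90 (%.0f ms) is not shorter than the period (%.0f ms); beats will overlap",
      implied_ctd90(shape), period
    ), "cthazard_shape_overlap")
  }
  shape
}

# Rise geometry of the kernel. The logistic is centred 3 time constants
# before the peak and renormalized so the kernel equals `amplitude` exactly
# at the peak time; the 10%-of-amplitude crossing then sits
# 5.2511 time constants before the peak (closed form, see implied_ctd90).
.rise_centre_tc <- 3
.rise_norm <- stats::plogis(.rise_centre_tc)

.rise10_offset_tc <- function() {
  .rise_centre_tc - log(0.1 * .rise_norm / (1 - 0.1 * .rise_norm))
}

#' Closed-form CTD90 implied by a transient shape
#'
#' Time from the 10%-of-amplitude upstroke crossing to the point where the
#' exponential decay has completed 90% of its excursion:
#' `5.2511 * upstroke_time_constant + log(10) * decay_time_constant` (ms).
#' This is the analytic ground truth that feature extraction is expected to
#' recover on noise-free simulated traces.
#'
#' @param shape A [transient_shape()].
#' @return CTD90 in milliseconds.
#' @export
implied_ctd90 <- function(shape) {
  stopifnot(inherits(shape, "transient_shape"))
  .rise10_offset_tc() * shape$upstroke_time_constant +
    log(10) * shape$decay_time_constant
}

#' @export
print.transient_shape <- function(x, ...) {
  cat(sprintf(
    "<transient_shape> BR %.1f bpm, implied CTD90 %.0f ms, amplitude %.1f a.u., noise sd %.2f\n",
    60000 / x$period, implied_ctd90(x), x$amplitude, x$noise_sd
  ))
  invisible(x)
}

#' Concentration-effect model for a simulated compound
#'
#' Describes how a compound perturbs the three beating parameters and the
#' probabilities of the three abnormal phenotypes as functions of
#' concentration. Parameter effects follow a hyperbolic (Hill slope 1)
#' saturation curve: the fractional change at concentration `C` is
#' `emax * C / (C + ec50)`, so the half-maximal effect occurs at `ec50` and
#' the curves are monotone in concentration. Event probabilities use the
#' same form with a maximum probability `pmax`.
#'
#' @param ctd90_emax,br_emax,amp_emax Maximum fractional change of CTD90,
#'   beat rate and amplitude (e.g. `0.6` = +60%, `-0.5` = -50%).
#' @param ctd90_ec50,br_ec50,amp_ec50 Midpoint concentrations (uM).
#' @param ead_pmax,fibrillation_pmax,arrest_pmax Maximum probabilities (in
#'   `[0, 1]`) of EAD-like events, fibrillation-like activity and beating
#'   arrest at saturating concentration.
#' @param ead_ec50,fibrillation_ec50,arrest_ec50 Midpoint concentrations (uM)
#'   of the event-probability curves.
#'
#' @return An object of class `drug_effect_model`.
#' @export
#' @examples
#' dofetilide_like <- drug_effect_model(ctd90_emax = 0.8, ctd90_ec50 = 0.001,
#'                                      ead_pmax = 0.8, ead_ec50 = 0.003)
drug_effect_model <- function(ctd90_emax = 0, ctd90_ec50 = 1,
                              br_emax = 0, br_ec50 = 1,
                              amp_emax = 0, amp_ec50 = 1,
                              ead_pmax = 0, ead_ec50 = 1,
                              fibrillation_pmax = 0, fibrillation_ec50 = 1,
                              arrest_pmax = 0, arrest_ec50 = 1) {
  for (p in c(ead_pmax, fibrillation_pmax, arrest_pmax)) {
    if (p < 0 || p > 1) {
      ct_stop("event probabilities must lie in [0, 1]", "cthazard_invalid_argument")
    }
  }
  if (any(c(ctd90_ec50, br_ec50, amp_ec50, ead_ec50,
            fibrillation_ec50, arrest_ec50) <= 0)) {
    ct_stop("all `ec50` values must be > 0", "cthazard_invalid_argument")
  }
  structure(
    list(
      ctd90 = list(emax = ctd90_emax, ec50 = ctd90_ec50),
      br = list(emax = br_emax, ec50 = br_ec50),
      amp = list(emax = amp_emax, ec50 = amp_ec50),
      ead = list(pmax = ead_pmax, ec50 = ead_ec50),
      fibrillation = list(pmax = fibrillation_pmax, ec50 = fibrillation_ec50),
      arrest = list(pmax = arrest_pmax, ec50 = arrest_ec50)
    ),
    class = "drug_effect_model"
  )
}

# Hyperbolic saturation curve shared by effects and event probabilities.
saturating_effect <- function(curve, concentration) {
  if (concentration == 0) return(0)
  m <- curve$emax %||% curve$pmax
  m * concentration / (concentration + curve$ec50)
}

#' Perturb a transient shape with a drug-effect model
#'
#' Applies the concentration-effect curves of `model` to `shape` and draws
#' the abnormal-phenotype flags from the seeded random stream. CTD90 changes
#' scale both kernel time constants (so [implied_ctd90()] scales by exactly
#' `1 + effect`), beat-rate changes scale the inverse period and amplitude
#' changes scale the amplitude. At concentration 0 the shape is
#' returned unchanged with all flags `FALSE`. Arrest, fibrillation and EADs
#' are drawn in that order of precedence (an arrested well cannot also
#' fibrillate).
#'
#' @param shape A [transient_shape()].
#' @param model A [drug_effect_model()].
#' @param concentration Concentration in uM; must be non-negative.
#' @param seed Optional integer seed making the event draws reproducible.
#'   When `NULL` the current RNG stream is used.
#' @return A list with elements `shape` (the perturbed [transient_shape()]),
#'   and logical flags `ead`, `fibrillation`, `arrest`.
#' @export
apply_drug_model <- function(shape, model, concentration, seed = NULL) {
  stopifnot(inherits(shape, "transient_shape"), inherits(model, "drug_effect_model"))
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      is.na(concentration) || concentration < 0) {
    ct_stop("`concentration` must be a single non-negative number",
            "cthazard_invalid_argument")
  }
  if (concentration == 0) {
    return(list(shape = shape, ead = FALSE, fibrillation = FALSE, arrest = FALSE))
  }
  if (!is.null(seed)) set.seed(seed)

  f_ctd <- saturating_effect(model$ctd90, concentration)
  f_br <- saturating_effect(model$br, concentration)
  f_amp <- saturating_effect(model$amp, concentration)

  # keep multiplicative factors physical
  clamp <- function(f) max(1 + f, 0.05)
  new_shape <- shape
  # scale both time constants so implied CTD90 scales by exactly (1 + f_ctd)
  new_shape$decay_time_constant <- shape$decay_time_constant * clamp(f_ctd)
  new_shape$upstroke_time_constant <- shape$upstroke_time_constant * clamp(f_ctd)
  new_shape$period <- shape$period / clamp(f_br)
  new_shape$amplitude <- shape$amplitude * clamp(f_amp)

  p_arr <- saturating_effect(model$arrest, concentration)
  p_fib <- saturating_effect(model$fibrillation, concentration)
  p_ead <- saturating_effect(model$ead, concentration)
  arrest <- stats::runif(1) < p_arr
  fibrillation <- !arrest && stats::runif(1) < p_fib
  ead <- !arrest && !fibrillation && stats::runif(1) < p_ead

  list(shape = new_shape, ead = ead, fibrillation = fibrillation, arrest = arrest)
}
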