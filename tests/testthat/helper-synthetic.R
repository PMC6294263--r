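# Shared fixture builders. Everything is generated in code at test time.

# noise-free shape with a near-instant upstroke, for closed-form checks
clean_shape <- function(period = 1000, decay_time_constant = 200,
                        upstroke_time_constant = 1, amplitude = 50,
                        noise_sd = 0) {
  transient_shape(
    baseline_level = 100, amplitude = amplitude,
    upstroke_time_constant = upstroke_time_constant,
    decay_time_constant = decay_time_constant,
    period = period, noise_sd = noise_sd
  )
}

# closed-form achieved confidence of the (min, max) interval: the coverage
# follows Beta(n - 1, 2) whose CDF is n p^(n-1) - (n-1) p^n; independent of
# the pbeta-based implementation
conf_oracle <- function(n, p) 1 - (n * p^(n - 1) - (n - 1) * p^n)

# a hand-written parameter spec matching the documented zone semantics
spec_pm10_30 <- function(points = list(mild = 1, strong = 3)) {
  list(
    increase = list(no_effect = 10, mild = 30, strong = 50, points = points),
    decrease = list(no_effect = -10, mild = -30, strong = -50, points = points)
  )
}

# minimal study-effect row for scoring tests
study_row <- function(dd_ctd90 = 0, dd_br = 0, dd_amp = 0,
                      beat_stop_incidence = 0, ead_incidence = 0,
                      fibrillation_incidence = 0,
                      compound = "x", concentration_uM = 1) {
  data.frame(
    compound = compound, concentration_uM = concentration_uM, role = "test",
    n_wells = 8L, d_ctd90 = dd_ctd90, d_br = dd_br, d_amp = dd_amp,
    beat_stop_incidence = beat_stop_incidence, ead_incidence = ead_incidence,
    fibrillation_incidence = fibrillation_incidence,
    dd_ctd90 = dd_ctd90, dd_br = dd_br, dd_amp = dd_amp,
    all_stopped = beat_stop_incidence == 1,
    stringsAsFactors = FALSE
  )
}

# minimal well-effect rows for QC tests
well_rows <- function(n, baseline_br = 60, reason = "", role = "vehicle",
                      compound = "vehicle", concentration_uM = 0) {
  data.frame(
    compound = compound, concentration_uM = concentration_uM, role = role,
    well = sprintf("W%03d", seq_len(n)),
    baseline_br = baseline_br, baseline_ctd90 = 500, baseline_amp = 50,
    n_beats_baseline = ifelse(reason == "no_beating", 0L, 60L),
    d_ctd90 = 0, d_br = 0, d_amp = 0,
    beat_stop = FALSE, ead = FALSE, fibrillation = FALSE,
    qc_status = ifelse(reason == "", "included", "excluded"),
    qc_reason = reason,
    stringsAsFactors = FALSE
  )
}
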