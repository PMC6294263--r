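fs <- 66.7
dt_ms <- 1000 / fs

# triangular bump used for injected-spike fixtures
add_bump <- function(x, at_s, height, half_width_s = 0.05) {
  t <- (seq_along(x) - 1) / fs
  w <- abs(t - at_s) <= half_width_s
  x[w] <- x[w] + height * (1 - abs(t[w] - at_s) / half_width_s)
  x
}

test_that("a flat trace contains no beats and malformed traces error", {
  set.seed(1)
  flat <- trace_recording(100 + rnorm(4500, sd = 0.5), fs)
  expect_equal(nrow(detect_beats(flat)), 0)

  expect_error(detect_beats(trace_recording(c(rep(1, 800), NA), fs)),
               class = "cthazard_input_error")
  expect_error(detect_beats(trace_recording(rnorm(100), fs)),
               class = "cthazard_input_error")   # < 10 s
})

test_that("a noise-free train is recovered beat for beat", {
  tr <- generate_trace(clean_shape(period = 1000), 60, fs, seed = 3)
  b <- detect_beats(tr)
  truth <- attr(tr, "true_peak_times")
  expect_equal(nrow(b), length(truth))
  expect_true(all(abs(b$peak_time - truth) <= 1 / fs + 1e-9))
})

test_that("an idealized linear decay yields a 900 ms transient duration", {
  # instant rise to 1, linear decay to baseline over 1000 ms, 2 s period
  t <- (0:(80 * fs)) / fs
  x <- numeric(length(t))
  on <- t >= 10
  d <- (t[on] - 10) %% 2
  x[on] <- pmax(0, 1 - d)
  tr <- trace_recording(x, fs)
  b <- detect_beats(tr)
  expect_gt(nrow(b), 20)
  expect_true(all(abs(b$ctd90 - 900) <= dt_ms, na.rm = TRUE))
})

test_that("an exponential decay recovers the closed-form CTD90", {
  sh <- clean_shape(period = 2000, decay_time_constant = 200,
                    upstroke_time_constant = 1)
  tr <- generate_trace(sh, 75, fs, seed = 2)
  b <- detect_beats(tr)
  expect_lt(abs(median(b$ctd90, na.rm = TRUE) - 200 * log(10)), 1.5 * dt_ms)
})

test_that("a beat whose decay is cut short by the next upstroke is excluded", {
  # sawtooth rising again at 85% decay: the first transient after the flat
  # lead-in never reaches its 90% level and must be NA
  t <- (0:(80 * fs)) / fs
  x <- numeric(length(t))
  on <- t >= 10
  x[on] <- 1 - ((t[on] - 10) %% 0.85)
  tr <- trace_recording(x, fs)
  b <- detect_beats(tr)
  expect_gt(nrow(b), 10)
  expect_true(is.na(b$ctd90[1]))
  expect_true(all(!is.na(b$ctd90[-1])))
  expect_false(is.na(median(b$ctd90, na.rm = TRUE)))
})

test_that("decay-phase spikes are counted as EADs, not as extra beats", {
  tr <- generate_trace(clean_shape(period = 1000, decay_time_constant = 217,
                                   amplitude = 50), 75, fs, seed = 5)
  x <- tr$samples
  hosts <- attr(tr, "true_peak_times")[c(20, 35, 50)]
  for (h in hosts) x <- add_bump(x, h + 0.25, 0.4 * 50)
  spiked <- trace_recording(x, fs)

  b0 <- detect_beats(tr)
  b1 <- detect_beats(spiked)
  expect_equal(nrow(b1), nrow(b0))               # no double counting

  e <- detect_eads(spiked, b1)
  expect_true(e$flag)
  expect_equal(e$count, 3L)

  expect_identical(detect_eads(tr, b0), list(flag = FALSE, count = 0L))
})

test_that("a sub-threshold bump is not an EAD", {
  tr <- generate_trace(clean_shape(period = 1000, amplitude = 50), 75, fs, seed = 6)
  x <- add_bump(tr$samples, attr(tr, "true_peak_times")[30] + 0.25, 0.05 * 50)
  spiked <- trace_recording(x, fs)
  b <- detect_beats(spiked)
  expect_identical(detect_eads(spiked, b), list(flag = FALSE, count = 0L))
})

test_that("fibrillation-like segments are recognized against the well's baseline", {
  sh <- transient_shape()
  base_s <- summarize_phase(generate_trace(sh, 75, fs, seed = 11))
  fib <- generate_trace(sh, 75, fs, seed = 12, fibrillation = TRUE,
                        fib_duration_s = 30, fib_rate_factor = 3.5,
                        fib_amp_factor = 0.2)
  normal <- generate_trace(sh, 75, fs, seed = 13)
  flat <- trace_recording(rep(100, 5000) + rnorm(5000, sd = 0.5), fs)

  expect_true(detect_fibrillation(fib, base_s))
  expect_false(detect_fibrillation(normal, base_s))
  expect_false(detect_fibrillation(flat, base_s))   # arrest, not fibrillation
  expect_error(detect_fibrillation(fib, NULL), class = "cthazard_input_error")
})

test_that("beat stop uses a strict 5 beats/min threshold at 30 minutes", {
  baseline <- generate_trace(transient_shape(noise_sd = 0), 75, fs, seed = 1)
  mk_slow <- function(period_ms) {
    generate_trace(clean_shape(period = period_ms, decay_time_constant = 150),
                   75, fs, start_offset_s = 1)
  }
  four <- mk_slow(15000)   # 4 transients in the 1-min window
  five <- mk_slow(12000)   # exactly 5

  ws4 <- summarize_well(list(baseline = baseline, post30 = four))
  ws5 <- summarize_well(list(baseline = baseline, post30 = five))
  expect_equal(ws4$phases[ws4$phases$phase == "post30", "beat_rate"], 4)
  expect_equal(ws5$phases[ws5$phases$phase == "post30", "beat_rate"], 5)
  expect_true(ws4$beat_stop)
  expect_false(ws5$beat_stop)   # strict inequality
})

test_that("a well silent at 15 min but beating at 30 min is not a beat stop", {
  baseline <- generate_trace(transient_shape(noise_sd = 0), 75, fs, seed = 2)
  silent <- trace_recording(rep(100, floor(75 * fs)), fs)
  beating <- generate_trace(transient_shape(noise_sd = 0), 75, fs, seed = 3)
  ws <- summarize_well(list(baseline = baseline, post15 = silent,
                            post30 = beating))
  expect_false(ws$beat_stop)
})

test_that("a missing required phase is reported by name", {
  baseline <- generate_trace(transient_shape(noise_sd = 0), 75, fs, seed = 2)
  err <- tryCatch(summarize_well(list(baseline = baseline)), error = identity)
  expect_s3_class(err, "cthazard_input_error")
  expect_match(conditionMessage(err), "post30")
})

test_that("parameter medians are invariant to beat order and robust to one outlier", {
  set.seed(8)
  vals <- rnorm(9, 500, 20)
  expect_equal(median(vals), median(sample(vals)))
  with_outlier <- c(vals[1:8], 5000)
  expect_lt(abs(median(with_outlier) - median(vals)), 30)
})
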