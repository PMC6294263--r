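test_that("percent change follows the baseline-normalized formula", {
  expect_equal(delta_percent(600, 500), 20)
  expect_equal(delta_percent(500, 500), 0)
  expect_equal(delta_percent(0, 500), -100)
  expect_error(delta_percent(10, 0), class = "cthazard_undefined_effect")
  expect_error(delta_percent(10, -5), class = "cthazard_undefined_effect")
})

test_that("net effects are the simple difference against the plate vehicle", {
  expect_equal(delta_delta(18, 2), 16)
  expect_equal(delta_delta(-30, 2), -32)
  for (x in c(-12, 0, 7.3)) expect_equal(delta_delta(x, x), 0)
  expect_error(delta_delta(10, NA_real_), class = "cthazard_normalization_error")
  # self-cancellation through the composed formulas
  a <- 612; b <- 480
  expect_equal(delta_delta(delta_percent(a, b), delta_percent(a, b)), 0)
})

test_that("baseline well QC applies the beating and 30-90 bpm rules", {
  df <- data.frame(
    well = sprintf("A%02d", 1:6),
    beat_rate = c(29, 30, 60, 90, 91, 0),
    n_beats = c(29, 30, 60, 90, 91, 0)
  )
  qc <- apply_well_qc(df, non_synchronous = "A03")
  expect_equal(qc$qc_status,
               c("excluded", "included", "excluded", "included", "excluded",
                 "excluded"))
  expect_equal(qc$qc_reason[c(1, 5, 6, 3)],
               c("br_out_of_range", "br_out_of_range", "no_beating",
                 "non_synchronous"))
})

test_that("treatment aggregation takes medians over beating wells and incidences over included wells", {
  w <- well_rows(4, role = "test", compound = "d", concentration_uM = 1)
  w$d_ctd90 <- c(10, 12, 14, 100)
  agg <- aggregate_treatment(w)
  expect_equal(agg$d_ctd90, 13)

  w8 <- well_rows(8, role = "test", compound = "d", concentration_uM = 1)
  w8$beat_stop <- rep(c(TRUE, FALSE), each = 4)
  w8$d_ctd90 <- NA_real_
  w8$d_ctd90[!w8$beat_stop] <- c(8, 10, 12, 20)
  agg8 <- aggregate_treatment(w8)
  expect_equal(agg8$beat_stop_incidence, 0.5)
  expect_equal(agg8$d_ctd90, 11)   # median over the 4 beating wells

  expect_warning(aggregate_treatment(well_rows(3)),
                 class = "cthazard_n_wells_warning")
  none <- well_rows(2, reason = "no_beating")
  expect_error(aggregate_treatment(none), class = "cthazard_aggregation_error")
})

test_that("aggregation is permutation invariant in wells", {
  set.seed(21)
  w <- well_rows(8, role = "test", compound = "d", concentration_uM = 1)
  w$d_ctd90 <- rnorm(8, 10, 4); w$d_br <- rnorm(8); w$d_amp <- rnorm(8)
  w$beat_stop <- c(TRUE, rep(FALSE, 7))
  a <- aggregate_treatment(w)
  b <- aggregate_treatment(w[sample(8), ])
  expect_equal(a, b)
})

test_that("the plate-wide beat-rate rule excludes plates above 10% offending wells", {
  ok <- well_rows(86)
  bad10 <- well_rows(10, baseline_br = 20, reason = "br_out_of_range")
  bad10$well <- sprintf("X%03d", 1:10)
  plate10 <- rbind(ok, bad10)                     # 10/96 = 10.4%
  qc10 <- apply_plate_qc(plate10, empty_study_effects())
  expect_false(qc10$plate_pass)
  expect_match(qc10$plate_fail_reasons[1], "br_criteria_exceeded")

  bad9 <- bad10[1:9, ]
  plate9 <- rbind(ok, well_rows(1), bad9)         # 9/96 = 9.4%
  plate9$well <- sprintf("Y%03d", seq_len(nrow(plate9)))
  expect_true(apply_plate_qc(plate9, empty_study_effects())$plate_pass)
})

test_that("positive-control sensitivity criteria gate the plate at their printed boundaries", {
  wells <- rbind(well_rows(90),
                 well_rows(6, role = "positive_control", compound = "dofetilide",
                           concentration_uM = 0.003))
  wells$well <- sprintf("Z%03d", seq_len(nrow(wells)))
  mk_se <- function(dof = 40, iso = NULL, nim = NULL) {
    rows <- list(cbind(study_row(dd_ctd90 = dof, compound = "dofetilide",
                                 concentration_uM = 0.003)))
    if (!is.null(iso)) rows <- c(rows, list(study_row(dd_br = iso, compound = "isoprenaline")))
    if (!is.null(nim)) rows <- c(rows, list(study_row(dd_ctd90 = nim, compound = "nimodipine")))
    se <- do.call(rbind, rows)
    se$role <- "positive_control"
    se
  }
  fail <- apply_plate_qc(wells, mk_se(dof = 14))
  expect_false(fail$plate_pass)
  expect_true("dofetilide_insensitive" %in% fail$plate_fail_reasons)
  expect_true(apply_plate_qc(wells, mk_se(dof = 15))$plate_pass)    # boundary: "<15" fails

  expect_false(apply_plate_qc(wells, mk_se(iso = 29.9))$plate_pass)
  expect_true(apply_plate_qc(wells, mk_se(iso = 30))$plate_pass)
  expect_false(apply_plate_qc(wells, mk_se(nim = -9.9))$plate_pass)
  expect_true(apply_plate_qc(wells, mk_se(nim = -10))$plate_pass)
})

test_that("study effects correct every treatment by the plate's vehicle median", {
  veh <- well_rows(8)
  veh$d_ctd90 <- rep(2, 8); veh$d_br <- rep(-1, 8); veh$d_amp <- rep(0.5, 8)
  drug <- well_rows(8, role = "test", compound = "d", concentration_uM = 1)
  drug$well <- sprintf("D%03d", 1:8)
  drug$d_ctd90 <- rep(18, 8); drug$d_br <- rep(3, 8); drug$d_amp <- rep(0.5, 8)
  se <- compute_study_effects(rbind(veh, drug))
  expect_equal(se$dd_ctd90, 16)
  expect_equal(se$dd_br, 4)
  expect_equal(se$dd_amp, 0)

  no_veh <- drug
  expect_error(compute_study_effects(no_veh),
               class = "cthazard_normalization_error")
})

test_that("a fully arrested treatment keeps incidences but no parameter effects", {
  veh <- well_rows(8)
  drug <- well_rows(6, role = "test", compound = "d", concentration_uM = 5)
  drug$well <- sprintf("D%03d", 1:6)
  drug$beat_stop <- TRUE
  drug$d_ctd90 <- drug$d_br <- drug$d_amp <- NA_real_
  se <- suppressWarnings(compute_study_effects(rbind(veh, drug)))
  expect_equal(se$beat_stop_incidence, 1)
  expect_true(se$all_stopped)
  expect_true(is.na(se$dd_ctd90))
})
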