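test_that("parameter zones score by size and direction with boundaries to the milder zone", {
  spec <- spec_pm10_30()
  expect_equal(score_parameter(0, spec)$points, 0L)
  expect_equal(score_parameter(0, spec)$zone, "no_effect")
  expect_equal(score_parameter(20, spec)$points, 1L)
  expect_equal(score_parameter(30, spec)$points, 1L)    # boundary -> milder
  expect_equal(score_parameter(30.01, spec)$points, 3L)
  expect_equal(score_parameter(10, spec)$points, 0L)    # boundary -> milder
  expect_equal(score_parameter(-20, spec)$points, 1L)
  expect_equal(score_parameter(-31, spec)$points, 3L)
  na <- score_parameter(NA_real_, spec)
  expect_equal(na$zone, "not_evaluable")
  expect_equal(na$points, 0L)
})

test_that("beat-stop incidence is scored in three zones and fibrillation adds points", {
  m <- default_scoring_matrix()
  expect_equal(score_incidence(0, 0, m)$points, 0L)
  expect_equal(score_incidence(0.5, 0, m)$beat_stop_points, 1L)   # phenytoin-like
  expect_equal(score_incidence(0.51, 0, m)$beat_stop_points, 2L)
  expect_equal(score_incidence(0.99, 0, m)$beat_stop_points, 2L)
  expect_equal(score_incidence(1, 0, m)$beat_stop_points, 4L)
  expect_equal(score_incidence(0, 0.125, m)$fibrillation_points, 4L)
  expect_error(score_incidence(1.2, 0, m), class = "cthazard_invalid_argument")
})

test_that("full beat stop alone reaches the high label", {
  m <- default_scoring_matrix()
  r <- score_study(study_row(dd_ctd90 = NA, dd_br = NA, dd_amp = NA,
                             beat_stop_incidence = 1), m)
  expect_equal(r$label, "high")
  expect_false(r$override_applied)
})

test_that("a null study scores zero and any EAD forces very high hazard", {
  m <- default_scoring_matrix()
  null <- score_study(study_row(), m)
  expect_equal(null$total_score, 0L)
  expect_equal(null$label, "no")
  expect_equal(null$color, "green")

  ead <- score_study(study_row(ead_incidence = 0.125), m)
  expect_equal(ead$label, "very_high")
  expect_equal(ead$color, "black")
  expect_true(ead$override_applied)
})

test_that("the default matrix sums strong CTD90 and mild BR effects to a high label", {
  m <- default_scoring_matrix()
  dd_ctd <- m$parameters$ctd90$increase$mild + 10     # strong prolongation
  dd_br <- m$parameters$br$decrease$no_effect - 3     # mild decrease
  r <- score_study(study_row(dd_ctd90 = dd_ctd, dd_br = dd_br), m)
  expect_equal(r$total_score, 3L + 1L)                # hand summation
  expect_equal(sum(r$breakdown$points), r$total_score)
  expect_equal(r$label, "high")
})

test_that("scoring a QC-failed plate is refused", {
  m <- default_scoring_matrix()
  qc_fail <- structure(list(plate_pass = FALSE,
                            plate_fail_reasons = "dofetilide_insensitive",
                            well_exclusions = data.frame(), br_out_fraction = 0),
                       class = "plate_qc_report")
  expect_error(score_study(study_row(), m, qc = qc_fail),
               class = "cthazard_qc_refusal")
})

test_that("scores are monotone in effect magnitude and labels are monotone in score", {
  m <- default_scoring_matrix()
  for (p in c("ctd90", "br", "amp")) {
    for (sign in c(1, -1)) {
      dd <- sign * seq(0, 120, by = 1.5)
      pts <- vapply(dd, function(v) score_parameter(v, m$parameters[[p]])$points,
                    integer(1))
      expect_true(all(diff(pts) >= 0))
    }
  }
  labels <- vapply(0:12, function(s) cthazard:::label_from_score(s, m$label_ranges),
                   character(1))
  sev <- match(labels, c("no", "low", "high"))
  expect_true(all(diff(sev) >= 0))
})

test_that("very high hazard is reached exactly when EADs occur", {
  m <- default_scoring_matrix()
  grid <- expand.grid(dd = c(-90, -25, 0, 25, 90),
                      bs = c(0, 0.5, 1),
                      ead = c(0, 0.125, 1),
                      fib = c(0, 0.25))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    r <- score_study(study_row(dd_ctd90 = if (g$bs == 1) NA else g$dd,
                               beat_stop_incidence = g$bs,
                               ead_incidence = g$ead,
                               fibrillation_incidence = g$fib), m)
    expect_identical(r$label == "very_high", g$ead > 0)
  }
})

test_that("compounds rank by worst label, then by the concentration reaching it", {
  tab <- data.frame(
    compound = c("b", "b", "a", "a", "c", "c"),
    concentration_uM = c(0.1, 1, 0.1, 1, 0.1, 1),
    total_score = c(3L, 3L, 0L, 0L, 0L, 0L),
    label = c("high", "high", "no", "very_high", "no", "high"),
    color = "x", override_applied = FALSE, stringsAsFactors = FALSE
  )
  ranked <- rank_compounds(tab)
  expect_equal(unique(ranked$compound), c("a", "b", "c"))   # very_high@1 beats high@0.1
  expect_equal(ranked$concentration_uM[ranked$compound == "a"], c(0.1, 1))

  tie <- tab[tab$compound %in% c("b", "c"), ]
  tie$label <- "low"
  expect_equal(unique(rank_compounds(tie)$compound), c("b", "c"))   # lexicographic

  dup <- tab[c(1, 1), ]
  expect_error(rank_compounds(dup), class = "cthazard_input_error")
})

test_that("single-compound tables keep ascending-concentration label order", {
  tab <- data.frame(
    compound = "z", concentration_uM = c(1, 0.1, 0.3, 3),
    total_score = c(1L, 0L, 0L, 3L),
    label = c("low", "no", "no", "high"),
    color = "x", override_applied = FALSE, stringsAsFactors = FALSE
  )
  ranked <- rank_compounds(tab)
  expect_equal(ranked$label, c("no", "no", "low", "high"))
})

test_that("the scoring matrix round-trips losslessly through its config file", {
  m <- default_scoring_matrix()
  path <- tempfile(fileext = ".yaml")
  write_scoring_matrix(m, path)
  m2 <- read_scoring_matrix(path)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12)

  # a corrupted matrix fails validation
  bad <- m
  bad$label_ranges$low <- c(2, 2)   # gap at score 1
  expect_error(validate_scoring_matrix(bad), class = "cthazard_config_error")
  bad2 <- m
  bad2$parameters$ctd90$increase$points$strong <- 0   # below mild
  expect_error(validate_scoring_matrix(bad2), class = "cthazard_config_error")
})
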