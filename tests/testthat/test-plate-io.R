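small_plate <- function(seed = 31) {
  layout <- plate_layout(c("A01", "A02"), c("vehicle", "vehicle"), c(0, 0),
                         c("vehicle", "vehicle"))
  generate_plate(layout, seed = seed, duration_s = 60)
}

test_that("write and read are inverse on the plate format", {
  plate <- small_plate()
  dir <- file.path(tempdir(), "plate_rt")
  write_plate(plate, dir)
  back <- read_plate(dir)
  expect_equal(back$layout, plate$layout)
  expect_equal(back$sampling_rate, plate$sampling_rate)
  for (w in plate$layout$well) {
    for (ph in c("baseline", "post15", "post30")) {
      expect_equal(back$recordings[[w]][[ph]]$samples,
                   plate$recordings[[w]][[ph]]$samples, tolerance = 1e-12)
    }
  }
  unlink(dir, recursive = TRUE)
})

test_that("a well missing from one phase is reported by name", {
  plate <- small_plate(32)
  dir <- file.path(tempdir(), "plate_missing")
  write_plate(plate, dir)
  df <- read.csv(file.path(dir, "post30.csv"), check.names = FALSE)
  df$A02 <- NULL
  write.csv(df, file.path(dir, "post30.csv"), row.names = FALSE)
  err <- tryCatch(read_plate(dir), error = identity)
  expect_s3_class(err, "cthazard_format_error")
  expect_match(conditionMessage(err), "A02")
  unlink(dir, recursive = TRUE)
})

test_that("a non-finite sample is a parse error with coordinates", {
  plate <- small_plate(33)
  dir <- file.path(tempdir(), "plate_nan")
  write_plate(plate, dir)
  df <- read.csv(file.path(dir, "baseline.csv"), check.names = FALSE)
  df$A01[17] <- NaN
  write.csv(df, file.path(dir, "baseline.csv"), row.names = FALSE)
  err <- tryCatch(read_plate(dir), error = identity)
  expect_s3_class(err, "cthazard_parse_error")
  expect_match(conditionMessage(err), "row 17")
  expect_match(conditionMessage(err), "A01")
  unlink(dir, recursive = TRUE)
})

pipeline_layout <- function(test_compound) {
  wells <- well_ids()[1:16]
  plate_layout(
    wells,
    c(rep("vehicle", 8), rep("dofetilide", 4), rep(test_compound, 4)),
    c(rep(0, 8), rep(0.003, 4), rep(0.1, 4)),
    c(rep("vehicle", 8), rep("positive_control", 4), rep("test", 4))
  )
}

test_that("an all-vehicle plate yields no hazard rows and passes QC", {
  layout <- plate_layout(well_ids()[1:12], rep("vehicle", 12), rep(0, 12),
                         rep("vehicle", 12))
  plate <- generate_plate(layout, seed = 41, include_post15 = FALSE)
  res <- run_pipeline(plate)
  expect_true(res$qc$plate_pass)
  expect_equal(nrow(res$hazard), 0)
  expect_equal(nrow(res$study_effects), 0)
})

test_that("a responsive plate passes control QC and scores its test compound", {
  models <- control_effect_models()
  models$drugX <- drug_effect_model(ctd90_emax = 0.8, ctd90_ec50 = 0.01)
  plate <- generate_plate(pipeline_layout("drugX"), models, seed = 42,
                          include_post15 = FALSE)
  res <- suppressWarnings(run_pipeline(plate))
  expect_true(res$qc$plate_pass)
  expect_equal(res$hazard$compound, "drugX")
  expect_true(res$hazard$label %in% c("low", "high", "very_high"))
  # determinism end to end
  res2 <- suppressWarnings(run_pipeline(generate_plate(pipeline_layout("drugX"),
                                                       models, seed = 42,
                                                       include_post15 = FALSE)))
  expect_identical(res$hazard$total_score, res2$hazard$total_score)
  expect_identical(res$study_effects$dd_ctd90, res2$study_effects$dd_ctd90)
})

test_that("a dofetilide-insensitive plate is excluded and never scored", {
  models <- control_effect_models()
  models$dofetilide <- drug_effect_model()   # unresponsive hERG control
  models$drugX <- drug_effect_model(ctd90_emax = 0.8, ctd90_ec50 = 0.01)
  plate <- generate_plate(pipeline_layout("drugX"), models, seed = 43,
                          include_post15 = FALSE)
  res <- suppressWarnings(run_pipeline(plate))
  expect_false(res$qc$plate_pass)
  expect_true("dofetilide_insensitive" %in% res$qc$plate_fail_reasons)
  expect_equal(nrow(res$hazard), 0)
})

test_that("simulated plates are valid scoring input after a disk round trip", {
  models <- control_effect_models()
  models$drugX <- drug_effect_model(ctd90_emax = 0.8, ctd90_ec50 = 0.01)
  plate <- generate_plate(pipeline_layout("drugX"), models, seed = 44)
  dir <- file.path(tempdir(), "plate_e2e")
  write_plate(plate, dir)
  res <- suppressWarnings(run_pipeline(config = run_config(plate_dir = dir)))
  expect_true(res$scored)
  expect_equal(res$hazard$compound, "drugX")

  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  export_hazard(res$hazard, csv, json)
  expect_equal(read.csv(csv)$compound, "drugX")
  expect_equal(jsonlite::read_json(json)[[1]]$label, res$hazard$label[1])
  unlink(dir, recursive = TRUE)
})
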