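#' Run configuration for the end-to-end pipeline
#'
#' @param plate_dir Directory with the plate files ([read_plate()] format);
#'   alternatively pass an in-memory `plate_dataset` directly to
#'   [run_pipeline()].
#' @param matrix_path Optional scoring-matrix YAML; default the packaged
#'   matrix.
#' @param feature_config A [feature_config()].
#' @param br_bounds Baseline beat-rate acceptance bounds.
#' @param control_criteria Positive-control plate criteria.
#' @param max_out_frac Plate-level limit on the fraction of wells outside
#'   the beat-rate criteria.
#' @param expected_n Included wells per treatment before a warning.
#' @return A list of class `run_config`.
#' @export
run_config <- function(plate_dir = NULL, matrix_path = NULL,
                       feature_config = cthazard::feature_config(),
                       br_bounds = c(30, 90),
                       control_criteria = default_control_criteria(),
                       max_out_frac = 0.10,
                       expected_n = c(4, 8)) {
  if (!is.null(plate_dir) && !dir.exists(plate_dir)) {
    ct_stop(paste0("plate directory does not exist: ", plate_dir),
            "cthazard_config_error")
  }
  if (!is.null(matrix_path) && !file.exists(matrix_path)) {
    ct_stop(paste0("scoring-matrix config does not exist: ", matrix_path),
            "cthazard_config_error")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full hazard-scoring pipeline on one plate
#'
#' Feature extraction, well QC, effect normalization, plate QC and hazard
#' scoring, in that order. A plate that fails QC yields the QC report with
#' an empty hazard table (excluded plates are never scored). The pipeline
#' is deterministic: identical inputs and configuration give identical
#' outputs.
#'
#' @param plate A `plate_dataset`, or `NULL` to read it from
#'   `config$plate_dir`.
#' @param config A [run_config()].
#' @param matrix A `scoring_matrix`; default from `config$matrix_path` or
#'   the packaged matrix.
#' @return A list of class `pipeline_result`: `well_effects`,
#'   `study_effects`, `qc` (a `plate_qc_report`), `hazard` (a
#'   `hazard_table`, empty when QC failed) and `scored` (logical).
#' @export
run_pipeline <- function(plate = NULL, config = run_config(), matrix = NULL) {
  if (is.null(plate)) {
    if (is.null(config$plate_dir)) {
      ct_stop("either `plate` or `config$plate_dir` is required",
              "cthazard_config_error")
    }
    plate <- read_plate(config$plate_dir)
  }
  if (is.null(matrix)) {
    matrix <- if (!is.null(config$matrix_path)) {
      read_scoring_matrix(config$matrix_path)
    } else {
      default_scoring_matrix()
    }
  }

  well_effects <- compute_well_effects(plate, config$feature_config,
                                       config$br_bounds)
  study_effects <- withCallingHandlers(
    compute_study_effects(well_effects, config$expected_n),
    cthazard_n_wells_warning = function(w) invokeRestart("muffleWarning")
  )
  qc <- apply_plate_qc(well_effects, study_effects,
                       config$control_criteria, config$max_out_frac)

  test_effects <- study_effects[study_effects$role == "test", , drop = FALSE]
  hazard <- if (qc$plate_pass && nrow(test_effects) > 0) {
    score_studies(test_effects, matrix, qc)
  } else {
    score_studies(empty_study_effects(), matrix)
  }

  structure(
    list(
      well_effects = well_effects,
      study_effects = study_effects,
      qc = qc,
      hazard = hazard,
      scored = qc$plate_pass
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$qc)
  if (x$scored && nrow(x$hazard) > 0) {
    cat("hazard table:\n")
    print(x$hazard)
  } else if (!x$scored) {
    cat("plate failed QC; no studies scored\n")
  }
  invisible(x)
}

#' Export a hazard table
#'
#' Writes the compound-concentration label table as CSV and, when
#' `json_path` is given, the full per-parameter breakdowns as JSON.
#'
#' @param hazard A `hazard_table`.
#' @param csv_path Output CSV path.
#' @param json_path Optional JSON path for the full breakdowns.
#' @return `csv_path`, invisibly.
#' @export
export_hazard <- function(hazard, csv_path, json_path = NULL) {
  df <- as.data.frame(hazard)
  attr(df, "results") <- NULL
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    results <- attr(hazard, "results") %||% list()
    payload <- lapply(results, function(r) {
      list(
        compound = r$compound, concentration_uM = r$concentration_uM,
        total_score = r$total_score, label = r$label, color = r$color,
        override_applied = r$override_applied,
        breakdown = r$breakdown
      )
    })
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(csv_path)
}
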