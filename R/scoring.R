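hazard_levels <- c("no", "low", "high", "very_high")
hazard_colors <- c(no = "green", low = "yellow", high = "red",
                   very_high = "black")

#' Score one parameter's net effect
#'
#' Locates the zone containing a net percent effect and returns its
#' weighted points. Zone boundaries belong to the milder zone, so an effect
#' exactly at a cutoff earns the milder zone's points; zero is always in
#' the no-effect zone. When the relevant direction has no defined
#' mild/strong boundary (no control was available at derivation), any
#' effect beyond the no-effect bound scores the mild points.
#'
#' @param dd Net percent effect (finite), or `NA` if not evaluable (e.g.
#'   all wells stopped beating).
#' @param param_spec One parameter entry of a `scoring_matrix`
#'   (`matrix$parameters$ctd90` etc.).
#' @return A list with `points`, `zone` (`"no_effect"`, `"mild"`,
#'   `"strong"`, or `"not_evaluable"`) and `direction`.
#' @export
score_parameter <- function(dd, param_spec) {
  if (is.na(dd)) {
    return(list(points = 0L, zone = "not_evaluable", direction = NA_character_))
  }
  if (!is.finite(dd)) {
    ct_stop("net effect must be finite", "cthazard_invalid_argument")
  }
  dir <- if (dd >= 0) "increase" else "decrease"
  z <- param_spec[[dir]]
  mag <- abs(dd)
  if (mag <= abs(z$no_effect)) {
    return(list(points = 0L, zone = "no_effect", direction = dir))
  }
  if (is.na(z$mild) || mag <= abs(z$mild)) {
    return(list(points = as.integer(z$points$mild), zone = "mild", direction = dir))
  }
  list(points = as.integer(z$points$strong), zone = "strong", direction = dir)
}

#' Score the beat-stop and fibrillation incidences
#'
#' Beat-stop incidence is scored in three zones: up to `low$upper`
#' (default 50%) of included wells earns the low points, more than that but
#' short of all wells the mid points, and exactly 100% the full points; an
#' incidence of zero earns nothing. Any fibrillation incidence adds the
#' fibrillation points.
#'
#' @param beat_stop_incidence,fibrillation_incidence Fractions in `[0, 1]`.
#' @param matrix A `scoring_matrix`.
#' @return A list with `beat_stop_points`, `fibrillation_points`, `points`
#'   (their sum) and `beat_stop_zone`.
#' @export
score_incidence <- function(beat_stop_incidence, fibrillation_incidence, matrix) {
  for (v in c(beat_stop_incidence, fibrillation_incidence)) {
    if (is.na(v) || v < 0 || v > 1) {
      ct_stop("incidences must lie in [0, 1]", "cthazard_invalid_argument")
    }
  }
  bz <- matrix$beat_stop_zones
  if (beat_stop_incidence == 0) {
    bs <- 0L; zone <- "none"
  } else if (beat_stop_incidence <= bz$low$upper) {
    bs <- as.integer(bz$low$points); zone <- "low"
  } else if (beat_stop_incidence < 1) {
    bs <- as.integer(bz$mid$points); zone <- "mid"
  } else {
    bs <- as.integer(bz$full$points); zone <- "full"
  }
  fp <- if (fibrillation_incidence > 0) as.integer(matrix$fibrillation_points) else 0L
  list(beat_stop_points = bs, fibrillation_points = fp, points = bs + fp,
       beat_stop_zone = zone)
}

label_from_score <- function(total, label_ranges) {
  for (lab in c("no", "low", "high")) {
    r <- label_ranges[[lab]]
    if (total >= r[1] && total <= r[2]) return(lab)
  }
  "high"
}

#' Score one compound-concentration study
#'
#' Sums the weighted points of the three parameter effects and the
#' incidence points, maps the total through the label ranges, and applies
#' the EAD override: any EAD incidence makes the study very high hazard
#' regardless of the score. Scoring a study from a QC-failed plate is
#' refused.
#'
#' @param effect One row of [compute_study_effects()] output.
#' @param matrix A `scoring_matrix`.
#' @param qc Optional `plate_qc_report` for the plate; if given and failed,
#'   scoring errors.
#' @return An object of class `hazard_result`: `compound`,
#'   `concentration_uM`, `total_score`, `label`, `color`,
#'   `override_applied`, `breakdown` (per-parameter data frame).
#' @export
score_study <- function(effect, matrix, qc = NULL) {
  if (!is.null(qc) && !qc$plate_pass) {
    ct_stop("refusing to score a study from a QC-failed plate",
            "cthazard_qc_refusal")
  }
  validate_scoring_matrix(matrix)

  pars <- c(ctd90 = "dd_ctd90", br = "dd_br", amp = "dd_amp")
  rows <- lapply(names(pars), function(p) {
    dd <- effect[[pars[[p]]]]
    sc <- score_parameter(dd, matrix$parameters[[p]])
    data.frame(parameter = p, dd = dd, zone = sc$zone,
               points = sc$points, stringsAsFactors = FALSE)
  })
  inc <- score_incidence(effect$beat_stop_incidence,
                         effect$fibrillation_incidence, matrix)
  rows <- c(rows, list(
    data.frame(parameter = "beat_stop", dd = 100 * effect$beat_stop_incidence,
               zone = inc$beat_stop_zone, points = inc$beat_stop_points,
               stringsAsFactors = FALSE),
    data.frame(parameter = "fibrillation",
               dd = 100 * effect$fibrillation_incidence,
               zone = if (inc$fibrillation_points > 0) "present" else "none",
               points = inc$fibrillation_points, stringsAsFactors = FALSE)
  ))
  breakdown <- do.call(rbind, rows)
  total <- sum(breakdown$points)

  override <- isTRUE(matrix$ead_override) && effect$ead_incidence > 0
  label <- if (override) "very_high" else label_from_score(total, matrix$label_ranges)

  structure(
    list(
      compound = effect$compound,
      concentration_uM = effect$concentration_uM,
      total_score = as.integer(total),
      label = label,
      color = unname(hazard_colors[label]),
      override_applied = override,
      ead_incidence = effect$ead_incidence,
      breakdown = breakdown
    ),
    class = "hazard_result"
  )
}

#' @export
print.hazard_result <- function(x, ...) {
  cat(sprintf("<hazard_result> %s @ %g uM: score %d -> %s (%s)%s\n",
              x$compound, x$concentration_uM, x$total_score, x$label, x$color,
              if (x$override_applied) " [EAD override]" else ""))
  print(x$breakdown, row.names = FALSE)
  invisible(x)
}

#' Score every study of a plate
#'
#' @param study_effects Data frame from [compute_study_effects()].
#' @param matrix A `scoring_matrix`.
#' @param qc Optional `plate_qc_report`; a failed plate refuses scoring.
#' @return A data frame (class `hazard_table`) with one row per
#'   compound-concentration: `compound`, `concentration_uM`, `total_score`,
#'   `label`, `color`, `override_applied`; full [score_study()] results in
#'   the attribute `"results"`.
#' @export
score_studies <- function(study_effects, matrix, qc = NULL) {
  results <- lapply(seq_len(nrow(study_effects)), function(i) {
    score_study(study_effects[i, , drop = FALSE], matrix, qc)
  })
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(compound = r$compound, concentration_uM = r$concentration_uM,
               total_score = r$total_score, label = r$label, color = r$color,
               override_applied = r$override_applied, stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(compound = character(0), concentration_uM = numeric(0),
                      total_score = integer(0), label = character(0),
                      color = character(0), override_applied = logical(0))
  }
  attr(tab, "results") <- results
  class(tab) <- c("hazard_table", "data.frame")
  tab
}

#' Rank compounds by concentration-dependent hazard
#'
#' Orders a hazard table for reporting: within each compound, labels are
#' listed by ascending concentration; compounds are ordered from worst to
#' safest by (most severe label reached, lowest concentration at which it
#' is reached), with a deterministic lexicographic tie-break on compound
#' id.
#'
#' @param results A `hazard_table` (possibly rbind-ed over plates).
#' @return The reordered hazard table, with a `rank` column added.
#' @export
rank_compounds <- function(results) {
  if (nrow(results) == 0) return(results)
  key <- paste(results$compound, results$concentration_uM)
  if (anyDuplicated(key)) {
    ct_stop(paste0("duplicate compound-concentration entries: ",
                   paste(unique(key[duplicated(key)]), collapse = "; ")),
            "cthazard_input_error")
  }
  sev <- match(results$label, hazard_levels)
  per_compound <- lapply(split(seq_len(nrow(results)), results$compound), function(idx) {
    worst <- max(sev[idx])
    at <- min(results$concentration_uM[idx][sev[idx] == worst])
    list(worst = worst, at = at)
  })
  comp <- names(per_compound)
  worst <- vapply(per_compound, `[[`, numeric(1), "worst")
  at <- vapply(per_compound, `[[`, numeric(1), "at")
  comp_order <- comp[order(-worst, at, comp)]

  out <- results[order(match(results$compound, comp_order),
                       results$concentration_uM), , drop = FALSE]
  out$rank <- match(out$compound, comp_order)
  rownames(out) <- NULL
  class(out) <- c("hazard_table", "data.frame")
  out
}

#' @export
print.hazard_table <- function(x, ...) {
  df <- as.data.frame(x)
  attr(df, "results") <- NULL
  print(df, row.names = FALSE)
  invisible(x)
}
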