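#' Percent change of a beating parameter versus baseline
#'
#' `100 * (value_30min - value_baseline) / value_baseline`. Defined only for
#' strictly positive baselines; a well that stopped beating has no 30-min
#' parameter value, and its effect is missing (`NA`), not `-100`.
#'
#' @param value_30min Parameter value at the 30-min time point.
#' @param value_baseline Parameter value at baseline (same units); must be
#'   `> 0`.
#' @return Percent change (vectorized).
#' @export
#' @examples
#' delta_percent(600, 500)   # +20
delta_percent <- function(value_30min, value_baseline) {
  if (any(!is.na(value_baseline) & value_baseline <= 0)) {
    ct_stop("baseline value must be > 0 for a percent effect to be defined",
            "cthazard_undefined_effect")
  }
  100 * (value_30min - value_baseline) / value_baseline
}

#' Vehicle-corrected (net) percent effect
#'
#' The plate-level net effect: the drug treatment's median percent change
#' minus the same plate's vehicle median percent change.
#'
#' @param drug_delta Treatment median percent effect.
#' @param vehicle_delta Vehicle median percent effect on the same plate.
#' @return Net percent effect (vectorized).
#' @export
#' @examples
#' delta_delta(18, 2)   # 16
delta_delta <- function(drug_delta, vehicle_delta) {
  if (any(is.na(vehicle_delta))) {
    ct_stop("vehicle median effect is unavailable for this plate",
            "cthazard_normalization_error")
  }
  drug_delta - vehicle_delta
}

#' Well-level quality control at baseline
#'
#' Applies the baseline exclusion rules: wells with no beating, wells
#' annotated as non-synchronous, and wells whose baseline beat rate is lower
#' than `br_bounds[1]` or higher than `br_bounds[2]` beats/min (bounds
#' themselves pass) are excluded.
#'
#' @param baseline_summaries Data frame with columns `well`, `beat_rate`
#'   and `n_beats` for the baseline phase.
#' @param non_synchronous Character vector of wells annotated upstream as
#'   non-synchronously beating.
#' @param br_bounds Inclusive beat-rate acceptance bounds (beats/min).
#' @return The input with `qc_status` (`"included"`/`"excluded"`) and
#'   `qc_reason` (`""`, `"no_beating"`, `"br_out_of_range"`,
#'   `"non_synchronous"`) columns added.
#' @export
apply_well_qc <- function(baseline_summaries, non_synchronous = character(0),
                          br_bounds = c(30, 90)) {
  df <- baseline_summaries
  status <- rep("included", nrow(df))
  reason <- rep("", nrow(df))

  no_beat <- df$n_beats == 0
  reason[no_beat] <- "no_beating"
  out_br <- !no_beat & (df$beat_rate < br_bounds[1] | df$beat_rate > br_bounds[2])
  reason[out_br] <- "br_out_of_range"
  nonsync <- !no_beat & !out_br & df$well %in% non_synchronous
  reason[nonsync] <- "non_synchronous"

  status[no_beat | out_br | nonsync] <- "excluded"
  df$qc_status <- status
  df$qc_reason <- reason
  df
}

#' Per-well percent effects for one plate
#'
#' Summarizes every well of a plate (see [summarize_well()]), applies
#' baseline well QC, and computes the per-well percent change of CTD90,
#' beat rate and amplitude between baseline and the 30-min recording.
#' Wells with beat stop keep their event flags but have missing parameter
#' effects.
#'
#' @param plate A `plate_dataset`.
#' @param config A [feature_config()].
#' @param br_bounds Baseline beat-rate acceptance bounds (beats/min).
#' @return A data frame with one row per well: layout columns, baseline
#'   parameters, `d_ctd90`, `d_br`, `d_amp` (percent), event flags,
#'   `qc_status`, `qc_reason`.
#' @export
compute_well_effects <- function(plate, config = feature_config(),
                                 br_bounds = c(30, 90)) {
  stopifnot(inherits(plate, "plate_dataset"))
  wells <- plate$layout$well

  rows <- lapply(wells, function(w) {
    ws <- summarize_well(plate$recordings[[w]], config)
    base <- ws$phases[ws$phases$phase == "baseline", ]
    p30 <- ws$phases[ws$phases$phase == "post30", ]
    stopped <- isTRUE(ws$beat_stop)
    data.frame(
      well = w,
      baseline_br = base$beat_rate,
      baseline_ctd90 = base$ctd90_median,
      baseline_amp = base$amplitude_median,
      n_beats_baseline = base$n_beats,
      d_ctd90 = if (!stopped && base$n_beats > 0 && p30$n_beats > 0)
        delta_percent(p30$ctd90_median, base$ctd90_median) else NA_real_,
      d_br = if (!stopped && base$n_beats > 0)
        delta_percent(p30$beat_rate, base$beat_rate) else NA_real_,
      d_amp = if (!stopped && base$n_beats > 0 && p30$n_beats > 0)
        delta_percent(p30$amplitude_median, base$amplitude_median) else NA_real_,
      beat_stop = stopped,
      ead = ws$ead_detected,
      fibrillation = ws$fibrillation_detected,
      stringsAsFactors = FALSE
    )
  })
  eff <- do.call(rbind, rows)
  eff <- cbind(plate$layout[match(eff$well, plate$layout$well),
                            c("compound", "concentration_uM", "role")], eff)
  rownames(eff) <- NULL

  qc_in <- data.frame(well = eff$well, beat_rate = eff$baseline_br,
                      n_beats = eff$n_beats_baseline)
  qc <- apply_well_qc(qc_in, plate$non_synchronous %||% character(0), br_bounds)
  eff$qc_status <- qc$qc_status
  eff$qc_reason <- qc$qc_reason
  eff
}

#' Aggregate included wells of one plate treatment
#'
#' Reduces the included wells of a single compound-concentration group to
#' the plate-level study summary: per-parameter medians of the percent
#' effects over included, still-beating wells, and incidence fractions of
#' beat stop, EADs and fibrillation-like events over all included wells.
#' Stopped wells contribute to the incidences but not to the parameter
#' medians. A warning is raised when the included-well count falls outside
#' the 4-8 wells typical of a plate study.
#'
#' @param well_effects Data frame rows (from [compute_well_effects()]) for
#'   one plate-treatment.
#' @param expected_n Acceptable included-well range before a warning.
#' @return A one-row data frame: `n_wells`, `d_ctd90`, `d_br`, `d_amp`,
#'   `beat_stop_incidence`, `ead_incidence`, `fibrillation_incidence`.
#' @export
aggregate_treatment <- function(well_effects, expected_n = c(4, 8)) {
  inc <- well_effects[well_effects$qc_status == "included", , drop = FALSE]
  if (nrow(inc) == 0) {
    ct_stop("no included wells to aggregate", "cthazard_aggregation_error")
  }
  if (nrow(inc) < expected_n[1] || nrow(inc) > expected_n[2]) {
    ct_warn(sprintf("included well count %d outside the expected %d-%d per plate",
                    nrow(inc), expected_n[1], expected_n[2]),
            "cthazard_n_wells_warning")
  }
  beating <- inc[!inc$beat_stop, , drop = FALSE]
  med <- function(v) if (length(v) == 0 || all(is.na(v))) NA_real_ else
    stats::median(v, na.rm = TRUE)
  data.frame(
    n_wells = nrow(inc),
    d_ctd90 = med(beating$d_ctd90),
    d_br = med(beating$d_br),
    d_amp = med(beating$d_amp),
    beat_stop_incidence = mean(inc$beat_stop),
    ead_incidence = mean(inc$ead),
    fibrillation_incidence = mean(inc$fibrillation)
  )
}

#' Plate-level study effects (vehicle-corrected)
#'
#' Aggregates every treatment group of a plate with
#' [aggregate_treatment()], then corrects each parameter median by the
#' plate's vehicle median to obtain the net (`dd_*`) effects. The vehicle
#' reference is the median over all included vehicle wells of the plate.
#'
#' @param well_effects Data frame from [compute_well_effects()].
#' @param expected_n Passed to [aggregate_treatment()].
#' @return A data frame with one row per non-vehicle compound-concentration:
#'   medians (`d_*`), net effects (`dd_*`), incidences and `n_wells`.
#' @export
compute_study_effects <- function(well_effects, expected_n = c(4, 8)) {
  veh <- well_effects[well_effects$role == "vehicle", , drop = FALSE]
  if (nrow(veh[veh$qc_status == "included", ]) == 0) {
    ct_stop("no included vehicle wells on this plate; net effects undefined",
            "cthazard_normalization_error")
  }
  veh_agg <- aggregate_treatment(veh, expected_n = c(1, Inf))
  drugs <- well_effects[well_effects$role != "vehicle", , drop = FALSE]
  if (nrow(drugs) == 0) return(empty_study_effects())

  keys <- unique(drugs[, c("compound", "concentration_uM", "role")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    grp <- drugs[drugs$compound == keys$compound[k] &
                 drugs$concentration_uM == keys$concentration_uM[k], , drop = FALSE]
    if (all(grp$qc_status == "excluded")) return(NULL)
    agg <- aggregate_treatment(grp, expected_n)
    all_stopped <- agg$beat_stop_incidence == 1
    cbind(
      keys[k, , drop = FALSE], agg,
      data.frame(
        dd_ctd90 = if (all_stopped) NA_real_ else delta_delta(agg$d_ctd90, veh_agg$d_ctd90),
        dd_br = if (all_stopped) NA_real_ else delta_delta(agg$d_br, veh_agg$d_br),
        dd_amp = if (all_stopped) NA_real_ else delta_delta(agg$d_amp, veh_agg$d_amp),
        all_stopped = all_stopped
      )
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_study_effects())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "vehicle") <- veh_agg
  out
}

#' An empty study-effects table
#'
#' The zero-row template of the [compute_study_effects()] output, useful
#' for composing QC reports of plates with no scorable treatments.
#'
#' @return A zero-row data frame with the study-effect columns.
#' @export
empty_study_effects <- function() {
  data.frame(
    compound = character(0), concentration_uM = numeric(0), role = character(0),
    n_wells = integer(0), d_ctd90 = numeric(0), d_br = numeric(0),
    d_amp = numeric(0), beat_stop_incidence = numeric(0),
    ead_incidence = numeric(0), fibrillation_incidence = numeric(0),
    dd_ctd90 = numeric(0), dd_br = numeric(0), dd_amp = numeric(0),
    all_stopped = logical(0)
  )
}

#' Default positive-control plate acceptance criteria
#'
#' Plate-level sensitivity checks referencing the standard control drugs:
#' dofetilide (3 nM) must prolong CTD90 by at least +15 net percent,
#' isoprenaline (0.1 uM) must raise the beat rate by at least +30 net
#' percent, and nimodipine (0.1 uM) must shorten CTD90 to at most -10 net
#' percent. A criterion is checked only when the control is present on the
#' plate.
#'
#' @return A list of criteria; each has `compound`, `parameter`
#'   (`"dd_ctd90"`/`"dd_br"`/`"dd_amp"`), `min` or `max`, and a `reason`
#'   tag.
#' @export
default_control_criteria <- function() {
  list(
    list(compound = "dofetilide", parameter = "dd_ctd90", min = 15,
         reason = "dofetilide_insensitive"),
    list(compound = "isoprenaline", parameter = "dd_br", min = 30,
         reason = "isoprenaline_insensitive"),
    list(compound = "nimodipine", parameter = "dd_ctd90", max = -10,
         reason = "nimodipine_insensitive")
  )
}

#' Plate-level quality control
#'
#' A plate fails when more than `max_out_frac` (default 10%) of its wells
#' fall outside the baseline beat-rate criteria (no beating counts as
#' outside), or when any present positive-control criterion is violated
#' (see [default_control_criteria()]). All triggered reasons are reported.
#'
#' @param well_effects Data frame from [compute_well_effects()].
#' @param study_effects Data frame from [compute_study_effects()].
#' @param criteria Positive-control criteria list.
#' @param max_out_frac Maximum tolerated fraction of wells outside the
#'   beat-rate criteria.
#' @return A list of class `plate_qc_report`: `plate_pass`,
#'   `plate_fail_reasons`, `well_exclusions` (data frame), `br_out_fraction`.
#' @export
apply_plate_qc <- function(well_effects, study_effects,
                           criteria = default_control_criteria(),
                           max_out_frac = 0.10) {
  excl <- well_effects[well_effects$qc_status == "excluded",
                       c("well", "qc_reason"), drop = FALSE]
  names(excl) <- c("well", "reason")
  br_out <- sum(well_effects$qc_reason %in% c("br_out_of_range", "no_beating"))
  br_frac <- br_out / nrow(well_effects)

  reasons <- character(0)
  if (br_frac > max_out_frac) {
    reasons <- c(reasons, sprintf("br_criteria_exceeded (%.1f%% of wells)",
                                  100 * br_frac))
  }
  has_controls <- any(well_effects$role == "positive_control")
  if (nrow(study_effects) > 0) {
    for (cr in criteria) {
      hit <- study_effects$compound == cr$compound &
        study_effects$role == "positive_control"
      if (!any(hit)) next
      val <- study_effects[[cr$parameter]][hit][1]
      if (is.na(val)) next
      if ((!is.null(cr$min) && val < cr$min) ||
          (!is.null(cr$max) && val > cr$max)) {
        reasons <- c(reasons, cr$reason)
      }
    }
  } else if (has_controls) {
    reasons <- c(reasons, "positive_controls_not_evaluable")
  }

  structure(
    list(
      plate_pass = length(reasons) == 0,
      plate_fail_reasons = reasons,
      well_exclusions = excl,
      br_out_fraction = br_frac
    ),
    class = "plate_qc_report"
  )
}

#' @export
print.plate_qc_report <- function(x, ...) {
  cat(sprintf("<plate_qc_report> %s | %.1f%% wells outside BR criteria | %d well exclusions\n",
              if (x$plate_pass) "PASS" else "FAIL",
              100 * x$br_out_fraction, nrow(x$well_exclusions)))
  if (!x$plate_pass) cat("reasons:", paste(x$plate_fail_reasons, collapse = "; "), "\n")
  invisible(x)
}
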