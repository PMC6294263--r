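#' Well identifiers of a 96-well plate
#'
#' @param n_rows,n_cols Plate geometry (default 8 x 12).
#' @return Character vector `"A01" ... "H12"` in row-major order.
#' @export
well_ids <- function(n_rows = 8, n_cols = 12) {
  as.vector(t(outer(LETTERS[seq_len(n_rows)], sprintf("%02d", seq_len(n_cols)),
                    paste0)))
}

#' Build a plate layout table
#'
#' @param well Character vector of well ids (`"A01"` style).
#' @param compound Compound identifier per well (`"vehicle"` for vehicle
#'   wells).
#' @param concentration_uM Concentration in uM (0 for vehicle).
#' @param role One of `"vehicle"`, `"positive_control"`, `"test"` per well.
#' @return A `data.frame` with those four columns.
#' @export
plate_layout <- function(well, compound, concentration_uM, role) {
  if (anyDuplicated(well)) {
    ct_stop(paste0("duplicate wells in layout: ",
                   paste(unique(well[duplicated(well)]), collapse = ", ")),
            "cthazard_layout_error")
  }
  if (!all(role %in% c("vehicle", "positive_control", "test"))) {
    ct_stop("`role` must be vehicle, positive_control or test",
            "cthazard_layout_error")
  }
  data.frame(
    well = normalize_well_ids(well), compound = compound,
    concentration_uM = concentration_uM, role = role,
    stringsAsFactors = FALSE
  )
}

# "a1" / "A1" / "A01" -> "A01"
normalize_well_ids <- function(w) {
  m <- regmatches(w, regexec("^([A-Za-z])0?([0-9]{1,2})$", w))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    ct_stop(paste0("malformed well ids: ", paste(w[bad], collapse = ", ")),
            "cthazard_layout_error")
  }
  vapply(m, function(g) sprintf("%s%02d", toupper(g[2]), as.integer(g[3])),
         character(1))
}

#' Baseline heterogeneity of a simulated cell plate
#'
#' Distribution settings for the per-well baseline phenotype: beat rate and
#' CTD90 follow truncated normal distributions (the spontaneous-beating
#' heterogeneity of hiPSC-CM syncytia is approximately Gaussian), amplitude
#' and resting fluorescence are normal with a floor.
#'
#' @param br_mean,br_sd,br_range Beat rate distribution (beats/min),
#'   truncated to `br_range`.
#' @param ctd90_mean,ctd90_sd,ctd90_range Baseline CTD90 distribution (ms).
#' @param amplitude_mean,amplitude_sd,amplitude_min Transient amplitude
#'   (a.u.).
#' @param baseline_level Resting fluorescence (a.u.).
#' @param upstroke_time_constant Kernel rise time constant (ms).
#' @param noise_sd Additive sample noise (a.u.).
#' @return A list of class `baseline_distributions`.
#' @export
baseline_distributions <- function(br_mean = 60, br_sd = 12,
                                   br_range = c(20, 110),
                                   ctd90_mean = 500, ctd90_sd = 80,
                                   ctd90_range = c(250, 850),
                                   amplitude_mean = 50, amplitude_sd = 8,
                                   amplitude_min = 30,
                                   baseline_level = 100,
                                   upstroke_time_constant = 8,
                                   noise_sd = 0.5) {
  structure(as.list(environment()), class = "baseline_distributions")
}

rtruncnorm1 <- function(mean, sd, range) {
  repeat {
    v <- stats::rnorm(1, mean, sd)
    if (v >= range[1] && v <= range[2]) return(v)
  }
}

draw_baseline_shape <- function(dist) {
  br <- rtruncnorm1(dist$br_mean, dist$br_sd, dist$br_range)
  ctd <- rtruncnorm1(dist$ctd90_mean, dist$ctd90_sd, dist$ctd90_range)
  period <- 60000 / br
  # cap CTD90 below the period so beats stay resolvable
  ctd <- min(ctd, 0.8 * period)
  tau_up <- dist$upstroke_time_constant
  tau_decay <- (ctd - .rise10_offset_tc() * tau_up) / log(10)
  amp <- max(stats::rnorm(1, dist$amplitude_mean, dist$amplitude_sd),
             dist$amplitude_min)
  transient_shape(
    baseline_level = dist$baseline_level, amplitude = amp,
    upstroke_time_constant = tau_up, decay_time_constant = tau_decay,
    period = period, noise_sd = dist$noise_sd
  )
}

# fractional vehicle drift per parameter, in percent -> multiplicative factor
drift_factors <- function(sd_pp) 1 + stats::rnorm(3, 0, sd_pp) / 100

#' Simulate a full plate dataset
#'
#' Generates one plate of three-phase recordings (baseline, 15 min and
#' 30 min post compound) for every well of `layout`. Baseline phenotypes are
#' drawn per well from `baseline`; vehicle wells receive only a small seeded
#' drift between baseline and the post phases; treated wells additionally
#' receive the concentration-dependent effect of their compound's
#' [drug_effect_model()], including stochastic EAD-like, fibrillation-like
#' and arrest phenotypes. Each well consumes its own random substream
#' derived from the master seed, so the dataset is reproducible and
#' independent of well iteration order.
#'
#' @param layout A [plate_layout()].
#' @param models Named list of [drug_effect_model()]s, one per non-vehicle
#'   compound in the layout.
#' @param seed Master integer seed; fully determines the dataset.
#' @param baseline A [baseline_distributions()].
#' @param vehicle_drift_sd Per-parameter drift between baseline and the
#'   post phases, in percentage points (applies to all wells).
#' @param duration_s,sampling_rate Recording settings per phase.
#' @param n_ead_spikes Number of EAD-like spikes injected into each post
#'   phase of a well whose EAD flag is drawn.
#' @param non_synchronous Optional character vector of wells annotated as
#'   non-synchronously beating (they are excluded by well QC downstream;
#'   the integrated-well signal itself cannot reveal this).
#' @param include_post15 Generate the 15-min observation recording (default
#'   `TRUE`). It is used only for EAD/fibrillation observation, so large
#'   simulation studies may omit it.
#' @return A list of class `plate_dataset`: `layout`, `recordings` (named by
#'   well, each a named list of the three [trace_recording()] phases),
#'   `sampling_rate`, `duration_s`, `seed`, `events` (data frame of drawn
#'   per-well event flags), `non_synchronous`.
#' @export
generate_plate <- function(layout, models = list(), seed,
                           baseline = baseline_distributions(),
                           vehicle_drift_sd = 3,
                           duration_s = 75, sampling_rate = 66.7,
                           n_ead_spikes = 4,
                           non_synchronous = character(0),
                           include_post15 = TRUE) {
  if (!is.data.frame(layout) ||
      !all(c("well", "compound", "concentration_uM", "role") %in% names(layout))) {
    ct_stop("`layout` must have columns well, compound, concentration_uM, role",
            "cthazard_layout_error")
  }
  if (anyDuplicated(layout$well)) {
    ct_stop(paste0("well referenced twice in layout: ",
                   paste(unique(layout$well[duplicated(layout$well)]), collapse = ", ")),
            "cthazard_layout_error")
  }
  needs_model <- unique(layout$compound[layout$role != "vehicle"])
  missing_models <- setdiff(needs_model, names(models))
  if (length(missing_models) > 0) {
    ct_stop(paste0("no drug_effect_model for: ",
                   paste(missing_models, collapse = ", ")),
            "cthazard_layout_error")
  }

  set.seed(seed)
  n_wells <- nrow(layout)
  well_seeds <- sample.int(.Machine$integer.max - 10L, n_wells)

  recordings <- vector("list", n_wells)
  names(recordings) <- layout$well
  events <- data.frame(
    well = layout$well, ead = FALSE, fibrillation = FALSE, arrest = FALSE,
    stringsAsFactors = FALSE
  )

  for (i in seq_len(n_wells)) {
    set.seed(well_seeds[i])
    shape0 <- draw_baseline_shape(baseline)
    drift <- drift_factors(vehicle_drift_sd)   # ctd90, br, amp

    is_vehicle <- layout$role[i] == "vehicle"
    if (is_vehicle) {
      post <- list(shape = shape0, ead = FALSE, fibrillation = FALSE, arrest = FALSE)
    } else {
      post <- apply_drug_model(shape0, models[[layout$compound[i]]],
                               layout$concentration_uM[i])
    }
    post_shape <- post$shape
    post_shape$decay_time_constant <- post_shape$decay_time_constant * drift[1]
    post_shape$upstroke_time_constant <- post_shape$upstroke_time_constant * drift[1]
    post_shape$period <- post_shape$period / drift[2]
    post_shape$amplitude <- post_shape$amplitude * drift[3]

    events$ead[i] <- post$ead
    events$fibrillation[i] <- post$fibrillation
    events$arrest[i] <- post$arrest

    gen_post <- function(phase) {
      generate_trace(
        post_shape, duration_s, sampling_rate,
        n_eads = if (post$ead) n_ead_spikes else 0,
        fibrillation = post$fibrillation,
        arrest_at_s = if (post$arrest) 10 else NULL
      )
    }
    rec <- list(baseline = generate_trace(shape0, duration_s, sampling_rate))
    if (include_post15) rec$post15 <- gen_post("post15")
    rec$post30 <- gen_post("post30")
    recordings[[i]] <- rec
  }

  structure(
    list(
      layout = layout, recordings = recordings,
      sampling_rate = sampling_rate, duration_s = duration_s, seed = seed,
      events = events,
      non_synchronous = normalize_well_ids(non_synchronous)
    ),
    class = "plate_dataset"
  )
}

#' @export
print.plate_dataset <- function(x, ...) {
  cat(sprintf(
    "<plate_dataset> %d wells x 3 phases, %.0f s @ %.1f Hz, seed %d\n",
    nrow(x$layout), x$duration_s, x$sampling_rate, x$seed
  ))
  print(table(x$layout$role))
  invisible(x)
}

#' A standard control-anchored plate layout
#'
#' Builds a 96-well layout containing 8 vehicle wells, 4 wells of each named
#' positive-control compound and the remaining wells split evenly across the
#' test compounds (one concentration per plate in this helper).
#'
#' @param test_compounds Character vector of test compound ids (may be
#'   empty).
#' @param test_concentration_uM Concentration applied to all test wells.
#' @param controls Named numeric vector of positive-control concentrations
#'   (uM); names are compound ids.
#' @param n_vehicle Number of vehicle wells.
#' @param wells_per_test Wells per test compound; remaining wells are left
#'   as additional vehicle wells.
#' @return A [plate_layout()].
#' @export
default_plate_layout <- function(test_compounds = character(0),
                                 test_concentration_uM = 1,
                                 controls = c(dofetilide = 0.003,
                                              isoprenaline = 0.1,
                                              nimodipine = 0.1),
                                 n_vehicle = 8, wells_per_test = 8) {
  ids <- well_ids()
  n_ctrl <- 4L * length(controls)
  n_test <- wells_per_test * length(test_compounds)
  if (n_vehicle + n_ctrl + n_test > length(ids)) {
    ct_stop("layout does not fit on a 96-well plate", "cthazard_layout_error")
  }
  compound <- c(
    rep("vehicle", n_vehicle),
    rep(names(controls), each = 4),
    rep(test_compounds, each = wells_per_test)
  )
  conc <- c(
    rep(0, n_vehicle),
    rep(unname(controls), each = 4),
    rep(test_concentration_uM, n_test)
  )
  role <- c(
    rep("vehicle", n_vehicle),
    rep("positive_control", n_ctrl),
    rep("test", n_test)
  )
  pad <- length(ids) - length(compound)
  if (pad > 0) {
    compound <- c(compound, rep("vehicle", pad))
    conc <- c(conc, rep(0, pad))
    role <- c(role, rep("vehicle", pad))
  }
  plate_layout(ids, compound, conc, role)
}
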