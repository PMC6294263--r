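#' Derive scoring-matrix cutoffs from vehicle and control effects
#'
#' Turns tolerance intervals of per-well percent effects into the zone
#' boundaries of the scoring matrix, per parameter and direction:
#'
#' * The **no-effect** zone is the vehicle tolerance interval re-centred at
#'   zero (both bounds minus the vehicle TI midpoint), expressing vehicle
#'   variability as net percent.
#' * The **strong anchor** in a direction is the outer bound of the
#'   corresponding control drug's tolerance interval, corrected for the
#'   vehicle offset (minus the vehicle TI midpoint).
#' * The **mild bound** (where the strong zone begins) is placed strictly
#'   between the no-effect bound and the strong anchor; by default at their
#'   midpoint, and a supplied `mild_fraction` moves it
#'   (`0` = at the no-effect bound, `1` = at the anchor).
#'
#' @param vehicle Named list of numeric vectors of vehicle percent effects,
#'   one per parameter (`ctd90`, `br`, `amp`).
#' @param controls List of control sample sets; each element is a list with
#'   `parameter` (`"ctd90"`/`"br"`/`"amp"`), `direction` (`"increase"` or
#'   `"decrease"`) and `samples` (numeric percent effects).
#' @param coverage_p,confidence_gamma Tolerance-interval settings (defaults
#'   0.90 and 0.95).
#' @param mild_fraction Position of the mild/strong boundary between the
#'   no-effect bound and the strong anchor; default 0.5 (midpoint).
#' @return An object of class `cutoff_set`: per parameter, per direction,
#'   `no_effect`, `mild` and `strong` (signed percent), plus the settings.
#' @export
derive_cutoffs <- function(vehicle, controls,
                           coverage_p = 0.90, confidence_gamma = 0.95,
                           mild_fraction = 0.5) {
  params <- c("ctd90", "br", "amp")
  if (!all(params %in% names(vehicle))) {
    ct_stop("`vehicle` must provide samples for ctd90, br and amp",
            "cthazard_input_error")
  }
  if (mild_fraction <= 0 || mild_fraction >= 1) {
    ct_stop("`mild_fraction` must lie strictly in (0, 1)",
            "cthazard_invalid_argument")
  }

  out <- list()
  for (p in params) {
    ti <- wilks_ti(vehicle[[p]], coverage_p, confidence_gamma)
    mid <- (ti$lower + ti$upper) / 2
    no_lo <- ti$lower - mid   # negative
    no_hi <- ti$upper - mid   # positive
    out[[p]] <- list(
      vehicle_ti = c(ti$lower, ti$upper),
      vehicle_midpoint = mid,
      increase = list(no_effect = no_hi, mild = NA_real_, strong = NA_real_),
      decrease = list(no_effect = no_lo, mild = NA_real_, strong = NA_real_)
    )
  }

  for (ctl in controls) {
    p <- ctl$parameter
    dir <- ctl$direction
    if (!p %in% params || !dir %in% c("increase", "decrease")) {
      ct_stop("control entries need parameter in {ctd90, br, amp} and direction in {increase, decrease}",
              "cthazard_input_error")
    }
    ti <- wilks_ti(ctl$samples, coverage_p, confidence_gamma)
    mid <- out[[p]]$vehicle_midpoint
    anchor <- if (dir == "increase") ti$upper - mid else ti$lower - mid
    no_bound <- out[[p]][[dir]]$no_effect
    inside <- if (dir == "increase") anchor <= no_bound else anchor >= no_bound
    if (inside) {
      ct_stop(sprintf(
        "control for %s %s is too weak: corrected TI bound %.1f lies inside the no-effect zone (bound %.1f)",
        p, dir, anchor, no_bound
      ), "cthazard_derivation_error")
    }
    mild <- no_bound + mild_fraction * (anchor - no_bound)
    out[[p]][[dir]]$strong <- anchor
    out[[p]][[dir]]$mild <- mild
  }

  undef <- unlist(lapply(params, function(p) {
    vapply(c("increase", "decrease"), function(d) is.na(out[[p]][[d]]$mild),
           logical(1))
  }))
  if (any(undef)) {
    ct_warn("some parameter directions have no control samples; their mild/strong zones are undefined",
            "cthazard_partial_cutoffs")
  }

  structure(
    list(parameters = out, coverage_p = coverage_p,
         confidence_gamma = confidence_gamma, mild_fraction = mild_fraction),
    class = "cutoff_set"
  )
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("<cutoff_set> %.0f%% coverage / %.0f%% confidence\n",
              100 * x$coverage_p, 100 * x$confidence_gamma))
  for (p in names(x$parameters)) {
    pp <- x$parameters[[p]]
    cat(sprintf(
      "  %-5s no-effect (%+.1f, %+.1f)  strong beyond (%+.1f, %+.1f)  anchors (%+.1f, %+.1f)\n",
      p, pp$decrease$no_effect, pp$increase$no_effect,
      pp$decrease$mild, pp$increase$mild,
      pp$decrease$strong, pp$increase$strong
    ))
  }
  invisible(x)
}
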