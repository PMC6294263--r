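#' Assemble a scoring matrix from cutoffs and weights
#'
#' Combines a [derive_cutoffs()] result with weighted points per zone,
#' beat-stop incidence zones, fibrillation points and the score-to-label
#' ranges into the scoring matrix used by [score_study()].
#'
#' Zone semantics per parameter and direction (boundaries belong to the
#' milder zone): net effects with magnitude up to the `no_effect` bound earn
#' 0 points, up to the `mild` bound earn the mild points, and beyond it the
#' strong points. Beat-stop incidence is scored in three zones (default:
#' up to 50% of wells, more than 50% but not all, and all wells), any
#' fibrillation incidence adds the fibrillation points, and any EAD
#' incidence overrides the label to very high hazard.
#'
#' @param cutoffs A `cutoff_set`.
#' @param weights Named list of per-parameter zone points, each
#'   `c(mild = , strong = )`.
#' @param beat_stop_zones List with `low` (`upper`, `points`), `mid`
#'   (`points`), `full` (`points`); `low$upper` is the inclusive upper edge
#'   of the low-incidence zone and full means incidence exactly 1.
#' @param fibrillation_points Points added when any well fibrillates.
#' @param label_ranges Named list of inclusive score ranges for the labels
#'   `no`, `low`, `high` (the `very_high` label is reachable only through
#'   the EAD override).
#' @return An object of class `scoring_matrix`.
#' @export
scoring_matrix <- function(cutoffs,
                           weights = list(ctd90 = c(mild = 1, strong = 3),
                                          br = c(mild = 1, strong = 2),
                                          amp = c(mild = 1, strong = 2)),
                           beat_stop_zones = list(low = list(upper = 0.5, points = 1),
                                                  mid = list(points = 2),
                                                  full = list(points = 4)),
                           fibrillation_points = 4,
                           label_ranges = list(no = c(0, 0), low = c(1, 2),
                                               high = c(3, Inf))) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  params <- list()
  for (p in c("ctd90", "br", "amp")) {
    cp <- cutoffs$parameters[[p]]
    params[[p]] <- list(
      increase = c(cp$increase, list(points = as.list(weights[[p]]))),
      decrease = c(cp$decrease, list(points = as.list(weights[[p]])))
    )
  }
  m <- structure(
    list(
      parameters = params,
      beat_stop_zones = beat_stop_zones,
      fibrillation_points = fibrillation_points,
      label_ranges = label_ranges,
      ead_override = TRUE,
      coverage_p = cutoffs$coverage_p,
      confidence_gamma = cutoffs$confidence_gamma
    ),
    class = "scoring_matrix"
  )
  validate_scoring_matrix(m)
  m
}

#' Validate a scoring matrix
#'
#' Checks the structural invariants: non-negative points that do not
#' decrease with zone severity, ordered zone boundaries per direction, and
#' label ranges that partition the non-negative scores without overlap.
#'
#' @param matrix A `scoring_matrix` (or the equivalent plain list read from
#'   a config file).
#' @return The matrix, invisibly; errors on violation.
#' @export
validate_scoring_matrix <- function(matrix) {
  for (p in c("ctd90", "br", "amp")) {
    mp <- matrix$parameters[[p]]
    if (is.null(mp)) ct_stop(paste0("matrix missing parameter ", p),
                             "cthazard_config_error")
    for (d in c("increase", "decrease")) {
      z <- mp[[d]]
      pts <- unlist(z$points)
      if (any(pts < 0) || pts["strong"] < pts["mild"]) {
        ct_stop(paste0("points must be >= 0 and nondecreasing with severity (", p, " ", d, ")"),
                "cthazard_config_error")
      }
      if (!is.na(z$mild)) {
        ok <- if (d == "increase") z$no_effect < z$mild else z$no_effect > z$mild
        if (!ok) ct_stop(paste0("zone bounds out of order for ", p, " ", d),
                         "cthazard_config_error")
      }
    }
  }
  lr <- matrix$label_ranges
  if (!all(c("no", "low", "high") %in% names(lr))) {
    ct_stop("label_ranges must define no, low and high", "cthazard_config_error")
  }
  edges <- rbind(lr$no, lr$low, lr$high)
  if (any(edges[, 1] > edges[, 2]) ||
      any(edges[-1, 1] != edges[-nrow(edges), 2] + 1) || edges[1, 1] != 0 ||
      !is.infinite(edges[nrow(edges), 2])) {
    ct_stop("label_ranges must partition [0, Inf) without gaps or overlap",
            "cthazard_config_error")
  }
  bz <- matrix$beat_stop_zones
  bpts <- c(bz$low$points, bz$mid$points, bz$full$points)
  if (any(bpts < 0) || any(diff(bpts) < 0)) {
    ct_stop("beat-stop zone points must be >= 0 and nondecreasing",
            "cthazard_config_error")
  }
  invisible(matrix)
}

#' Write a scoring matrix to a YAML config file
#'
#' @param matrix A `scoring_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scoring_matrix <- function(matrix, path) {
  validate_scoring_matrix(matrix)
  obj <- unclass(matrix)
  # YAML has no native Inf; encode the open-ended top label range explicitly
  obj$label_ranges <- lapply(obj$label_ranges, function(r) {
    if (is.infinite(r[2])) list(r[1], ".inf") else as.list(r)
  })
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a scoring matrix from a YAML config file
#'
#' @param path File written by [write_scoring_matrix()] (or hand-edited in
#'   the same structure); validated on read.
#' @return A `scoring_matrix`.
#' @export
read_scoring_matrix <- function(path) {
  if (!file.exists(path)) {
    ct_stop(paste0("scoring-matrix config not found: ", path),
            "cthazard_config_error")
  }
  obj <- yaml::read_yaml(path)
  obj$label_ranges <- lapply(obj$label_ranges, function(r) {
    v <- vapply(r, function(e) if (identical(e, ".inf")) Inf else as.numeric(e),
                numeric(1))
    v
  })
  fix_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  for (p in c("ctd90", "br", "amp")) {
    for (d in c("increase", "decrease")) {
      z <- obj$parameters[[p]][[d]]
      z$no_effect <- fix_na(z$no_effect)
      z$mild <- fix_na(z$mild)
      z$strong <- fix_na(z$strong)
      obj$parameters[[p]][[d]] <- z
    }
  }
  m <- structure(obj, class = "scoring_matrix")
  validate_scoring_matrix(m)
  m
}

#' The packaged default scoring matrix
#'
#' Cutoffs derived from the packaged synthetic calibration study (see the
#' `data-raw` script and the methods vignette) with the default weights:
#' CTD90 mild 1 / strong 3, beat rate and amplitude mild 1 / strong 2,
#' beat-stop zones 1 / 2 / 4 points, fibrillation 4 points, and label
#' ranges 0 = no, 1-2 = low, >= 3 = high. These are configuration defaults
#' of this package, not published reference values.
#'
#' @return A `scoring_matrix`.
#' @export
default_scoring_matrix <- function() {
  read_scoring_matrix(system.file("extdata", "default_matrix.yaml",
                                  package = "cthazard", mustWork = TRUE))
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("<scoring_matrix>\n")
  for (p in c("ctd90", "br", "amp")) {
    z <- x$parameters[[p]]
    cat(sprintf(
      "  %-5s no (%+.1f, %+.1f)  strong beyond (%+.1f, %+.1f)  points %d/%d (mild/strong)\n",
      p, z$decrease$no_effect, z$increase$no_effect,
      z$decrease$mild, z$increase$mild,
      z$increase$points$mild, z$increase$points$strong
    ))
  }
  bz <- x$beat_stop_zones
  cat(sprintf("  beat stop: (0, %.0f%%] -> %d, (%.0f%%, 100%%) -> %d, 100%% -> %d; fibrillation -> %d\n",
              100 * bz$low$upper, bz$low$points, 100 * bz$low$upper,
              bz$mid$points, bz$full$points, x$fibrillation_points))
  lr <- x$label_ranges
  cat(sprintf("  labels: 0 no | %g-%g low | >=%g high | EAD -> very_high\n",
              lr$low[1], lr$low[2], lr$high[1]))
  invisible(x)
}
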