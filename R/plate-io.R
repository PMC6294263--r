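#' Write a plate dataset to disk
#'
#' Serializes a [generate_plate()] result as the package's plain-text plate
#' format: one wide CSV per phase (`baseline.csv`, `post15.csv`,
#' `post30.csv`; first column `time_s`, one column per well in `A01` order),
#' a `layout.csv` (`well, compound, concentration_uM, role`) and a
#' `manifest.json` (`sampling_rate_hz`, `duration_s`, `seed`,
#' `non_synchronous`).
#'
#' @param plate A `plate_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plate <- function(plate, dir) {
  stopifnot(inherits(plate, "plate_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wells <- plate$layout$well
  phases_present <- intersect(c("baseline", "post15", "post30"),
                              names(plate$recordings[[wells[1]]]))
  for (phase in phases_present) {
    mat <- vapply(wells, function(w) plate$recordings[[w]][[phase]]$samples,
                  numeric(length(plate$recordings[[wells[1]]][[phase]]$samples)))
    df <- data.frame(time_s = (seq_len(nrow(mat)) - 1) / plate$sampling_rate)
    df[wells] <- as.data.frame(mat)
    utils::write.csv(df, file.path(dir, paste0(phase, ".csv")), row.names = FALSE)
  }
  utils::write.csv(plate$layout, file.path(dir, "layout.csv"), row.names = FALSE)
  manifest <- list(
    sampling_rate_hz = plate$sampling_rate,
    duration_s = plate$duration_s,
    seed = plate$seed,
    non_synchronous = plate$non_synchronous
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a plate dataset from disk
#'
#' Inverse of [write_plate()]. Validates that the three phase files share an
#' identical well set, that the time column is strictly increasing and that
#' every sample is finite; well ids are normalized to `A01` style.
#'
#' @param dir Directory containing `baseline.csv`, `post15.csv`,
#'   `post30.csv`, `layout.csv` and `manifest.json`.
#' @return A `plate_dataset`.
#' @export
read_plate <- function(dir) {
  paths <- file.path(dir, c("baseline.csv", "post15.csv", "post30.csv",
                            "layout.csv", "manifest.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    ct_stop(paste0("missing plate files: ", paste(basename(missing), collapse = ", ")),
            "cthazard_format_error")
  }
  manifest <- jsonlite::read_json(paths[5], simplifyVector = TRUE)
  layout <- utils::read.csv(paths[4], stringsAsFactors = FALSE)
  layout$well <- normalize_well_ids(layout$well)

  phases <- list()
  well_sets <- list()
  for (k in 1:3) {
    phase <- c("baseline", "post15", "post30")[k]
    df <- utils::read.csv(paths[k], stringsAsFactors = FALSE, check.names = FALSE)
    if (names(df)[1] != "time_s") {
      ct_stop(paste0(phase, ".csv: first column must be time_s"),
              "cthazard_format_error")
    }
    tt <- df[[1]]
    if (any(diff(tt) <= 0)) {
      ct_stop(paste0(phase, ".csv: time column is not strictly increasing"),
              "cthazard_format_error")
    }
    for (j in 2:ncol(df)) {
      col <- df[[j]]
      if (!is.numeric(col) || anyNA(col) || any(!is.finite(col))) {
        bad_row <- which(!is.finite(suppressWarnings(as.numeric(col))))[1]
        ct_stop(sprintf("%s.csv: non-numeric or non-finite sample at row %d, column %s",
                        phase, bad_row, names(df)[j]),
                "cthazard_parse_error")
      }
    }
    names(df)[-1] <- normalize_well_ids(names(df)[-1])
    phases[[phase]] <- df
    well_sets[[phase]] <- names(df)[-1]
  }

  ref <- well_sets$baseline
  for (phase in c("post15", "post30")) {
    diffw <- c(setdiff(ref, well_sets[[phase]]), setdiff(well_sets[[phase]], ref))
    if (length(diffw) > 0) {
      ct_stop(paste0("wells differ between baseline and ", phase, ": ",
                     paste(unique(diffw), collapse = ", ")),
              "cthazard_format_error")
    }
  }
  if (!setequal(ref, layout$well)) {
    offenders <- c(setdiff(ref, layout$well), setdiff(layout$well, ref))
    ct_stop(paste0("wells differ between trace files and layout: ",
                   paste(offenders, collapse = ", ")),
            "cthazard_format_error")
  }

  fs <- manifest$sampling_rate_hz
  recordings <- lapply(ref, function(w) {
    lapply(phases, function(df) trace_recording(df[[w]], fs))
  })
  names(recordings) <- ref
  layout <- layout[match(ref, layout$well), , drop = FALSE]
  rownames(layout) <- NULL

  structure(
    list(
      layout = layout, recordings = recordings,
      sampling_rate = fs,
      duration_s = manifest$duration_s,
      seed = manifest$seed,
      events = NULL,
      non_synchronous = as.character(unlist(manifest$non_synchronous))
    ),
    class = "plate_dataset"
  )
}
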