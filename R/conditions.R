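# Classed error helper so callers can distinguish failure modes with
# tryCatch(..., cthazard_invalid_argument = ...) etc.
ct_stop <- function(message, class, call. = FALSE) {
  stop(structure(
    class = c(class, "cthazard_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL)
  ))
}

ct_warn <- function(message, class) {
  warning(structure(
    class = c(class, "cthazard_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
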