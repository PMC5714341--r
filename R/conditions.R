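# Classed conditions so the CLI can map failures to exit codes
# (2 = validation / input error, 3 = numerical error).

stop_validation <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...),
                      class = c("crossvar_validation_error", "crossvar_error", "error")))
}

stop_numerical <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...),
                      class = c("crossvar_numerical_error", "crossvar_error", "error")))
}

stop_io <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...),
                      class = c("crossvar_io_error", "crossvar_validation_error",
                                "crossvar_error", "error")))
}
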