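# Classed conditions so callers (and the CLI) can distinguish failure kinds.

.stop_ppi <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "ppi_error"), ...)
}

stop_input      <- function(msg, ...) .stop_ppi(msg, "ppi_input_error", ...)
stop_format     <- function(msg, ...) .stop_ppi(msg, "ppi_format_error", ...)
stop_dimension  <- function(msg, ...) .stop_ppi(msg, "ppi_dimension_error", ...)
stop_degenerate <- function(msg, ...) .stop_ppi(msg, "ppi_degenerate_error", ...)
stop_length     <- function(msg, ...) .stop_ppi(msg, c("ppi_length_error", "ppi_input_error"), ...)
stop_resolution <- function(msg, ...) .stop_ppi(msg, c("ppi_resolution_error", "ppi_format_error"), ...)
stop_schema     <- function(msg, ...) .stop_ppi(msg, c("ppi_schema_error", "ppi_input_error"), ...)
stop_training   <- function(msg, ...) .stop_ppi(msg, c("ppi_training_error", "ppi_input_error"), ...)
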