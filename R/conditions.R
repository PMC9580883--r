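# Classed conditions so callers (and the CLI) can distinguish failure modes.

pcpi_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "pcpinet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_parse       <- function(fmt, ...) pcpi_stop("pcpinet_parse_error", fmt, ...)
stop_dialect     <- function(fmt, ...) pcpi_stop("pcpinet_dialect_error", fmt, ...)
stop_value       <- function(fmt, ...) pcpi_stop("pcpinet_value_error", fmt, ...)
stop_input       <- function(fmt, ...) pcpi_stop("pcpinet_input_error", fmt, ...)
stop_registry    <- function(fmt, ...) pcpi_stop("pcpinet_registry_error", fmt, ...)
stop_assembly    <- function(fmt, ...) pcpi_stop("pcpinet_assembly_error", fmt, ...)
stop_annotation  <- function(fmt, ...) pcpi_stop("pcpinet_annotation_error", fmt, ...)
stop_calibration <- function(fmt, ...) pcpi_stop("pcpinet_calibration_error", fmt, ...)
stop_style       <- function(fmt, ...) pcpi_stop("pcpinet_style_error", fmt, ...)
stop_layout      <- function(fmt, ...) pcpi_stop("pcpinet_layout_error", fmt, ...)
stop_spec        <- function(fmt, ...) pcpi_stop("pcpinet_spec_error", fmt, ...)
stop_config      <- function(fmt, ...) pcpi_stop("pcpinet_config_error", fmt, ...)
stop_usage       <- function(fmt, ...) pcpi_stop("pcpinet_usage_error", fmt, ...)
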