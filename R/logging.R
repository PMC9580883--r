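# Minimal leveled logger. Messages go to stderr via message(); when the
# option pcpinet.log_file is set (the pipeline driver sets it per run), lines
# are appended there too. Log lines carry no timestamps so that pipeline
# output directories are byte-identical across reruns.

.log_levels <- c(debug = 10L, info = 20L, warn = 30L)

pcpi_log <- function(level, fmt, ...) {
  lv <- .log_levels[[level]]
  threshold <- .log_levels[[getOption("pcpinet.log_level", "info")]]
  line <- sprintf("[%s] %s", toupper(level), sprintf(fmt, ...))
  logfile <- getOption("pcpinet.log_file", NULL)
  if (!is.null(logfile)) cat(line, "\n", sep = "", file = logfile, append = TRUE)
  if (lv >= threshold) message(line)
  invisible(line)
}

log_info <- function(fmt, ...) pcpi_log("info", fmt, ...)
log_warn <- function(fmt, ...) pcpi_log("warn", fmt, ...)
log_debug <- function(fmt, ...) pcpi_log("debug", fmt, ...)
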