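# Classed error conditions so callers can distinguish failure modes
# programmatically (validation vs state vs I/O vs integrity ...).

st_stop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(
    msg,
    class = c(paste0("spectratrack_", class, "_error"), "spectratrack_error")
  ))
}

st_validation <- function(fmt, ...) st_stop("validation", fmt, ...)
st_state      <- function(fmt, ...) st_stop("state", fmt, ...)
st_io         <- function(fmt, ...) st_stop("io", fmt, ...)
st_schema     <- function(fmt, ...) st_stop("schema", fmt, ...)
st_integrity  <- function(fmt, ...) st_stop("integrity", fmt, ...)
st_parse      <- function(fmt, ...) st_stop("parse", fmt, ...)
st_resolution <- function(fmt, ...) st_stop("resolution", fmt, ...)
st_estimation <- function(fmt, ...) st_stop("estimation", fmt, ...)
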