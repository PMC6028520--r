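# Classed conditions: every user-facing failure carries a package-specific
# condition class so callers (and the CLI exit-code map) can dispatch on it.

csa_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "dropfreq_error")))
}

stop_io <- function(msg, ...) csa_error("dropfreq_io_error", msg, ...)

stop_parameter <- function(msg, ...) csa_error("dropfreq_parameter_error", msg, ...)

stop_dimension <- function(msg, ...) {
  csa_error(c("dropfreq_dimension_error", "dropfreq_parameter_error"), msg, ...)
}

# cosine similarity is undefined for a zero vector (a black frame signals
# acquisition failure; aborting keeps the time base intact)
stop_zero_vector <- function(msg, ...) {
  csa_error(c("dropfreq_zero_vector_error", "dropfreq_parameter_error"), msg, ...)
}

stop_no_peak <- function(msg, ...) csa_error("dropfreq_no_peak_error", msg, ...)

stop_insufficient <- function(msg, ...) {
  csa_error("dropfreq_insufficient_data_error", msg, ...)
}

warn_aliasing <- function(msg) {
  warning(warningCondition(msg, class = "dropfreq_aliasing_warning"))
}
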