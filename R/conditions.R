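# Classed conditions so callers can tell malformed files (format), internally
# inconsistent content (integrity), bad arguments (parameter) and unusable
# models (model) apart without parsing messages.
scgeno_abort <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "scgeno_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-2))
  ))
}

abort_format    <- function(fmt, ...) scgeno_abort("scgeno_format_error", fmt, ...)
abort_integrity <- function(fmt, ...) scgeno_abort("scgeno_integrity_error", fmt, ...)
abort_parameter <- function(fmt, ...) scgeno_abort("scgeno_parameter_error", fmt, ...)
abort_model     <- function(fmt, ...) scgeno_abort("scgeno_model_error", fmt, ...)
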