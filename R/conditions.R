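# Classed conditions so callers can distinguish failure modes programmatically.
# All error classes are prefixed "afc_" and inherit from "afc_error".

afc_error <- function(subclass, message, call = sys.call(-1), ...) {
  structure(
    class = c(paste0("afc_", subclass, "_error"), "afc_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

stop_degenerate <- function(message, ...) {
  stop(afc_error("degenerate_input", message, ...))
}

stop_domain <- function(message, ...) {
  stop(afc_error("domain", message, ...))
}

afc_warning <- function(subclass, message) {
  warning(structure(
    class = c(paste0("afc_", subclass, "_warning"), "afc_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
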