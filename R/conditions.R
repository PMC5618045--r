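#' @keywords internal
"_PACKAGE"

# Structured error helper: every user-facing failure carries a condition
# class so callers (and the CLI) can branch on error identity.
stop_sicklestain <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "sicklestain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_validation <- function(msg) stop_sicklestain("validation_error", msg)
abort_config     <- function(msg) stop_sicklestain("config_error", msg)
abort_format     <- function(msg) stop_sicklestain("format_error", msg)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
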