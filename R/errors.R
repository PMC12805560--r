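#' @title Condition classes
#' @description All user-facing failures raised by molforge are classed
#'   conditions inheriting from `molforge_error`, so callers (and the CLI) can
#'   distinguish bad input from internal bugs.
#' @name molforge-errors
#' @keywords internal
NULL

abort_mf <- function(class, message, ...) {
  stop(structure(
    class = c(class, "molforge_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

is_mf_error <- function(e) inherits(e, "molforge_error")
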