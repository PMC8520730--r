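#' Structured error conditions
#'
#' Every error raised by the package carries a category class so that callers
#' (and the device-server wire protocol) can match on the *kind* of failure
#' rather than on message text. The category is the first class of the
#' condition; all package errors also inherit from `"virtuscopeError"`.
#'
#' Categories in use: `lifecycleError`, `unknownSettingError`,
#' `validationError`, `permissionError`, `rangeError`, `configurationError`,
#' `triggerMismatchError`, `unknownAxisError`, `limitError`,
#' `emptyQueueError`, `compilationError`, `runtimeError`, `connectionError`,
#' `startupError`, `registrationError`, `ioError`, `deviceFaultError`.
#'
#' @param category single string naming the error category.
#' @param message human-readable message.
#' @param ... additional fields stored on the condition.
#' @return `vsError()` does not return; it signals the condition.
#' @keywords internal
vsError <- function(category, message, ...) {
  cond <- structure(
    class = c(category, "virtuscopeError", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Category of a package error
#'
#' @param e a condition object.
#' @return the category string (first class), or `"error"` for foreign
#'   conditions.
#' @export
errorCategory <- function(e) {
  cls <- class(e)
  if ("virtuscopeError" %in% cls) cls[[1L]] else "error"
}

# Evaluate an expression, capturing a package error as its category string;
# non-errors return list(ok = TRUE, value = ...). Used by fuzzing tests and
# by the wire protocol.
vsTry <- function(expr) {
  tryCatch(
    list(ok = TRUE, value = expr),
    virtuscopeError = function(e) list(ok = FALSE, category = errorCategory(e),
                                       message = conditionMessage(e)),
    error = function(e) list(ok = FALSE, category = "error",
                             message = conditionMessage(e))
  )
}
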