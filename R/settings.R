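#' SettingDescriptor: typed, bounded description of one device feature
#'
#' Device-specific features beyond the per-type interface are exposed through
#' a settings map: name -> value, each value constrained by a descriptor.
#' Kinds are `"integer"`, `"real"`, `"enumerated"`, `"boolean"` and `"text"`.
#' Integer/real descriptors carry an inclusive `(lo, hi)` bound; enumerated
#' descriptors carry a non-empty, duplicate-free list of allowed values;
#' boolean and text descriptors carry no bounds.
#'
#' @slot name setting identifier.
#' @slot kind one of integer, real, enumerated, boolean, text.
#' @slot bounds numeric length-2 for integer/real, a list of allowed values
#'   for enumerated, `NULL` otherwise.
#' @slot readOnly whether writes are refused.
#' @export
setClass("SettingDescriptor",
  representation(name = "character", kind = "character",
                 bounds = "ANY", readOnly = "logical"),
  validity = function(object) {
    msgs <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msgs <- c(msgs, "name must be a single non-empty string")
    kinds <- c("integer", "real", "enumerated", "boolean", "text")
    if (length(object@kind) != 1L || !(object@kind %in% kinds))
      msgs <- c(msgs, sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
    else {
      needsBounds <- object@kind %in% c("integer", "real", "enumerated")
      if (needsBounds && is.null(object@bounds))
        msgs <- c(msgs, "bounds required for integer/real/enumerated kinds")
      if (!needsBounds && !is.null(object@bounds))
        msgs <- c(msgs, "bounds must be absent for boolean/text kinds")
      if (object@kind %in% c("integer", "real") && !is.null(object@bounds)) {
        b <- object@bounds
        if (!is.numeric(b) || length(b) != 2L || anyNA(b))
          msgs <- c(msgs, "numeric bounds must be (lo, hi)")
        else if (b[[1L]] > b[[2L]])
          msgs <- c(msgs, "lo must not exceed hi")
      }
      if (object@kind == "enumerated" && !is.null(object@bounds)) {
        b <- object@bounds
        if (length(b) == 0L)
          msgs <- c(msgs, "enumerated bounds must be non-empty")
        else if (anyDuplicated(b))
          msgs <- c(msgs, "enumerated bounds must be duplicate-free")
      }
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' Create a setting descriptor
#'
#' @param name setting identifier.
#' @param kind `"integer"`, `"real"`, `"enumerated"`, `"boolean"` or
#'   `"text"`.
#' @param bounds inclusive `c(lo, hi)` for integer/real, vector or list of
#'   allowed values for enumerated, `NULL` otherwise.
#' @param readOnly refuse writes if `TRUE`.
#' @return a [SettingDescriptor-class] object.
#' @examples
#' settingDescriptor("gain", "integer", bounds = c(0, 10))
#' settingDescriptor("readout_mode", "enumerated", bounds = c("fast", "slow"))
#' @export
settingDescriptor <- function(name, kind, bounds = NULL, readOnly = FALSE) {
  if (!is.null(bounds) && kind == "enumerated") bounds <- as.list(bounds)
  if (!is.null(bounds) && kind %in% c("integer", "real")) bounds <- as.numeric(bounds)
  new("SettingDescriptor", name = as.character(name), kind = as.character(kind),
      bounds = bounds, readOnly = isTRUE(readOnly))
}

setMethod("show", "SettingDescriptor", function(object) {
  b <- if (is.null(object@bounds)) "" else if (is.numeric(object@bounds))
    sprintf(" in [%g, %g]", object@bounds[[1L]], object@bounds[[2L]])
  else sprintf(" in {%s}", paste(vapply(object@bounds, format, ""), collapse = ", "))
  cat(sprintf("<setting> %s: %s%s%s\n", object@name, object@kind, b,
              if (object@readOnly) " (read-only)" else ""))
})

# Validate a candidate value against a descriptor; signal validationError on
# mismatch. Returns the (possibly coerced) value to store.
checkSettingValue <- function(desc, value) {
  bad <- function(why) vsError("validationError",
    sprintf("invalid value for setting '%s': %s", desc@name, why))
  switch(desc@kind,
    integer = {
      if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
          value != round(value)) bad("not a single integer")
      if (value < desc@bounds[[1L]] || value > desc@bounds[[2L]])
        bad(sprintf("%g outside [%g, %g]", value, desc@bounds[[1L]], desc@bounds[[2L]]))
      as.integer(value)
    },
    real = {
      if (!is.numeric(value) || length(value) != 1L || is.na(value))
        bad("not a single number")
      if (value < desc@bounds[[1L]] || value > desc@bounds[[2L]])
        bad(sprintf("%g outside [%g, %g]", value, desc@bounds[[1L]], desc@bounds[[2L]]))
      as.numeric(value)
    },
    enumerated = {
      if (!any(vapply(desc@bounds, identical, NA, y = value)))
        bad("not one of the allowed values")
      value
    },
    boolean = {
      if (!is.logical(value) || length(value) != 1L || is.na(value))
        bad("not TRUE/FALSE")
      value
    },
    text = {
      if (!is.character(value) || length(value) != 1L) bad("not a single string")
      value
    }
  )
}

#' Accessors for SettingDescriptor
#' @param x a [SettingDescriptor-class].
#' @return the corresponding field.
#' @export
settingName <- function(x) x@name
#' @rdname settingName
#' @export
settingKind <- function(x) x@kind
#' @rdname settingName
#' @export
settingBounds <- function(x) x@bounds
#' @rdname settingName
#' @export
settingReadOnly <- function(x) x@readOnly
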