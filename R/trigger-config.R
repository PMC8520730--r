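#' TriggerConfig: how a device is activated
#'
#' A trigger configuration pairs a trigger *type* (where the activation
#' signal comes from) with a trigger *mode* (what one activation means).
#' Software triggers are just another trigger type, so code written against
#' software triggering upgrades to hardware triggering by changing the
#' configuration, not the code.
#'
#' Types: `software` (an explicit [trigger()] call), `rising_edge` /
#' `falling_edge` (a TTL edge on a digital line), `level_high` / `level_low`
#' (activity spans the interval the line is held at the level).
#'
#' Modes: `once` (one activation per trigger event), `strobe` (one
#' activation per matching edge while the device is enabled), `bulb`
#' (exposure/emission lasts exactly as long as the level is held).
#'
#' The closed set of valid combinations is: software x once;
#' rising_edge/falling_edge x once or strobe; level_high/level_low x bulb.
#'
#' @slot triggerType one of software, rising_edge, falling_edge, level_high,
#'   level_low.
#' @slot triggerMode one of once, bulb, strobe.
#' @export
setClass("TriggerConfig",
  representation(triggerType = "character", triggerMode = "character"),
  validity = function(object) {
    types <- c("software", "rising_edge", "falling_edge", "level_high", "level_low")
    modes <- c("once", "bulb", "strobe")
    if (!(length(object@triggerType) == 1L && object@triggerType %in% types))
      return(sprintf("trigger type must be one of %s", paste(types, collapse = ", ")))
    if (!(length(object@triggerMode) == 1L && object@triggerMode %in% modes))
      return(sprintf("trigger mode must be one of %s", paste(modes, collapse = ", ")))
    lvl <- object@triggerType %in% c("level_high", "level_low")
    if (object@triggerMode == "bulb" && !lvl)
      return("bulb mode requires a level trigger type")
    if (lvl && object@triggerMode != "bulb")
      return("level trigger types support only bulb mode")
    if (object@triggerType == "software" && object@triggerMode != "once")
      return("software triggering supports only once mode")
    TRUE
  }
)

#' Create a trigger configuration
#'
#' @param triggerType `"software"`, `"rising_edge"`, `"falling_edge"`,
#'   `"level_high"` or `"level_low"`.
#' @param triggerMode `"once"`, `"bulb"` or `"strobe"`.
#' @return a [TriggerConfig-class] object; invalid combinations signal a
#'   `configurationError`.
#' @examples
#' triggerConfig("software", "once")
#' triggerConfig("level_high", "bulb")
#' @export
triggerConfig <- function(triggerType, triggerMode = "once") {
  obj <- tryCatch(
    new("TriggerConfig", triggerType = triggerType, triggerMode = triggerMode),
    error = function(e) vsError("configurationError", conditionMessage(e))
  )
  obj
}

setMethod("show", "TriggerConfig", function(object) {
  cat(sprintf("<trigger> type=%s mode=%s\n", object@triggerType, object@triggerMode))
})

#' @rdname triggerConfig
#' @param x a [TriggerConfig-class].
#' @export
triggerType <- function(x) x@triggerType
#' @rdname triggerConfig
#' @export
triggerMode <- function(x) x@triggerMode

# Edge direction (if any) this config responds to, given a line transition.
# transition is "rising" or "falling"; returns TRUE if an edge-configured
# target activates on it.
edgeMatches <- function(config, transition) {
  (config@triggerType == "rising_edge" && transition == "rising") ||
  (config@triggerType == "falling_edge" && transition == "falling")
}

# Level-configured target: does raising the line start (level_high) or end
# (level_low) the active interval?
isLevelType <- function(config) config@triggerType %in% c("level_high", "level_low")
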