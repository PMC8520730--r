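#' Device operation generics
#'
#' The user-facing surface of the device model. Every generic has a method
#' for local [Device] objects and for remote [DeviceProxy] objects, so
#' control code is written once and runs identically against in-process
#' simulators and devices served over the network.
#'
#' @param device a [Device] or [DeviceProxy].
#' @param ... operation arguments, see the individual descriptions.
#' @name device-operations
#' @export describeSettings
#' @export getSetting
#' @export setSetting
#' @export enable
#' @export disable
#' @export shutdown
#' @export deviceState
#' @export deviceKind
#' @export deviceName
#' @export setTrigger
#' @export getTrigger
#' @export trigger
#' @export setPower
#' @export getPower
#' @export emissionLog
#' @export setExposure
#' @export getExposure
#' @export setBinning
#' @export getBinning
#' @export setROI
#' @export getROI
#' @export sensorShape
#' @export framesAvailable
#' @export fetchFrame
#' @export droppedFrames
#' @export nPositions
#' @export setFilterPosition
#' @export getFilterPosition
#' @export moveTo
#' @export moveBy
#' @export axisPositions
#' @export axisLimits
#' @export axisNames
#' @export nActuators
#' @export applyPattern
#' @export queuePatterns
#' @export nextPattern
#' @export currentPattern
#' @export queueLength
#' @export appliedLog
#' @export children
#' @export injectFault
#' @export slowOp
NULL

# One forwarding method per operation: local devices execute the reference
# method of the same name; proxies (see proxy.R) forward over the wire.
.deviceOps <- c(
  "describeSettings", "getSetting", "setSetting",
  "enable", "disable", "shutdown", "deviceState", "deviceKind", "deviceName",
  "setTrigger", "getTrigger", "trigger",
  "setPower", "getPower", "emissionLog",
  "setExposure", "getExposure", "setBinning", "getBinning",
  "setROI", "getROI", "sensorShape",
  "framesAvailable", "fetchFrame", "droppedFrames",
  "nPositions", "setFilterPosition", "getFilterPosition",
  "moveTo", "moveBy", "axisPositions", "axisLimits", "axisNames",
  "nActuators", "applyPattern", "queuePatterns", "nextPattern",
  "currentPattern", "queueLength", "appliedLog",
  "children", "injectFault", "slowOp"
)

for (.op in .deviceOps) {
  setGeneric(.op, eval(bquote(function(device, ...) standardGeneric(.(.op)))))
  setMethod(.op, "Device", eval(bquote(function(device, ...) {
    do.call(`$`(device, .(.op)), list(...))
  })))
}
rm(.op)
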