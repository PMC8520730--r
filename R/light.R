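#' LightSource: normalised power and timed emission
#'
#' Light sources expose `power` as a fraction in the 0-1 range regardless of
#' what a physical device would use (percent, milliwatts, ...), so control
#' code ports between lasers and LEDs unchanged. Out-of-range writes are
#' rejected, never clamped. Power persists across enable/disable.
#'
#' Activations are recorded in an emission log: a software or edge trigger
#' logs one instantaneous emission; a bulb activation logs an emission whose
#' duration equals the time the line was held at its active level.
#'
#' @export LightSource
#' @exportClass LightSource
LightSource <- setRefClass("LightSource",
  contains = "Device",
  fields = list(
    .power = "numeric",
    .emissions = "list"   # list of list(tick, durationSeconds, power)
  ),
  methods = list(
    initialize = function(...) {
      callSuper(...)
      initFields(.power = 0, .emissions = list())
      invisible(NULL)
    },
    deviceKind = function() "light",

    setPower = function(p) {
      assertNotShutDown()
      maybeFault()
      if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
        vsError("rangeError", sprintf("power must be in [0, 1], got %s", format(p)))
      .power <<- as.numeric(p)
      invisible(NULL)
    },
    getPower = function() .power,

    activateOnce = function(tick, tickSeconds) {
      logEmission(tick, 0)
    },
    activateLevelStart = function(tick) {
      .levelOpenTick <<- tick
      invisible(NULL)
    },
    activateLevelEnd = function(tick, durationSeconds) {
      start <- .levelOpenTick
      .levelOpenTick <<- NA_real_
      logEmission(start, durationSeconds)
    },
    logEmission = function(tick, durationSeconds) {
      .emissions[[length(.emissions) + 1L]] <<-
        list(tick = tick, durationSeconds = durationSeconds, power = .power)
      invisible(NULL)
    },
    emissionLog = function() .emissions
  )
)
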