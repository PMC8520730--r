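#' DeformableMirror: actuator patterns and a FIFO pattern queue
#'
#' An adaptive-optics mirror whose surface is shaped by `n` actuators, each
#' set to a fractional displacement in [0, 1]. Patterns can be applied
#' directly or queued; a trigger activation (software call or matching
#' edge) pops and applies the next queued pattern in FIFO order — the
#' standard arrangement for synchronising mirror shapes with camera
#' exposures through hardware triggers.
#'
#' @export DeformableMirror
#' @exportClass DeformableMirror
DeformableMirror <- setRefClass("DeformableMirror",
  contains = "Device",
  fields = list(
    .nActuators = "integer",
    .current = "numeric",
    .queue = "list",
    .applied = "list"   # log of applied patterns (for event-order checks)
  ),
  methods = list(
    initialize = function(..., nActuators = 69L) {
      callSuper(...)
      initFields(.nActuators = as.integer(nActuators),
                 .current = rep(0, nActuators), .queue = list(),
                 .applied = list())
      invisible(NULL)
    },
    deviceKind = function() "mirror",

    nActuators = function() .nActuators,
    checkPattern = function(values) {
      if (!is.numeric(values) || length(values) != .nActuators)
        vsError("validationError",
                sprintf("pattern must have %d values", .nActuators))
      if (anyNA(values) || min(values) < 0 || max(values) > 1)
        vsError("validationError", "actuator values must be in [0, 1]")
      as.numeric(values)
    },
    applyPattern = function(values) {
      assertNotShutDown()
      maybeFault()
      v <- checkPattern(values)
      .current <<- v
      .applied[[length(.applied) + 1L]] <<- v
      invisible(NULL)
    },
    queuePatterns = function(patterns) {
      assertNotShutDown()
      patterns <- lapply(patterns, function(p) checkPattern(p))
      .queue <<- c(.queue, patterns)
      invisible(NULL)
    },
    nextPattern = function() {
      assertNotShutDown()
      if (!length(.queue))
        vsError("emptyQueueError", "pattern queue is empty")
      v <- .queue[[1L]]
      .queue[[1L]] <<- NULL
      .current <<- v
      .applied[[length(.applied) + 1L]] <<- v
      invisible(NULL)
    },
    currentPattern = function() .current,
    queueLength = function() length(.queue),
    appliedLog = function() .applied,

    activateOnce = function(tick, tickSeconds) {
      nextPattern()
    }
  )
)
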