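#' Camera: exposure, binning, ROI and frame delivery
#'
#' Abstract camera on top of [Device]. Concrete cameras implement
#' `acquirePixels()` returning an integer matrix of shape
#' `(roi height, roi width)`. Each activation produces one [Frame-class]
#' with a strictly increasing per-camera index. Frames go to the registered
#' data sink if one is set, otherwise to a bounded internal buffer
#' (capacity 256, drop-oldest with a logged count) from which they can be
#' fetched on demand.
#'
#' ROI is specified in binned-pixel coordinates and applied after binning;
#' changing the binning resets the ROI to the full binned sensor.
#'
#' @export Camera
#' @exportClass Camera
Camera <- setRefClass("Camera",
  contains = "Device",
  fields = list(
    .sensor = "integer",      # c(H, W) in unbinned pixels
    .binning = "integer",     # c(h, v)
    .roi = "ANY",             # ROI in binned coordinates
    .exposure = "numeric",    # seconds
    .frameCounter = "integer",
    .buffer = "list",
    .bufferCapacity = "integer",
    .droppedFrames = "integer",
    .sinkFun = "ANY"          # function(Frame) or NULL
  ),
  methods = list(
    initialize = function(..., sensorShape = c(512L, 512L)) {
      callSuper(...)
      initFields(.sensor = as.integer(sensorShape), .binning = c(1L, 1L),
                 .exposure = 0.1, .frameCounter = 0L, .buffer = list(),
                 .bufferCapacity = 256L, .droppedFrames = 0L, .sinkFun = NULL)
      .roi <<- roi(0L, 0L, .sensor[[2L]], .sensor[[1L]])
      invisible(NULL)
    },
    deviceKind = function() "camera",

    sensorShape = function() .sensor,
    binnedShape = function()
      c(.sensor[[1L]] %/% .binning[[2L]], .sensor[[2L]] %/% .binning[[1L]]),

    setExposure = function(seconds) {
      assertNotShutDown()
      if (!is.numeric(seconds) || length(seconds) != 1L || is.na(seconds) ||
          seconds <= 0)
        vsError("validationError", "exposure must be a single positive number")
      .exposure <<- as.numeric(seconds)
      invisible(NULL)
    },
    getExposure = function() .exposure,

    setBinning = function(h, v) {
      assertNotShutDown()
      if (!all(c(h, v) >= 1) || any(c(h, v) != round(c(h, v))))
        vsError("validationError", "binning factors must be integers >= 1")
      .binning <<- as.integer(c(h, v))
      bs <- binnedShape()
      .roi <<- roi(0L, 0L, bs[[2L]], bs[[1L]])  # reset to full binned frame
      invisible(NULL)
    },
    getBinning = function() .binning,

    setROI = function(region) {
      assertNotShutDown()
      stopifnot(is(region, "ROI"))
      bs <- binnedShape()
      if (region@left + region@width > bs[[2L]] ||
          region@top + region@height > bs[[1L]])
        vsError("validationError",
                sprintf("ROI %dx%d at (%d, %d) exceeds binned sensor %dx%d",
                        region@width, region@height, region@left, region@top,
                        bs[[2L]], bs[[1L]]))
      .roi <<- region
      invisible(NULL)
    },
    getROI = function() .roi,

    # -- trigger-target behaviour ---------------------------------------
    activateOnce = function(tick, tickSeconds) {
      produceFrame(tick = tick, exposure = .exposure)
    },
    activateLevelStart = function(tick) {
      .levelOpenTick <<- tick
      invisible(NULL)
    },
    activateLevelEnd = function(tick, durationSeconds) {
      start <- .levelOpenTick
      .levelOpenTick <<- NA_real_
      produceFrame(tick = start, exposure = durationSeconds)
    },

    produceFrame = function(tick, exposure) {
      pixels <- acquirePixels()
      .frameCounter <<- .frameCounter + 1L
      fr <- newFrame(pixels, .frameCounter, timestampTicks = tick,
                     exposure = exposure)
      if (!is.null(.sinkFun)) .sinkFun(fr) else bufferFrame(fr)
      invisible(fr)
    },
    bufferFrame = function(fr) {
      if (length(.buffer) >= .bufferCapacity) {
        .buffer[[1L]] <<- NULL
        .droppedFrames <<- .droppedFrames + 1L
      }
      .buffer[[length(.buffer) + 1L]] <<- fr
      invisible(NULL)
    },

    acquirePixels = function() {
      vsError("runtimeError", "abstract camera cannot acquire")
    },

    # -- frame retrieval -------------------------------------------------
    framesAvailable = function() length(.buffer),
    fetchFrame = function() {
      if (!length(.buffer)) return(NULL)
      fr <- .buffer[[1L]]
      .buffer[[1L]] <<- NULL
      fr
    },
    droppedFrames = function() .droppedFrames,
    setSinkFun = function(fun) {
      .sinkFun <<- fun
      invisible(NULL)
    }
  )
)
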