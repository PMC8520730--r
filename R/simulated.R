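#' Deterministic stream of Gaussian-spot frames
#'
#' Produces an infinite sequence of single-spot images at uniform-random
#' subpixel locations, with sigma and amplitude drawn uniformly from the
#' given ranges. Centres are kept a margin of `3 * max(sigmaRange)` pixels
#' away from the sensor edge so the full spot stays inside the frame. The
#' stream is a pure function of `(parameters, seed)`: the same seed yields
#' a bit-identical sequence, and the caller's RNG state is never disturbed.
#'
#' @param shape `c(H, W)` frame shape in pixels.
#' @param sigmaRange `c(lo, hi)` spot widths in pixels.
#' @param amplitudeRange `c(lo, hi)` peak intensities above background.
#' @param seed integer seed.
#' @param background baseline intensity.
#' @return a list with `nextFrame()` (returns the next integer pixel
#'   matrix), `lastSpot()` (parameters of the most recent spot) and
#'   `spotLog()` (all spots so far).
#' @examples
#' st <- spotStream(c(64, 64), seed = 7)
#' img <- st$nextFrame()
#' st$lastSpot()$center
#' @export
spotStream <- function(shape, sigmaRange = c(2, 4),
                       amplitudeRange = c(500, 5000), seed,
                       background = 100) {
  stopifnot(length(shape) == 2L, all(shape >= 1),
            sigmaRange[[1L]] > 0, sigmaRange[[2L]] >= sigmaRange[[1L]],
            amplitudeRange[[2L]] >= amplitudeRange[[1L]])
  state <- NULL
  log <- list()
  margin <- 3 * sigmaRange[[2L]]
  drawFrame <- function() {
    env <- globalenv()
    old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
      get(".Random.seed", envir = env) else NULL
    if (is.null(state)) set.seed(as.integer(seed)) else
      assign(".Random.seed", state, envir = env)
    on.exit({
      state <<- get(".Random.seed", envir = env)
      if (is.null(old)) rm(".Random.seed", envir = env)
      else assign(".Random.seed", old, envir = env)
    })
    # for tiny frames the margin may exceed half the frame; degrade to
    # drawing near the centre rather than failing
    mx <- min(margin, (shape[[2L]] - 1) / 2)
    my <- min(margin, (shape[[1L]] - 1) / 2)
    cx <- stats::runif(1, mx, shape[[2L]] - 1 - mx)
    cy <- stats::runif(1, my, shape[[1L]] - 1 - my)
    sg <- stats::runif(1, sigmaRange[[1L]], sigmaRange[[2L]])
    am <- stats::runif(1, amplitudeRange[[1L]], amplitudeRange[[2L]])
    spot <- list(center = c(cx, cy), sigma = sg, amplitude = am,
                 background = background)
    log[[length(log) + 1L]] <<- spot
    renderGaussianSpot(shape, spot$center, spot$sigma, spot$amplitude,
                       spot$background)
  }
  list(nextFrame = drawFrame,
       lastSpot = function() log[[length(log)]],
       spotLog = function() log)
}

#' SpotCamera: simulated camera acquiring random Gaussian spots
#'
#' The development-tool camera: every activation returns a frame with a
#' single 2D Gaussian spot at a seeded uniform-random location, the classic
#' synthetic target for testing alignment and centroiding code without
#' hardware. Declares the raw setting `display_image_number` (stamp the
#' acquisition counter into the top-left pixel)
#' and — illustrating the name-clash rule — `binning_h`/`binning_v`, raw
#' settings that share their underlying state with the interface-level
#' binning property: writing either path updates the same state.
#'
#' @export SpotCamera
#' @exportClass SpotCamera
SpotCamera <- setRefClass("SpotCamera",
  contains = "Camera",
  fields = list(
    .stream = "ANY",
    .seed = "integer",
    .sigmaRange = "numeric",
    .amplitudeRange = "numeric"
  ),
  methods = list(
    initialize = function(..., sensorShape = c(512L, 512L), seed = 1L,
                          sigmaRange = c(2, 4), amplitudeRange = c(500, 5000)) {
      callSuper(..., sensorShape = sensorShape)
      initFields(.stream = NULL, .seed = as.integer(seed),
                 .sigmaRange = as.numeric(sigmaRange),
                 .amplitudeRange = as.numeric(amplitudeRange))
      declareSetting(settingDescriptor("display_image_number", "boolean"),
                     initial = FALSE)
      me <- .self
      declareSetting(settingDescriptor("binning_h", "integer", bounds = c(1, 16)),
                     get = function() me$.binning[[1L]],
                     set = function(value) me$setBinning(value, me$.binning[[2L]]))
      declareSetting(settingDescriptor("binning_v", "integer", bounds = c(1, 16)),
                     get = function() me$.binning[[2L]],
                     set = function(value) me$setBinning(me$.binning[[1L]], value))
      invisible(NULL)
    },
    deviceKind = function() "camera",
    acquirePixels = function() {
      shape <- c(.roi@height, .roi@width)
      if (is.null(.stream) || !identical(.stream$shape, shape)) {
        .stream <<- list(shape = shape,
                         gen = spotStream(shape, .sigmaRange, .amplitudeRange,
                                          seed = .seed))
      }
      px <- .stream$gen$nextFrame()
      if (isTRUE(getSetting("display_image_number")))
        px[1L, 1L] <- (.frameCounter + 1L) %% 65536L
      px
    },
    lastSpot = function() .stream$gen$lastSpot(),
    spotLog = function() if (is.null(.stream)) list() else .stream$gen$spotLog()
  )
)

#' VirtualSampleCamera: stage-aware acquisition from a mosaic
#'
#' Simulates sample navigation: each activation crops an ROI-sized window
#' of the [VirtualSample-class] at the current lateral stage position,
#' selects the channel plane from the current filter-wheel position, and
#' defocuses by the z distance from focus per the [BlurModel-class]. The
#' wheel must have exactly as many positions as the sample has channels.
#'
#' @export VirtualSampleCamera
#' @exportClass VirtualSampleCamera
VirtualSampleCamera <- setRefClass("VirtualSampleCamera",
  contains = "Camera",
  fields = list(
    .sample = "ANY",
    .stage = "ANY",
    .wheel = "ANY",
    .blur = "ANY"
  ),
  methods = list(
    initialize = function(..., sample = NULL, stage = NULL, wheel = NULL,
                          blur = NULL, sensorShape = NULL) {
      if (is.null(sample)) sample <- makeTestSample()
      if (is.null(blur)) blur <- blurModel()
      if (is.null(sensorShape)) sensorShape <- dim(sample@planes)[1:2]
      callSuper(..., sensorShape = as.integer(sensorShape))
      if (is.null(stage) || is.null(wheel))
        vsError("configurationError",
                "a virtual-sample camera needs a stage and a filter wheel")
      if (wheel$nPositions() != nChannels(sample))
        vsError("configurationError",
                sprintf("wheel has %d positions but sample has %d channels",
                        wheel$nPositions(), nChannels(sample)))
      initFields(.sample = sample, .stage = stage, .wheel = wheel, .blur = blur)
      invisible(NULL)
    },
    deviceKind = function() "camera",
    acquirePixels = function() {
      pos <- .stage$axisPositions()
      acquireVirtual(.sample, pos, .wheel$getFilterPosition(), .blur, .roi)
    },
    sampleUsed = function() .sample,
    blurUsed = function() .blur
  )
)

#' SimulatedController: a hub with a filter wheel and a light source
#'
#' Minimal integrated controller used to exercise the children contract:
#' the wheel and light are constructed with the controller, share its
#' lifecycle, and — when served — are auto-registered so clients receive
#' them as working proxies.
#'
#' @export SimulatedController
#' @exportClass SimulatedController
SimulatedController <- setRefClass("SimulatedController",
  contains = "Controller",
  methods = list(
    initialize = function(..., nPositions = 6L) {
      callSuper(...,
        children = list(
          wheel = FilterWheel$new(name = "wheel", nPositions = nPositions),
          light = LightSource$new(name = "light")))
      invisible(NULL)
    }
  )
)
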