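#' ROI: camera readout region
#'
#' Region of interest in *binned* pixel coordinates (applied after binning),
#' 0-based offsets from the sensor's top-left corner.
#'
#' @slot left,top 0-based pixel offsets.
#' @slot width,height region size in pixels (>= 1).
#' @export
setClass("ROI",
  representation(left = "integer", top = "integer",
                 width = "integer", height = "integer"),
  validity = function(object) {
    if (object@width < 1L || object@height < 1L)
      return("width and height must be >= 1")
    if (object@left < 0L || object@top < 0L)
      return("left and top must be >= 0")
    TRUE
  }
)

#' Create an ROI
#' @param left,top 0-based pixel offsets.
#' @param width,height region size in pixels.
#' @return an [ROI-class] object; invalid geometry signals a
#'   `validationError`.
#' @export
roi <- function(left, top, width, height) {
  tryCatch(
    new("ROI", left = as.integer(left), top = as.integer(top),
        width = as.integer(width), height = as.integer(height)),
    error = function(e) vsError("validationError", conditionMessage(e))
  )
}

setMethod("show", "ROI", function(object) {
  cat(sprintf("<roi> %dx%d at (%d, %d)\n",
              object@width, object@height, object@left, object@top))
})

#' Frame: one acquired image plus metadata
#'
#' The unit of camera output: a 2D matrix of unsigned 16-bit intensities
#' (stored as R integers in [0, 65535]), a per-camera running acquisition
#' index, the virtual-clock tick of acquisition (NA for software-triggered
#' captures outside the trigger engine) and the exposure in seconds.
#'
#' @slot pixels integer matrix, values in [0, 65535].
#' @slot index running acquisition counter, strictly increasing per camera.
#' @slot timestampTicks virtual-clock tick of acquisition, or `NA`.
#' @slot exposure exposure duration in seconds.
#' @export
setClass("Frame",
  representation(pixels = "matrix", index = "integer",
                 timestampTicks = "numeric", exposure = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (!is.integer(p)) return("pixels must be an integer matrix")
    if (length(p) && (min(p) < 0L || max(p) > 65535L))
      return("pixel values must be within [0, 65535]")
    if (length(object@index) != 1L || object@index < 1L)
      return("index must be a single positive integer")
    TRUE
  }
)

newFrame <- function(pixels, index, timestampTicks = NA_real_, exposure = NA_real_) {
  new("Frame", pixels = pixels, index = as.integer(index),
      timestampTicks = as.numeric(timestampTicks), exposure = as.numeric(exposure))
}

setMethod("show", "Frame", function(object) {
  cat(sprintf("<frame> #%d %dx%d px, tick=%s, exposure=%s s\n",
              object@index, nrow(object@pixels), ncol(object@pixels),
              format(object@timestampTicks), format(object@exposure)))
})

#' Frame accessors
#' @param x a [Frame-class].
#' @return pixel matrix, acquisition index, timestamp tick or exposure.
#' @export
framePixels <- function(x) x@pixels
#' @rdname framePixels
#' @export
frameIndex <- function(x) x@index
#' @rdname framePixels
#' @export
frameTimestamp <- function(x) x@timestampTicks
#' @rdname framePixels
#' @export
frameExposure <- function(x) x@exposure

# Round and clip a numeric matrix to the unsigned 16-bit integer range.
clipU16 <- function(m) {
  m <- round(m)
  m[m < 0] <- 0
  m[m > 65535] <- 65535
  storage.mode(m) <- "integer"
  m
}
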