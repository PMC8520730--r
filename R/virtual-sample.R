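#' VirtualSample: the world the simulated microscope images
#'
#' A multi-channel mosaic image plus geometry. The stage-aware simulated
#' camera "acquires" a subsection of the mosaic: lateral stage positions
#' select the window (via `unitsPerPixel`), the filter wheel selects the
#' channel plane, and the z axis defocuses the image. Windows that extend
#' past the mosaic are padded with the constant `background` intensity so
#' navigation scripts can roam freely.
#'
#' @slot planes numeric array `(H, W, nChannels)` of intensities in
#'   [0, 65535].
#' @slot unitsPerPixel stage units per mosaic pixel, `c(x, y)`.
#' @slot background pad intensity for out-of-bounds reads.
#' @export
setClass("VirtualSample",
  representation(planes = "array", unitsPerPixel = "numeric",
                 background = "numeric"),
  validity = function(object) {
    d <- dim(object@planes)
    if (length(d) != 3L) return("planes must be a (H, W, nChannels) array")
    if (d[[3L]] < 1L) return("at least one channel required")
    if (length(object@unitsPerPixel) != 2L || any(object@unitsPerPixel <= 0))
      return("unitsPerPixel must be two positive numbers (x, y)")
    if (object@background < 0 || object@background > 65535)
      return("background must be within [0, 65535]")
    TRUE
  }
)

#' Create a virtual sample
#' @param planes `(H, W, nChannels)` array, or a list of equal-shape
#'   matrices (one per channel).
#' @param unitsPerPixel stage units per mosaic pixel; scalar or `c(x, y)`.
#' @param background pad intensity for out-of-bounds reads.
#' @return a [VirtualSample-class].
#' @export
virtualSample <- function(planes, unitsPerPixel = 1, background = 0) {
  if (is.list(planes)) {
    planes <- array(unlist(planes),
                    dim = c(dim(planes[[1L]]), length(planes)))
  }
  if (length(unitsPerPixel) == 1L) unitsPerPixel <- rep(unitsPerPixel, 2L)
  new("VirtualSample", planes = planes,
      unitsPerPixel = as.numeric(unitsPerPixel),
      background = as.numeric(background))
}

setMethod("show", "VirtualSample", function(object) {
  d <- dim(object@planes)
  cat(sprintf("<virtual sample> %dx%d px, %d channel(s), %g/%g units/px, background=%g\n",
              d[[1L]], d[[2L]], d[[3L]], object@unitsPerPixel[[1L]],
              object@unitsPerPixel[[2L]], object@background))
})

#' @rdname virtualSample
#' @param x a [VirtualSample-class].
#' @export
nChannels <- function(x) dim(x@planes)[[3L]]
#' @rdname virtualSample
#' @export
samplePlanes <- function(x) x@planes
#' @rdname virtualSample
#' @export
sampleBackground <- function(x) x@background

#' BlurModel: defocus as Gaussian blur
#'
#' Focus is emulated by blurring the cropped window with a Gaussian kernel
#' whose sigma grows linearly with the distance of the stage z axis from
#' the in-focus position: `sigma = coefficient * |z - focalZ|` (pixels).
#' This is the simplest blur law that is monotone in defocus and symmetric
#' about focus; at `z = focalZ` the acquisition is bit-identical to the
#' mosaic crop.
#'
#' @slot focalZ in-focus z position (stage units).
#' @slot coefficient blur sigma in pixels per stage unit of defocus
#'   (`>= 0`).
#' @export
setClass("BlurModel",
  representation(focalZ = "numeric", coefficient = "numeric"),
  validity = function(object) {
    if (object@coefficient < 0) return("coefficient must be >= 0")
    TRUE
  }
)

#' @rdname BlurModel-class
#' @param focalZ in-focus z position.
#' @param coefficient blur sigma (pixels) per stage unit of defocus.
#' @return a [BlurModel-class].
#' @export
blurModel <- function(focalZ = 0, coefficient = 0.5) {
  new("BlurModel", focalZ = as.numeric(focalZ),
      coefficient = as.numeric(coefficient))
}

#' Render a 2D Gaussian spot
#'
#' Pixel `(r, c)` (0-based) gets
#' `background + amplitude * exp(-((c - x)^2 + (r - y)^2) / (2 sigma^2))`,
#' rounded and clipped to the unsigned 16-bit range.
#'
#' @param shape `c(H, W)` in pixels.
#' @param center `c(x, y)` subpixel spot centre (x along columns, y along
#'   rows, 0-based).
#' @param sigma spot width in pixels (> 0).
#' @param amplitude peak intensity above background (>= 0).
#' @param background baseline intensity (>= 0);
#'   `amplitude + background <= 65535`.
#' @return integer matrix `(H, W)`.
#' @examples
#' img <- renderGaussianSpot(c(64, 64), c(20, 30), sigma = 3,
#'                           amplitude = 1000, background = 100)
#' @export
renderGaussianSpot <- function(shape, center, sigma, amplitude, background = 0) {
  if (length(shape) != 2L || any(shape < 1))
    vsError("validationError", "shape must be positive (H, W)")
  if (sigma <= 0) vsError("validationError", "sigma must be > 0")
  if (amplitude < 0 || background < 0)
    vsError("validationError", "amplitude and background must be >= 0")
  if (amplitude + background > 65535)
    vsError("validationError", "amplitude + background must not exceed 65535")
  H <- shape[[1L]]; W <- shape[[2L]]
  dy <- (seq_len(H) - 1) - center[[2L]]
  dx <- (seq_len(W) - 1) - center[[1L]]
  g <- exp(-outer(dy^2, dx^2, `+`) / (2 * sigma^2))
  clipU16(background + amplitude * g)
}

#' Deterministic synthetic multi-channel sample
#'
#' Builds a [VirtualSample-class] whose channels each contain `nSpots`
#' Gaussian spots at seeded random positions over a constant background.
#' Channels use distinct sub-seeds so they differ; the whole sample is a
#' pure function of its parameters and seed.
#'
#' @param nChannels number of channel planes.
#' @param H,W mosaic size in pixels.
#' @param nSpots spots per channel.
#' @param seed integer seed.
#' @param background baseline intensity.
#' @param unitsPerPixel stage units per mosaic pixel.
#' @return a [VirtualSample-class].
#' @export
makeTestSample <- function(nChannels = 2L, H = 256L, W = 256L, nSpots = 30L,
                           seed = 1L, background = 100, unitsPerPixel = 1) {
  planes <- array(0, dim = c(H, W, nChannels))
  for (ch in seq_len(nChannels)) {
    acc <- matrix(background, H, W)
    withSeed(seed * 1009L + ch * 9973L, {
      for (s in seq_len(nSpots)) {
        cx <- stats::runif(1, 0, W - 1)
        cy <- stats::runif(1, 0, H - 1)
        sg <- stats::runif(1, 1.5, 4)
        am <- stats::runif(1, 500, 4000)
        dy <- (seq_len(H) - 1) - cy
        dx <- (seq_len(W) - 1) - cx
        acc <- acc + am * exp(-outer(dy^2, dx^2, `+`) / (2 * sg^2))
      }
    })
    planes[, , ch] <- pmin(pmax(round(acc), 0), 65535)
  }
  virtualSample(planes, unitsPerPixel = unitsPerPixel, background = background)
}

# Crop a (h, w) window from a matrix with top-left (0-based) (top, left),
# padding out-of-bounds pixels with `background`.
cropWithPadding <- function(plane, top, left, h, w, background) {
  out <- matrix(background, h, w)
  H <- nrow(plane); W <- ncol(plane)
  rows <- (top + 1L):(top + h)
  cols <- (left + 1L):(left + w)
  rIn <- which(rows >= 1L & rows <= H)
  cIn <- which(cols >= 1L & cols <= W)
  if (length(rIn) && length(cIn))
    out[rIn, cIn] <- plane[rows[rIn], cols[cIn]]
  out
}

# Separable Gaussian blur with kernel truncated at 4*sigma. The input is
# expected to already include the padding margin; "valid" convolution
# shrinks it back by the kernel radius on each side.
gaussianBlurValid <- function(m, sigma) {
  r <- blurRadius(sigma)
  if (r == 0L) return(m)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  # convolve columns then rows; stats::filter keeps length, so pad-crop by r
  byCol <- apply(m, 2L, function(col) stats::convolve(col, rev(k), type = "filter"))
  t(apply(byCol, 1L, function(row) stats::convolve(row, rev(k), type = "filter")))
}

blurRadius <- function(sigma) if (sigma <= 0) 0L else as.integer(ceiling(4 * sigma))

#' Acquire a frame from a virtual sample
#'
#' Implements the stage-aware simulated acquisition: the window's top-left
#' mosaic pixel is `(round(x / unitsPerPixel[x]), round(y / unitsPerPixel[y]))`
#' plus the ROI offsets; the channel plane is chosen by the filter-wheel
#' position `k` (0-based); the ROI-sized window is cropped with constant
#' background padding; defocus blur of
#' `sigma = coefficient * |z - focalZ|` is applied with a kernel truncated
#' at 4 sigma over a window enlarged by the kernel radius, so edge pixels
#' blur correctly; finally values are rounded and clipped to unsigned
#' 16 bits. At `z = focalZ` the result is bit-identical to the mosaic
#' subregion.
#'
#' @param sample a [VirtualSample-class].
#' @param position named vector with `x`, `y`, `z` stage positions.
#' @param k filter-wheel position selecting the channel (0-based).
#' @param blur a [BlurModel-class].
#' @param region an [ROI-class] giving the frame shape and offsets.
#' @return integer matrix `(region height, region width)`.
#' @export
acquireVirtual <- function(sample, position, k, blur, region) {
  nc <- nChannels(sample)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k >= nc)
    vsError("rangeError",
            sprintf("channel %s outside wheel range [0, %d]", format(k), nc - 1L))
  plane <- sample@planes[, , as.integer(k) + 1L]
  left0 <- as.integer(round(position[["x"]] / sample@unitsPerPixel[[1L]])) + region@left
  top0 <- as.integer(round(position[["y"]] / sample@unitsPerPixel[[2L]])) + region@top
  sigma <- blur@coefficient * abs(position[["z"]] - blur@focalZ)
  r <- blurRadius(sigma)
  win <- cropWithPadding(plane, top0 - r, left0 - r,
                         region@height + 2L * r, region@width + 2L * r,
                         sample@background)
  clipU16(gaussianBlurValid(win, sigma))
}

# Run expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards. Keeps every generator a pure function of
# (parameters, seed) without disturbing user code.
withSeed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = env)
    else assign(".Random.seed", old, envir = env)
  })
  expr
}
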