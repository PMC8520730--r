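#' AxisDescriptor: one stage axis with limits
#'
#' @slot name axis name (e.g. "x", "y", "z").
#' @slot lower,upper position limits in device units.
#' @slot position current position; always within `[lower, upper]`.
#' @export
setClass("AxisDescriptor",
  representation(name = "character", lower = "numeric",
                 upper = "numeric", position = "numeric"),
  validity = function(object) {
    if (object@lower > object@upper) return("lower must not exceed upper")
    if (object@position < object@lower || object@position > object@upper)
      return("position must be within [lower, upper]")
    TRUE
  }
)

#' Create an axis descriptor
#' @param name axis name.
#' @param lower,upper position limits in device units.
#' @param position starting position (defaults to `lower`).
#' @return an [AxisDescriptor-class].
#' @export
axisDescriptor <- function(name, lower, upper, position = lower) {
  new("AxisDescriptor", name = name, lower = as.numeric(lower),
      upper = as.numeric(upper), position = as.numeric(position))
}

setMethod("show", "AxisDescriptor", function(object) {
  cat(sprintf("<axis> %s: %g in [%g, %g]\n", object@name, object@position,
              object@lower, object@upper))
})

#' Stage: multi-axis positioner with hard limits and atomic moves
#'
#' Moves address any subset of axes by name. All targets are validated
#' against the axis limits *before* any axis moves, so a rejected move
#' leaves every axis where it was (atomic multi-axis moves). Positions are
#' in device units; the virtual-sample camera maps lateral positions to
#' mosaic pixels.
#'
#' @export Stage
#' @exportClass Stage
Stage <- setRefClass("Stage",
  contains = "Device",
  fields = list(
    .axes = "list"   # name -> AxisDescriptor
  ),
  methods = list(
    initialize = function(..., axes = list()) {
      callSuper(...)
      if (!length(axes)) {
        axes <- list(axisDescriptor("x", 0, 10000, 0),
                     axisDescriptor("y", 0, 10000, 0),
                     axisDescriptor("z", 0, 100, 0))
      }
      names(axes) <- vapply(axes, function(a) a@name, "")
      initFields(.axes = axes)
      invisible(NULL)
    },
    deviceKind = function() "stage",

    axisNames = function() names(.axes),
    axisLimits = function() {
      lims <- lapply(.axes, function(a) c(lower = a@lower, upper = a@upper))
      lims
    },
    axisPositions = function() {
      vapply(.axes, function(a) a@position, 0)
    },

    # targets: named numeric vector/list of absolute positions.
    moveTo = function(targets) {
      assertNotShutDown()
      maybeFault()
      targets <- unlist(targets)
      nms <- names(targets)
      if (is.null(nms) || any(!nzchar(nms)))
        vsError("validationError", "move targets must be named by axis")
      unknown <- setdiff(nms, names(.axes))
      if (length(unknown))
        vsError("unknownAxisError",
                sprintf("no axis named '%s'", unknown[[1L]]))
      # validate everything before moving anything
      for (nm in nms) {
        a <- .axes[[nm]]
        tgt <- targets[[nm]]
        if (!is.finite(tgt) || tgt < a@lower || tgt > a@upper)
          vsError("limitError",
                  sprintf("target %g for axis '%s' outside [%g, %g]; no axis moved",
                          tgt, nm, a@lower, a@upper))
      }
      for (nm in nms) .axes[[nm]]@position <<- as.numeric(targets[[nm]])
      axisPositions()
    },
    moveBy = function(deltas) {
      deltas <- unlist(deltas)
      nms <- names(deltas)
      if (is.null(nms) || any(!nzchar(nms)))
        vsError("validationError", "move deltas must be named by axis")
      unknown <- setdiff(nms, names(.axes))
      if (length(unknown))
        vsError("unknownAxisError", sprintf("no axis named '%s'", unknown[[1L]]))
      cur <- vapply(nms, function(nm) .axes[[nm]]@position, 0)
      moveTo(stats::setNames(cur + deltas, nms))
    }
  )
)
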