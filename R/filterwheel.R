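#' FilterWheel: discrete channel selection
#'
#' A rotating carrier with `n` positions, indexed 0-based and contiguous;
#' moves are instantaneous for simulators. When paired with the stage-aware
#' virtual-sample camera, the wheel position selects the imaged channel.
#'
#' @export FilterWheel
#' @exportClass FilterWheel
FilterWheel <- setRefClass("FilterWheel",
  contains = "Device",
  fields = list(
    .nPositions = "integer",
    .position = "integer"
  ),
  methods = list(
    initialize = function(..., nPositions = 6L) {
      callSuper(...)
      if (nPositions < 1L)
        vsError("validationError", "a filter wheel needs at least one position")
      initFields(.nPositions = as.integer(nPositions), .position = 0L)
      invisible(NULL)
    },
    deviceKind = function() "filterwheel",

    nPositions = function() .nPositions,
    setFilterPosition = function(k) {
      assertNotShutDown()
      maybeFault()
      if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k) ||
          k < 0 || k >= .nPositions)
        vsError("rangeError",
                sprintf("position must be an integer in [0, %d]", .nPositions - 1L))
      .position <<- as.integer(k)
      invisible(NULL)
    },
    getFilterPosition = function() .position
  )
)
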