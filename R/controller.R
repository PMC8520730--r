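#' Controller: integrated multi-device hardware
#'
#' Some instruments expose several logical devices behind one connection
#' (e.g. a hub with a filter wheel and a light source). A controller owns a
#' stable name -> device map of children. Children share the controller's
#' lifecycle: shutting the controller down shuts every child down. When a
#' controller is published by the device server, its children are
#' registered at initialisation and client calls to [children()] return
#' working remote proxies.
#'
#' @export Controller
#' @exportClass Controller
Controller <- setRefClass("Controller",
  contains = "Device",
  fields = list(
    .children = "list"   # name -> Device
  ),
  methods = list(
    initialize = function(..., children = list()) {
      callSuper(...)
      initFields(.children = children)
      invisible(NULL)
    },
    deviceKind = function() "controller",
    children = function() .children,
    onShutdown = function() {
      for (child in .children) child$shutdown()
      invisible(NULL)
    }
  )
)
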