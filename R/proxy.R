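#' DeviceProxy: transparent client-side handle to a served device
#'
#' Obtained from [connectDevice()]. Exposes the same operation surface as
#' a local device: every generic in the device API dispatches over the
#' wire, results come back as local values, remote errors are re-raised
#' client-side in the same category, and device references in results
#' (controller children) arrive as working proxies. Two proxies to one URI
#' address the same single device instance.
#'
#' @export DeviceProxy
#' @exportClass DeviceProxy
DeviceProxy <- setRefClass("DeviceProxy",
  fields = list(
    .host = "character",
    .port = "integer",
    .target = "character",
    .pending = "ANY"      # open connection of an in-flight async call
  ),
  methods = list(
    initialize = function(..., host = "127.0.0.1", port = 0L, target = "") {
      initFields(.host = host, .port = as.integer(port), .target = target,
                 .pending = NULL)
      callSuper(...)
    },
    uri = function() sprintf("scope://%s:%d/%s", .host, .port, .target),
    remoteCall = function(method, args = list()) {
      con <- openWire(.host, .port)
      on.exit(try(close(con), silent = TRUE))
      sendMsg(con, list(target = .target, method = method, args = args))
      resp <- recvMsg(con, timeoutSeconds = 60)
      if (!isTRUE(resp$ok)) vsError(resp$category, resp$message)
      decodeFromWire(resp$value)
    },
    # Pipelined call: send now, read the reply later with collectCall().
    # Two async calls on proxies served by different workers overlap in
    # real time (each worker is its own process).
    sendCall = function(method, args = list()) {
      if (!is.null(.pending))
        vsError("connectionError", "a call is already in flight on this proxy")
      con <- openWire(.host, .port)
      sendMsg(con, list(target = .target, method = method, args = args))
      .pending <<- con
      invisible(NULL)
    },
    collectCall = function(timeoutSeconds = 60) {
      if (is.null(.pending))
        vsError("connectionError", "no call in flight on this proxy")
      con <- .pending
      .pending <<- NULL
      on.exit(try(close(con), silent = TRUE))
      resp <- recvMsg(con, timeoutSeconds = timeoutSeconds)
      if (!isTRUE(resp$ok)) vsError(resp$category, resp$message)
      decodeFromWire(resp$value)
    },
    show = function() {
      cat(sprintf("<device proxy> %s\n", uri()))
    }
  )
)

# Forward every device operation (plus the engine activation hooks) over
# the wire under its own name, so a proxy drops into any code written for
# local devices — including the trigger engine.
local({
  ops <- c(.deviceOps, "activateOnce", "activateLevelStart", "activateLevelEnd")
  for (op in ops) {
    DeviceProxy$methods(stats::setNames(list(eval(bquote(
      function(...) remoteCall(.(op), list(...))
    ))), op))
  }
  for (op in .deviceOps) {
    setMethod(op, "DeviceProxy", eval(bquote(function(device, ...) {
      device$remoteCall(.(op), list(...))
    })))
  }
})

#' Connect to a served device
#'
#' @param uri the device URI, canonically `scope://host:port/name`.
#' @param timeoutSeconds connection timeout.
#' @return a [DeviceProxy]; unreachable endpoints or unknown device names
#'   signal a `connectionError`.
#' @export
connectDevice <- function(uri, timeoutSeconds = 5) {
  p <- parseURI(uri)
  con <- openWire(p$host, p$port, timeoutSeconds)
  on.exit(try(close(con), silent = TRUE))
  sendMsg(con, list(control = "describe"))
  resp <- recvMsg(con, timeoutSeconds = timeoutSeconds)
  if (!isTRUE(resp$ok))
    vsError("connectionError", sprintf("endpoint refused: %s", resp$message))
  if (!(p$name %in% names(resp$value$devices)))
    vsError("connectionError",
            sprintf("no device named '%s' at %s:%d", p$name, p$host, p$port))
  DeviceProxy$new(host = p$host, port = p$port, target = p$name)
}

#' @rdname registerDataClient
setMethod("registerDataClient", "DeviceProxy", function(camera, sink) {
  camera$remoteCall(".registerSink", list(sink$uri()))
  invisible(NULL)
})

#' Overlap two slow operations on different workers
#'
#' Convenience wrapper over the pipelined proxy calls: both requests are
#' written before either response is read, so devices served by different
#' worker processes execute them concurrently.
#'
#' @param proxyA,proxyB device proxies (served by different workers for
#'   true overlap).
#' @param method operation name.
#' @param argsA,argsB argument lists.
#' @return list of the two results.
#' @export
callConcurrently <- function(proxyA, proxyB, method, argsA = list(),
                             argsB = list()) {
  proxyA$sendCall(method, argsA)
  proxyB$sendCall(method, argsB)
  resA <- proxyA$collectCall()
  resB <- proxyB$collectCall()
  list(resA, resB)
}
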