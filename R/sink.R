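#' FrameSink: client-side endpoint receiving camera frames
#'
#' The data client of the acquisition pipeline. A *local* sink simply
#' collects frames pushed by an in-process camera. A *network* sink opens a
#' listening endpoint; a served camera registered with
#' [registerDataClient()] connects to it and pushes every subsequent frame
#' asynchronously — the triggering call returns before delivery completes,
#' and frames arrive in acquisition-index order.
#'
#' @export FrameSink
#' @exportClass FrameSink
FrameSink <- setRefClass("FrameSink",
  fields = list(
    .mode = "character",
    .host = "character",
    .port = "integer",
    .srv = "ANY",
    .con = "ANY",
    .frames = "list"
  ),
  methods = list(
    initialize = function(..., network = FALSE, host = "127.0.0.1", port = NULL) {
      initFields(.mode = if (network) "network" else "local", .host = host,
                 .port = NA_integer_, .srv = NULL, .con = NULL, .frames = list())
      callSuper(...)
      if (network) {
        if (is.null(port)) port <- freePort()
        .srv <<- tryCatch(serverSocket(port), error = function(e)
          vsError("startupError",
                  sprintf("cannot listen on port %d: %s", port, conditionMessage(e))))
        .port <<- as.integer(port)
      }
      invisible(NULL)
    },
    uri = function() {
      if (.mode != "network")
        vsError("configurationError", "a local sink has no uri")
      sprintf("scope://%s:%d/sink", .host, .port)
    },
    push = function(fr) {
      .frames[[length(.frames) + 1L]] <<- fr
      invisible(NULL)
    },
    # Receive until `n` frames are held or `timeoutSeconds` passes.
    collect = function(n, timeoutSeconds = 10) {
      if (.mode == "local") return(.frames)
      deadline <- Sys.time() + timeoutSeconds
      while (length(.frames) < n && Sys.time() < deadline) {
        if (is.null(.con)) {
          if (!isTRUE(socketSelect(list(.srv), timeout = 0.2)[[1L]])) next
          .con <<- socketAccept(.srv, blocking = TRUE, open = "a+b")
        }
        if (!isTRUE(socketSelect(list(.con), timeout = 0.2)[[1L]])) next
        fr <- tryCatch(unserialize(.con), error = function(e) NULL)
        if (is.null(fr)) { try(base::close(.con), silent = TRUE); .con <<- NULL; next }
        push(fr)
      }
      .frames
    },
    frames = function() .frames,
    closeSink = function() {
      if (!is.null(.con)) try(base::close(.con), silent = TRUE)
      if (!is.null(.srv)) try(base::close(.srv), silent = TRUE)
      .con <<- NULL; .srv <<- NULL
      invisible(NULL)
    },
    show = function() {
      cat(sprintf("<frame sink> %s, %d frame(s)%s\n", .mode, length(.frames),
                  if (.mode == "network") sprintf(" at %s", uri()) else ""))
    }
  )
)

#' Create a frame sink
#' @param network listen on a TCP endpoint (for served cameras) instead of
#'   collecting in-process.
#' @param port endpoint port; a free port is picked when `NULL`.
#' @return a [FrameSink] object.
#' @export
frameSink <- function(network = FALSE, port = NULL) {
  FrameSink$new(network = network, port = port)
}

#' @rdname frameSink
#' @param sink a [FrameSink].
#' @param n number of frames to wait for.
#' @param timeoutSeconds how long to wait.
#' @export
collectFrames <- function(sink, n, timeoutSeconds = 10) {
  sink$collect(n, timeoutSeconds)
}

#' @rdname frameSink
#' @export
sinkFrames <- function(sink) sink$frames()

#' Register the data client of a camera
#'
#' For a local camera, subsequent frames are pushed straight into the sink.
#' For a served camera proxy, the sink's URI is passed to the worker, which
#' connects back and pushes frames asynchronously (the triggering call
#' returns before delivery completes). Re-registering replaces the previous
#' sink: subsequent frames go only to the new one.
#'
#' @param camera a [Camera] or a camera [DeviceProxy].
#' @param sink a [FrameSink] (network mode required for proxies).
#' @export
setGeneric("registerDataClient", function(camera, sink)
  standardGeneric("registerDataClient"))

#' @rdname registerDataClient
setMethod("registerDataClient", "Camera", function(camera, sink) {
  camera$setSinkFun(function(fr) sink$push(fr))
  invisible(NULL)
})

# Pick an unused TCP port by binding and releasing it.
freePort <- function() {
  for (i in 1:50) {
    p <- sample(20000:59999, 1L)
    s <- tryCatch(serverSocket(p), error = function(e) NULL)
    if (!is.null(s)) { close(s); return(p) }
  }
  vsError("startupError", "no free port found")
}
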