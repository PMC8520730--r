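#' ServerHandle: a running device server
#'
#' Returned by [serveDevices()]. Tracks the spawned worker processes (one
#' per definition or per `share_process` group) and offers orderly
#' shutdown, the list of served URIs, and access to worker logs.
#'
#' @export ServerHandle
#' @exportClass ServerHandle
ServerHandle <- setRefClass("ServerHandle",
  fields = list(
    .groups = "list",     # each: list(host, port, defs, logPath, specPath)
    .stopped = "logical"
  ),
  methods = list(
    uris = function() {
      unlist(lapply(.groups, function(g)
        vapply(g$defs, definitionURI, "")))
    },
    stop = function() {
      if (isTRUE(.stopped)) return(invisible(NULL))
      for (g in .groups) {
        res <- tryCatch({
          con <- openWire(g$host, g$port, timeoutSeconds = 2)
          on.exit(try(close(con), silent = TRUE), add = TRUE)
          sendMsg(con, list(control = "shutdown_worker"))
          recvMsg(con, timeoutSeconds = 5)
        }, error = function(e) NULL)
      }
      .stopped <<- TRUE
      invisible(NULL)
    },
    # Simulate a worker crash (used to verify endpoint isolation).
    killWorker = function(port) {
      g <- Filter(function(g) g$port == port, .groups)
      if (!length(g)) vsError("connectionError", sprintf("no worker on port %d", port))
      con <- openWire(g[[1L]]$host, g[[1L]]$port, timeoutSeconds = 2)
      on.exit(try(close(con), silent = TRUE))
      sendMsg(con, list(control = "die"))
      invisible(NULL)
    },
    workerStats = function(port) {
      g <- Filter(function(g) g$port == port, .groups)
      if (!length(g)) vsError("connectionError", sprintf("no worker on port %d", port))
      con <- openWire(g[[1L]]$host, g[[1L]]$port, timeoutSeconds = 2)
      on.exit(try(close(con), silent = TRUE))
      sendMsg(con, list(control = "stats"))
      resp <- recvMsg(con, timeoutSeconds = 5)
      resp$value
    },
    workerLogs = function() {
      lapply(.groups, function(g)
        if (file.exists(g$logPath)) readLines(g$logPath, warn = FALSE)
        else character())
    },
    ports = function() vapply(.groups, function(g) g$port, 0L),
    show = function() {
      cat(sprintf("<device server> %d worker(s), %d device(s)%s\n",
                  length(.groups), length(uris()),
                  if (isTRUE(.stopped)) " (stopped)" else ""))
    }
  )
)

#' Publish devices at network endpoints
#'
#' Spawns one worker process per device definition (or per `share_process`
#' group), each serving its devices on the definition's port. Exactly one
#' device instance exists per definition. Workers are separate operating
#' system processes, so operations on devices in different workers proceed
#' concurrently without serialising on any shared interpreter-wide lock.
#' Controller children are auto-registered and arrive at clients as working
#' proxies.
#'
#' @param config a path to an INI configuration file (see
#'   [parseDeviceConfig()]) or a list of [DeviceDefinition-class] objects.
#' @param startupTimeout seconds to wait for every worker to come up.
#' @param lifetimeSeconds safety cap on worker lifetime; workers always
#'   stop earlier on [ServerHandle]$stop().
#' @return a [ServerHandle].
#' @examples
#' \dontrun{
#' defs <- list(deviceDefinition("cam", "spot_camera", port = 41001L),
#'              deviceDefinition("stage1", "stage", port = 41002L))
#' srv <- serveDevices(defs)
#' cam <- connectDevice("scope://127.0.0.1:41001/cam")
#' srv$stop()
#' }
#' @export
serveDevices <- function(config, startupTimeout = 30, lifetimeSeconds = 900) {
  defs <- if (is.character(config)) parseDeviceConfig(config) else config
  validateDefinitions(defs)
  groupKey <- vapply(defs, function(d)
    if (is.na(d@shareProcess)) paste0(".solo.", d@name) else d@shareProcess, "")
  groups <- split(defs, groupKey)

  handleGroups <- list()
  for (g in groups) {
    host <- g[[1L]]@host
    port <- g[[1L]]@port
    specPath <- tempfile(fileext = ".rds")
    statusPath <- tempfile(fileext = ".status")
    logPath <- tempfile(fileext = ".log")
    saveRDS(list(defs = g, host = host, port = port,
                 statusPath = statusPath,
                 lifetimeSeconds = lifetimeSeconds), specPath)
    rscript <- file.path(R.home("bin"), "Rscript")
    expr <- sprintf("virtuscope:::workerMain('%s')", specPath)
    system2(rscript, c("-e", shQuote(expr)), wait = FALSE,
            stdout = logPath, stderr = logPath)
    handleGroups[[length(handleGroups) + 1L]] <-
      list(host = host, port = port, defs = g, logPath = logPath,
           specPath = specPath, statusPath = statusPath)
  }

  handle <- ServerHandle$new(.groups = handleGroups, .stopped = FALSE)
  deadline <- Sys.time() + startupTimeout
  for (g in handleGroups) {
    repeat {
      if (file.exists(g$statusPath)) {
        status <- tryCatch(readLines(g$statusPath, warn = FALSE),
                           error = function(e) character())
        if (length(status) && startsWith(status[[1L]], "error")) {
          try(handle$stop(), silent = TRUE)
          vsError("startupError",
                  sprintf("worker for '%s' failed: %s",
                          g$defs[[1L]]@name, status[[1L]]))
        }
        if (length(status) && identical(status[[1L]], "ok")) break
      }
      if (Sys.time() > deadline) {
        try(handle$stop(), silent = TRUE)
        vsError("startupError",
                sprintf("worker for '%s' did not start within %gs",
                        g$defs[[1L]]@name, startupTimeout))
      }
      Sys.sleep(0.05)
    }
  }
  handle
}
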