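# Device-server worker process. One worker serves the devices of one
# definition (or of one share_process group) on one port, in its own R
# process — device operations in different workers proceed concurrently
# with no shared interpreter lock. The worker:
#   * constructs exactly one device instance per definition,
#   * auto-registers controller children under "<parent>.<child>",
#   * answers one request per client connection,
#   * pushes camera frames to registered data sinks only after the
#     triggering response has been written (asynchronous delivery),
#   * on a deviceFaultError, logs and recreates the instance from its
#     definition (same uri, volatile state reset to construction defaults).

workerLog <- function(state, event) {
  cat(sprintf("%s %s %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
              state$uriBase, event), file = stderr())
}

workerBuildDevices <- function(state) {
  state$registry <- new.env(parent = emptyenv())
  siblings <- list()
  for (def in state$defs) {
    dev <- createDevice(def@kind, def@params, name = def@name,
                        siblings = siblings)
    siblings[[def@name]] <- dev
    entry <- new.env(parent = emptyenv())
    entry$device <- dev
    entry$def <- def
    entry$reinitCount <- 0L
    entry$outbox <- list()
    entry$dropped <- 0L
    entry$sinkCon <- NULL
    assign(def@name, entry, envir = state$registry)
    workerLog(state, sprintf("registered %s kind=%s", def@name, def@kind))
    if (is(dev, "Controller")) workerRegisterChildren(state, def@name, dev)
  }
  invisible(NULL)
}

workerRegisterChildren <- function(state, parentName, controller) {
  kids <- controller$children()
  for (nm in names(kids)) {
    entry <- new.env(parent = emptyenv())
    entry$device <- kids[[nm]]
    entry$def <- NULL   # children are reinitialised through their parent
    entry$parent <- parentName
    entry$reinitCount <- 0L
    entry$outbox <- list(); entry$dropped <- 0L; entry$sinkCon <- NULL
    assign(paste0(parentName, ".", nm), entry, envir = state$registry)
    workerLog(state, sprintf("registered child %s.%s", parentName, nm))
  }
  invisible(NULL)
}

workerReinit <- function(state, targetName, entry) {
  def <- entry$def
  if (is.null(def)) {   # child: reinitialise through the parent definition
    parent <- get(entry$parent, envir = state$registry)
    workerReinit(state, entry$parent, parent)
    return(invisible(NULL))
  }
  siblings <- list()
  for (nm in ls(state$registry))
    siblings[[nm]] <- get(nm, envir = state$registry)$device
  entry$device <- createDevice(def@kind, def@params, name = def@name,
                               siblings = siblings)
  entry$reinitCount <- entry$reinitCount + 1L
  if (is(entry$device, "Controller"))
    workerRegisterChildren(state, def@name, entry$device)
  workerLog(state, sprintf("reinitialized %s (count=%d)", targetName,
                           entry$reinitCount))
  invisible(NULL)
}

workerEnqueueFrame <- function(entry, fr, state, targetName) {
  if (length(entry$outbox) >= 256L) {
    entry$outbox[[1L]] <- NULL
    entry$dropped <- entry$dropped + 1L
    workerLog(state, sprintf("%s dropped oldest frame (total dropped=%d)",
                             targetName, entry$dropped))
  }
  entry$outbox[[length(entry$outbox) + 1L]] <- fr
  invisible(NULL)
}

workerFlushSinks <- function(state) {
  for (nm in ls(state$registry)) {
    entry <- get(nm, envir = state$registry)
    if (is.null(entry$sinkCon) || !length(entry$outbox)) next
    while (length(entry$outbox)) {
      fr <- entry$outbox[[1L]]
      ok <- tryCatch({ serialize(fr, entry$sinkCon); flush(entry$sinkCon); TRUE },
                     error = function(e) FALSE)
      if (!ok) {
        workerLog(state, sprintf("%s sink write failed; buffering %d frame(s)",
                                 nm, length(entry$outbox)))
        break
      }
      entry$outbox[[1L]] <- NULL
    }
  }
  invisible(NULL)
}

workerHandle <- function(state, req, con) {
  if (!is.null(req$control)) {
    if (req$control == "describe") {
      names <- ls(state$registry)
      kinds <- vapply(names, function(nm)
        get(nm, envir = state$registry)$device$deviceKind(), "")
      sendMsg(con, list(ok = TRUE, value = list(devices = as.list(
        stats::setNames(kinds, names)))))
      return("continue")
    }
    if (req$control == "stats") {
      names <- ls(state$registry)
      reinits <- vapply(names, function(nm)
        get(nm, envir = state$registry)$reinitCount, 0L)
      dropped <- vapply(names, function(nm)
        get(nm, envir = state$registry)$dropped, 0L)
      sendMsg(con, list(ok = TRUE, value = list(
        reinits = as.list(stats::setNames(reinits, names)),
        dropped = as.list(stats::setNames(dropped, names)))))
      return("continue")
    }
    if (req$control == "shutdown_worker") {
      for (nm in ls(state$registry))
        try(get(nm, envir = state$registry)$device$shutdown(), silent = TRUE)
      sendMsg(con, list(ok = TRUE, value = NULL))
      workerLog(state, "worker shutdown requested")
      return("stop")
    }
    if (req$control == "die") {   # simulated worker crash: no response
      workerLog(state, "worker killed by control message")
      quit(save = "no", status = 0L)
    }
    sendMsg(con, list(ok = FALSE, category = "connectionError",
                      message = sprintf("unknown control '%s'", req$control)))
    return("continue")
  }

  entry <- if (!is.null(req$target) &&
               exists(req$target, envir = state$registry, inherits = FALSE))
    get(req$target, envir = state$registry) else NULL
  if (is.null(entry)) {
    sendMsg(con, list(ok = FALSE, category = "connectionError",
                      message = sprintf("no device '%s' at this endpoint",
                                        req$target)))
    return("continue")
  }

  if (identical(req$method, ".registerSink")) {
    if (!is(entry$device, "Camera")) {
      sendMsg(con, list(ok = FALSE, category = "registrationError",
                        message = "data clients can only be registered on cameras"))
      return("continue")
    }
    uri <- req$args[[1L]]
    parsed <- vsTry(parseURI(uri))
    if (!parsed$ok) {
      sendMsg(con, list(ok = FALSE, category = parsed$category,
                        message = parsed$message))
      return("continue")
    }
    newCon <- tryCatch(
      suppressWarnings(socketConnection(parsed$value$host, parsed$value$port,
                                        blocking = TRUE, open = "a+b",
                                        timeout = 10)),
      error = function(e) NULL)
    if (is.null(newCon)) {
      sendMsg(con, list(ok = FALSE, category = "registrationError",
                        message = sprintf("cannot reach data sink %s", uri)))
      return("continue")
    }
    if (!is.null(entry$sinkCon)) try(close(entry$sinkCon), silent = TRUE)
    entry$sinkCon <- newCon
    tgt <- req$target
    entry$device$setSinkFun(function(fr)
      workerEnqueueFrame(entry, fr, state, tgt))
    workerLog(state, sprintf("%s data client registered: %s", req$target, uri))
    sendMsg(con, list(ok = TRUE, value = NULL))
    return("continue")
  }

  res <- vsTry({
    m <- tryCatch(refMethod(entry$device, req$method), error = function(e)
      vsError("runtimeError",
              sprintf("device '%s' has no operation '%s'", req$target, req$method)))
    do.call(m, req$args)
  })
  if (res$ok) {
    register <- function(dev, suggested = NULL) {
      # children registered at init; find the existing name
      for (nm in ls(state$registry))
        if (identical(get(nm, envir = state$registry)$device, dev))
          return(sprintf("scope://%s:%d/%s", state$host, state$port, nm))
      nm <- paste0(req$target, ".", if (is.null(suggested)) "child" else suggested)
      entryC <- new.env(parent = emptyenv())
      entryC$device <- dev; entryC$def <- NULL; entryC$parent <- req$target
      entryC$reinitCount <- 0L; entryC$outbox <- list(); entryC$dropped <- 0L
      entryC$sinkCon <- NULL
      assign(nm, entryC, envir = state$registry)
      sprintf("scope://%s:%d/%s", state$host, state$port, nm)
    }
    sendMsg(con, list(ok = TRUE, value = encodeForWire(res$value, register)))
  } else {
    if (identical(res$category, "deviceFaultError")) {
      workerLog(state, sprintf("%s fault: %s", req$target, res$message))
      workerReinit(state, req$target, entry)
    }
    sendMsg(con, list(ok = FALSE, category = res$category,
                      message = res$message))
  }
  "continue"
}

# Entry point, run inside the spawned process:
#   Rscript -e "virtuscope:::workerMain('<spec.rds>')"
workerMain <- function(specPath) {
  spec <- readRDS(specPath)
  state <- new.env(parent = emptyenv())
  state$defs <- spec$defs
  state$host <- spec$host
  state$port <- spec$port
  state$uriBase <- sprintf("scope://%s:%d", spec$host, spec$port)
  status <- function(text) writeLines(text, spec$statusPath)

  built <- vsTry(workerBuildDevices(state))
  if (!built$ok) {
    status(sprintf("error: %s", built$message))
    quit(save = "no", status = 1L)
  }
  srv <- tryCatch(serverSocket(spec$port), error = function(e) NULL)
  if (is.null(srv)) {
    status(sprintf("error: port %d in use or unavailable", spec$port))
    quit(save = "no", status = 1L)
  }
  status("ok")
  workerLog(state, sprintf("serving %d device(s)", length(spec$defs)))
  deadline <- Sys.time() + spec$lifetimeSeconds
  repeat {
    if (Sys.time() > deadline) { workerLog(state, "lifetime reached"); break }
    ready <- tryCatch(socketSelect(list(srv), timeout = 0.5),
                      error = function(e) FALSE)
    if (!isTRUE(ready[[1L]])) next
    con <- tryCatch(socketAccept(srv, blocking = TRUE, open = "a+b"),
                    error = function(e) NULL)
    if (is.null(con)) next
    req <- tryCatch(unserialize(con), error = function(e) NULL)
    verdict <- "continue"
    if (!is.null(req))
      verdict <- tryCatch(workerHandle(state, req, con), error = function(e) {
        workerLog(state, sprintf("internal error: %s", conditionMessage(e)))
        "continue"
      })
    # flush after responding: the triggering call has already returned
    workerFlushSinks(state)
    try(close(con), silent = TRUE)
    if (identical(verdict, "stop")) break
  }
  close(srv)
  invisible(NULL)
}
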