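#' DeviceDefinition: one served device
#'
#' @slot name device name (the INI section header).
#' @slot kind registered device-kind identifier.
#' @slot host,port endpoint address.
#' @slot shareProcess optional group label; definitions sharing a label are
#'   served from one worker process (and must share one port).
#' @slot params named list of construction parameters.
#' @export
setClass("DeviceDefinition",
  representation(name = "character", kind = "character", host = "character",
                 port = "integer", shareProcess = "character",
                 params = "list"))

#' @rdname DeviceDefinition-class
#' @param name,kind,host,port,shareProcess,params see slots.
#' @return a [DeviceDefinition-class].
#' @export
deviceDefinition <- function(name, kind, host = "127.0.0.1", port,
                             shareProcess = NA_character_, params = list()) {
  new("DeviceDefinition", name = name, kind = kind, host = host,
      port = as.integer(port), shareProcess = as.character(shareProcess),
      params = params)
}

#' @rdname DeviceDefinition-class
#' @param x a [DeviceDefinition-class].
#' @export
definitionURI <- function(x) sprintf("scope://%s:%d/%s", x@host, x@port, x@name)

setMethod("show", "DeviceDefinition", function(object) {
  cat(sprintf("<device definition> %s: kind=%s at %s\n", object@name,
              object@kind, definitionURI(object)))
})

#' Parse a device-server configuration file
#'
#' INI-style: one `[name]` section per device with keys `kind`, `host`,
#' `port`, optional `share_process`, and `param.<name>=<value>` entries
#' passed to the device constructor.
#'
#' @param path configuration file.
#' @return list of [DeviceDefinition-class]; duplicate URIs or malformed
#'   sections signal a `startupError` naming the definition.
#' @export
parseDeviceConfig <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, ";")]
  defs <- list()
  current <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(invisible(NULL))
    if (is.null(cur$kind))
      vsError("startupError", sprintf("definition '%s' has no kind", cur$name))
    if (is.null(cur$port))
      vsError("startupError", sprintf("definition '%s' has no port", cur$name))
    defs[[length(defs) + 1L]] <<- deviceDefinition(
      name = cur$name, kind = cur$kind,
      host = if (is.null(cur$host)) "127.0.0.1" else cur$host,
      port = as.integer(cur$port),
      shareProcess = if (is.null(cur$share)) NA_character_ else cur$share,
      params = cur$params)
    invisible(NULL)
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      flush(current)
      current <- list(name = sub("^\\[(.+)\\]$", "\\1", ln), params = list())
    } else {
      if (is.null(current))
        vsError("startupError", sprintf("key outside any section: '%s'", ln))
      kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1L]]
      if (length(kv) != 3L)
        vsError("startupError", sprintf("malformed line: '%s'", ln))
      key <- trimws(kv[[2L]]); value <- trimws(kv[[3L]])
      if (startsWith(key, "param.")) {
        current$params[[sub("^param\\.", "", key)]] <- value
      } else if (key == "kind") current$kind <- value
      else if (key == "host") current$host <- value
      else if (key == "port") current$port <- value
      else if (key == "share_process") current$share <- value
      else vsError("startupError",
                   sprintf("unknown key '%s' in definition '%s'", key, current$name))
    }
  }
  flush(current)
  validateDefinitions(defs)
  defs
}

validateDefinitions <- function(defs) {
  uris <- vapply(defs, definitionURI, "")
  if (anyDuplicated(uris))
    vsError("startupError",
            sprintf("duplicate uri '%s' in configuration", uris[duplicated(uris)][[1L]]))
  groups <- split(defs, vapply(defs, function(d)
    if (is.na(d@shareProcess)) paste0(".solo.", d@name) else d@shareProcess, ""))
  for (g in groups) {
    ports <- unique(vapply(g, function(d) d@port, 0L))
    if (length(ports) != 1L)
      vsError("startupError",
              sprintf("share_process group '%s' spans multiple ports",
                      g[[1L]]@shareProcess))
  }
  invisible(defs)
}

#' Parse a device URI
#'
#' Canonical form `scope://host:port/name`; parsed leniently (the scheme is
#' optional).
#'
#' @param uri uri string.
#' @return list with `host`, `port`, `name`.
#' @export
parseURI <- function(uri) {
  m <- regmatches(uri, regexec("^(?:[A-Za-z0-9+.-]+://)?([^:/]+):([0-9]+)/(.+)$", uri))[[1L]]
  if (length(m) != 4L)
    vsError("connectionError", sprintf("cannot parse uri '%s'", uri))
  list(host = m[[2L]], port = as.integer(m[[3L]]), name = m[[4L]])
}
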