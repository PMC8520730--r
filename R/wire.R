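# Wire protocol: one R object per message over a blocking TCP socket,
# framed by R's native serialization. A request is
#   list(target = <device name>, method = <string>, args = <list>)
# or a control message list(control = <string>, ...). A response is
#   list(ok = TRUE, value = <encoded>) |
#   list(ok = FALSE, category = <error category>, message = <string>).
# Device objects inside results are replaced by child references
# (list(.childRef = TRUE, uri = ...)) server-side and re-materialised as
# proxies client-side.

# Look up a reference-class method by name computed at run time ($ does
# not evaluate its right-hand side).
refMethod <- function(obj, name) eval(call("$", obj, name))

sendMsg <- function(con, obj) {
  serialize(obj, con)
  flush(con)
  invisible(NULL)
}

recvMsg <- function(con, timeoutSeconds = NULL) {
  if (!is.null(timeoutSeconds)) {
    ready <- socketSelect(list(con), timeout = timeoutSeconds)
    if (!isTRUE(ready[[1L]]))
      vsError("connectionError", "timed out waiting for a reply")
  }
  tryCatch(unserialize(con),
           error = function(e)
             vsError("connectionError",
                     sprintf("connection closed: %s", conditionMessage(e))))
}

openWire <- function(host, port, timeoutSeconds = 5) {
  con <- tryCatch(
    suppressWarnings(socketConnection(host, port, blocking = TRUE,
                                      open = "a+b", timeout = 60)),
    error = function(e)
      vsError("connectionError",
              sprintf("cannot connect to %s:%d: %s", host, port,
                      conditionMessage(e))))
  con
}

# Replace Device objects in a result (possibly nested one level in lists)
# by child references the client can proxy. `register` is a callback
# (device, suggestedName) -> uri.
encodeForWire <- function(value, register) {
  if (is(value, "Device")) {
    uri <- register(value)
    return(list(.childRef = TRUE, uri = uri))
  }
  if (is.list(value) && !isS4(value)) {
    nm <- names(value)
    enc <- lapply(seq_along(value), function(i) {
      v <- value[[i]]
      if (is(v, "Device"))
        list(.childRef = TRUE, uri = register(v, if (!is.null(nm)) nm[[i]]))
      else v
    })
    names(enc) <- nm
    return(enc)
  }
  value
}

# Client-side: turn child references back into live proxies.
decodeFromWire <- function(value) {
  isRef <- function(v) is.list(v) && isTRUE(v$.childRef)
  if (isRef(value)) return(connectDevice(value$uri))
  if (is.list(value) && !isS4(value)) {
    return(lapply(value, function(v) if (isRef(v)) connectDevice(v$uri) else v))
  }
  value
}
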