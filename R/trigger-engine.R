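#' ExperimentTemplate: a precompiled, timed schedule of line actions
#'
#' Experiments are prepared as templates — ordered rows of
#' `(tick, line, action)` with `action` one of `pulse`, `raise`, `lower` —
#' and loaded onto a timing device that triggers all other devices. The
#' emulated timing device here defines correctness on a *virtual* clock:
#' one tick lasts `tickSeconds` of virtual time and the engine never
#' sleeps, so identical inputs always give identical logs regardless of
#' wall-clock scheduling (operating-system timing carries jitter of tens of
#' milliseconds, which is exactly what a dedicated timing device avoids).
#'
#' Rows are sorted by tick with ties broken by row order; a `pulse` is an
#' instantaneous raise+lower within its tick.
#'
#' @slot tickSeconds duration of one virtual tick, in seconds.
#' @slot actions data.frame with columns `tick`, `line`, `action`.
#' @export
setClass("ExperimentTemplate",
  representation(tickSeconds = "numeric", actions = "data.frame"),
  validity = function(object) {
    if (object@tickSeconds <= 0) return("tickSeconds must be > 0")
    a <- object@actions
    if (nrow(a) && is.unsorted(a$tick)) return("actions must be sorted by tick")
    TRUE
  }
)

setMethod("show", "ExperimentTemplate", function(object) {
  cat(sprintf("<experiment template> %d action(s), tick = %g s\n",
              nrow(object@actions), object@tickSeconds))
})

#' @rdname compileTemplate
#' @param x an [ExperimentTemplate-class].
#' @export
templateActions <- function(x) x@actions
#' @rdname compileTemplate
#' @export
templateTickSeconds <- function(x) x@tickSeconds

#' Compile experiment rows into a validated template
#'
#' Sorts rows by tick (stable within a tick, preserving row order),
#' validates actions and simulates line levels to reject redundant
#' transitions: raising a line that is already high, or lowering one that
#' is already low (including via a `pulse` on a high line), is a
#' compilation error naming the offending row. All lines start low.
#'
#' @param rows data.frame with columns `tick` (non-negative integer),
#'   `line` (non-negative integer) and `action`
#'   (`"pulse"`, `"raise"` or `"lower"`).
#' @param tickSeconds duration of one virtual tick in seconds.
#' @return an [ExperimentTemplate-class].
#' @examples
#' compileTemplate(data.frame(tick = c(0, 5, 5),
#'                            line = c(0, 1, 0),
#'                            action = c("pulse", "raise", "pulse")),
#'                 tickSeconds = 0.001)
#' @export
compileTemplate <- function(rows, tickSeconds = 0.001) {
  if (is.null(rows) || nrow(rows) == 0L) {
    empty <- data.frame(tick = integer(), line = integer(),
                        action = character(), stringsAsFactors = FALSE)
    return(new("ExperimentTemplate", tickSeconds = as.numeric(tickSeconds),
               actions = empty))
  }
  need <- c("tick", "line", "action")
  if (!all(need %in% names(rows)))
    vsError("compilationError", "rows need columns tick, line, action")
  rows <- rows[, need]
  rows$action <- as.character(rows$action)
  for (i in seq_len(nrow(rows))) {
    if (is.na(rows$tick[[i]]) || rows$tick[[i]] < 0 ||
        rows$tick[[i]] != round(rows$tick[[i]]))
      vsError("compilationError",
              sprintf("row %d: tick must be a non-negative integer", i))
    if (is.na(rows$line[[i]]) || rows$line[[i]] < 0 ||
        rows$line[[i]] != round(rows$line[[i]]))
      vsError("compilationError",
              sprintf("row %d: line must be a non-negative integer", i))
    if (!(rows$action[[i]] %in% c("pulse", "raise", "lower")))
      vsError("compilationError",
              sprintf("row %d: unknown action '%s'", i, rows$action[[i]]))
  }
  rows$.row <- seq_len(nrow(rows))
  ord <- order(rows$tick)             # stable: preserves row order within tick
  rows <- rows[ord, ]
  level <- new.env(parent = emptyenv())
  lineLevel <- function(line) {
    v <- get0(as.character(line), envir = level, inherits = FALSE)
    if (is.null(v)) FALSE else v
  }
  for (i in seq_len(nrow(rows))) {
    ln <- rows$line[[i]]; act <- rows$action[[i]]; orig <- rows$.row[[i]]
    high <- lineLevel(ln)
    if (act == "raise") {
      if (high)
        vsError("compilationError",
                sprintf("row %d: raise on line %d which is already high", orig, ln))
      assign(as.character(ln), TRUE, envir = level)
    } else if (act == "lower") {
      if (!high)
        vsError("compilationError",
                sprintf("row %d: lower on line %d which is already low", orig, ln))
      assign(as.character(ln), FALSE, envir = level)
    } else if (high) {
      vsError("compilationError",
              sprintf("row %d: pulse on line %d which is held high", orig, ln))
    }
  }
  rows$.row <- NULL
  rows$tick <- as.integer(rows$tick)
  rows$line <- as.integer(rows$line)
  rownames(rows) <- NULL
  new("ExperimentTemplate", tickSeconds = as.numeric(tickSeconds),
      actions = rows)
}

#' EventLog: executed actions and their effects, in order
#'
#' @slot entries data.frame with columns `tick`, `line`, `action`,
#'   `target`, `effect`. Ticks are non-decreasing; within a tick, template
#'   row order is preserved.
#' @export
setClass("EventLog",
  representation(entries = "data.frame"),
  validity = function(object) {
    e <- object@entries
    if (nrow(e) && is.unsorted(e$tick)) return("entry ticks must be non-decreasing")
    TRUE
  }
)

setMethod("show", "EventLog", function(object) {
  cat(sprintf("<event log> %d entr%s\n", nrow(object@entries),
              if (nrow(object@entries) == 1L) "y" else "ies"))
})

#' @rdname runTemplate
#' @param x an [EventLog-class].
#' @export
logEntries <- function(x) x@entries

#' Map digital lines to trigger-target devices
#'
#' @param ... named arguments: `` `0` = camera, `1` = light ``, i.e. line
#'   index (as name) to device.
#' @return a line mapping usable by [runTemplate()].
#' @export
lineMapping <- function(...) {
  m <- list(...)
  if (length(m) && (is.null(names(m)) || any(!nzchar(names(m)))))
    vsError("configurationError", "every line in a mapping must be named")
  m
}

# Validate that a target's TriggerConfig is compatible with the actions the
# template performs on its line.
checkMappingAgainstTemplate <- function(template, mapping) {
  a <- template@actions
  for (lineName in names(mapping)) {
    target <- mapping[[lineName]]
    cfg <- target$getTrigger()
    ln <- as.integer(lineName)
    acts <- a$action[a$line == ln]
    if (!length(acts)) next
    if (is.null(cfg))
      vsError("configurationError",
              sprintf("device on line %d has no trigger configuration", ln))
    if (cfg@triggerType == "software")
      vsError("configurationError",
              sprintf("device on line %d is software-configured but mapped to a hardware line", ln))
    if (any(acts == "pulse") && isLevelType(cfg) )
      vsError("configurationError",
              sprintf("pulse on line %d but its device is level-configured", ln))
    if (any(acts %in% c("raise", "lower")) && !isLevelType(cfg))
      vsError("configurationError",
              sprintf("raise/lower on line %d but its device is edge-configured", ln))
  }
  invisible(NULL)
}

#' Execute a template against mapped devices on the virtual clock
#'
#' Walks the template rows in order, maintaining each line's level, and
#' activates the mapped target devices: a `pulse` on an edge-configured
#' target causes one activation at that tick; `raise`/`lower` around a
#' level-configured bulb target produce one activation spanning the held
#' interval, with duration `(lower tick - raise tick) * tickSeconds` —
#' e.g. a camera exposure or light emission exactly as long as the line is
#' held. Disabled devices do not act (logged as ignored). The run is a pure
#' function of `(template, mapping, device states)`.
#'
#' An optional `moves` plan (from [zstackTemplate()]) interleaves stage and
#' filter-wheel motion: at each tick, moves execute before line actions, in
#' plan order.
#'
#' @param template an [ExperimentTemplate-class].
#' @param mapping a [lineMapping()] of line index to device.
#' @param moves optional data.frame with columns `tick`, `device`
#'   (`"stage"` or `"wheel"`), `axis`, `value`.
#' @param stage,wheel devices addressed by the `moves` plan.
#' @return an [EventLog-class].
#' @export
runTemplate <- function(template, mapping, moves = NULL, stage = NULL,
                        wheel = NULL) {
  checkMappingAgainstTemplate(template, mapping)
  a <- template@actions
  ts <- template@tickSeconds
  entries <- list()
  addEntry <- function(tick, line, action, target, effect) {
    entries[[length(entries) + 1L]] <<- data.frame(
      tick = tick, line = line, action = action, target = target,
      effect = effect, stringsAsFactors = FALSE)
  }
  levels <- new.env(parent = emptyenv())
  openSince <- new.env(parent = emptyenv())  # line -> tick activation opened
  movesLeft <- if (!is.null(moves) && nrow(moves)) moves else NULL
  applyMovesUpTo <- function(tick) {
    if (is.null(movesLeft)) return(invisible(NULL))
    while (!is.null(movesLeft) && nrow(movesLeft) &&
           movesLeft$tick[[1L]] <= tick) {
      mv <- movesLeft[1L, ]
      movesLeft <<- if (nrow(movesLeft) > 1L) movesLeft[-1L, ] else NULL
      if (mv$device == "stage") {
        if (is.null(stage))
          vsError("runtimeError",
                  sprintf("tick %d: move plan addresses a stage but none was given", mv$tick))
        stage$moveTo(stats::setNames(mv$value, mv$axis))
        addEntry(mv$tick, NA_integer_, "move", "stage",
                 sprintf("%s=%g", mv$axis, mv$value))
      } else if (mv$device == "wheel") {
        if (is.null(wheel))
          vsError("runtimeError",
                  sprintf("tick %d: move plan addresses a wheel but none was given", mv$tick))
        wheel$setFilterPosition(mv$value)
        addEntry(mv$tick, NA_integer_, "move", "wheel",
                 sprintf("position=%d", as.integer(mv$value)))
      }
    }
    invisible(NULL)
  }

  edgeEffect <- function(target, tick, transition) {
    cfg <- target$getTrigger()
    if (!edgeMatches(cfg, transition)) return(NULL)
    if (!identical(target$deviceState(), "enabled")) return("ignored (disabled)")
    target$activateOnce(tick = tick, tickSeconds = ts)
    "activated"
  }

  for (i in seq_len(nrow(a))) {
    tick <- a$tick[[i]]; ln <- a$line[[i]]; act <- a$action[[i]]
    applyMovesUpTo(tick)
    key <- as.character(ln)
    target <- mapping[[key]]
    if (is.null(target))
      vsError("runtimeError",
              sprintf("tick %d: action on unmapped line %d", tick, ln))
    cfg <- target$getTrigger()
    if (act == "pulse") {
      # instantaneous raise+lower: rising then falling edge within the tick
      eff <- c(edgeEffect(target, tick, "rising"),
               edgeEffect(target, tick, "falling"))
      addEntry(tick, ln, "pulse", target$deviceName(),
               if (is.null(eff)) "no effect" else paste(eff, collapse = "+"))
    } else if (act == "raise") {
      assign(key, TRUE, envir = levels)
      eff <- "line high"
      if (isLevelType(cfg)) {
        enabled <- identical(target$deviceState(), "enabled")
        if (cfg@triggerType == "level_high") {
          if (enabled) {
            target$activateLevelStart(tick)
            assign(key, tick, envir = openSince)
            eff <- "activation start"
          } else eff <- "ignored (disabled)"
        } else {  # level_low: raising ends the active-low interval
          since <- get0(key, envir = openSince, inherits = FALSE)
          if (enabled && !is.null(since)) {
            dur <- (tick - since) * ts
            rm(list = key, envir = openSince)
            target$activateLevelEnd(tick, dur)
            eff <- sprintf("activation end, duration=%g s", dur)
          }
        }
      }
      addEntry(tick, ln, "raise", target$deviceName(), eff)
    } else if (act == "lower") {
      assign(key, FALSE, envir = levels)
      eff <- "line low"
      if (isLevelType(cfg)) {
        enabled <- identical(target$deviceState(), "enabled")
        if (cfg@triggerType == "level_high") {
          since <- get0(key, envir = openSince, inherits = FALSE)
          if (enabled && !is.null(since)) {
            dur <- (tick - since) * ts
            rm(list = key, envir = openSince)
            target$activateLevelEnd(tick, dur)
            eff <- sprintf("activation end, duration=%g s", dur)
          }
        } else {
          if (enabled) {
            target$activateLevelStart(tick)
            assign(key, tick, envir = openSince)
            eff <- "activation start"
          } else eff <- "ignored (disabled)"
        }
      }
      addEntry(tick, ln, "lower", target$deviceName(), eff)
    }
  }
  applyMovesUpTo(Inf)
  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(tick = integer(), line = integer(), action = character(),
               target = character(), effect = character(),
               stringsAsFactors = FALSE)
  new("EventLog", entries = entries)
}

#' Build a z-stack / multichannel experiment
#'
#' For each z position and each channel (channel-major within z): move the
#' stage and wheel, wait `settleTicks`, raise the light line, pulse the
#' camera line in the same tick (light listed first, so at equal ticks the
#' light leads), and lower the light after `exposureTicks`. Produces
#' exactly `length(zPositions) * length(channels)` camera pulses.
#'
#' @param zPositions numeric z targets (stage units).
#' @param channels integer filter-wheel positions; or a single count `n`
#'   meaning channels `0:(n-1)`.
#' @param settleTicks ticks to wait after motion before exposing.
#' @param exposureTicks ticks the light line is held high per exposure.
#' @param cameraLine,lightLine digital line indices.
#' @param tickSeconds virtual tick duration in seconds.
#' @return list with `template` ([ExperimentTemplate-class]) and `moves`
#'   (data.frame for [runTemplate()]).
#' @export
zstackTemplate <- function(zPositions, channels, settleTicks = 2L,
                           exposureTicks = 10L, cameraLine = 0L,
                           lightLine = 1L, tickSeconds = 0.001) {
  rows <- list(); moves <- list()
  tick <- 0L
  for (z in zPositions) {
    for (ch in channels) {
      moves[[length(moves) + 1L]] <- data.frame(
        tick = tick, device = "stage", axis = "z", value = z,
        stringsAsFactors = FALSE)
      moves[[length(moves) + 1L]] <- data.frame(
        tick = tick, device = "wheel", axis = NA_character_, value = ch,
        stringsAsFactors = FALSE)
      tick <- tick + as.integer(settleTicks)
      rows[[length(rows) + 1L]] <- data.frame(
        tick = tick, line = lightLine, action = "raise", stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        tick = tick, line = cameraLine, action = "pulse", stringsAsFactors = FALSE)
      tick <- tick + as.integer(exposureTicks)
      rows[[length(rows) + 1L]] <- data.frame(
        tick = tick, line = lightLine, action = "lower", stringsAsFactors = FALSE)
      tick <- tick + 1L
    }
  }
  rows <- if (length(rows)) do.call(rbind, rows) else NULL
  moves <- if (length(moves)) do.call(rbind, moves) else
    data.frame(tick = integer(), device = character(), axis = character(),
               value = numeric(), stringsAsFactors = FALSE)
  list(template = compileTemplate(rows, tickSeconds = tickSeconds),
       moves = moves)
}
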