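#' Read and write experiment templates as plain text
#'
#' The on-disk dialect is a header line `tick_seconds=<float>` followed by
#' one tab-separated row per action: `tick<TAB>line<TAB>action`. Event logs
#' are written in the same dialect with two extra columns (`target`,
#' `effect`).
#'
#' @param path file path.
#' @return `readTemplate()` returns an [ExperimentTemplate-class];
#'   the writers return `path` invisibly.
#' @export
readTemplate <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !grepl("^tick_seconds=", lines[[1L]]))
    vsError("ioError", "template file must start with tick_seconds=<float>")
  ts <- as.numeric(sub("^tick_seconds=", "", lines[[1L]]))
  body <- lines[-1L]
  if (!length(body)) return(compileTemplate(NULL, tickSeconds = ts))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    vsError("ioError", sprintf("malformed template row %d", bad[[1L]]))
  rows <- data.frame(
    tick = as.numeric(vapply(parts, `[[`, "", 1L)),
    line = as.numeric(vapply(parts, `[[`, "", 2L)),
    action = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  compileTemplate(rows, tickSeconds = ts)
}

#' @rdname readTemplate
#' @param template an [ExperimentTemplate-class].
#' @export
writeTemplate <- function(template, path) {
  a <- template@actions
  lines <- c(sprintf("tick_seconds=%s", format(template@tickSeconds, digits = 15)),
             sprintf("%d\t%d\t%s", a$tick, a$line, a$action))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname readTemplate
#' @param log an [EventLog-class].
#' @param tickSeconds tick duration recorded in the header.
#' @export
writeEventLog <- function(log, path, tickSeconds = NA_real_) {
  e <- log@entries
  lines <- c(sprintf("tick_seconds=%s", format(tickSeconds, digits = 15)),
             sprintf("%s\t%s\t%s\t%s\t%s",
                     ifelse(is.na(e$tick), "-", e$tick),
                     ifelse(is.na(e$line), "-", e$line),
                     e$action, e$target, e$effect))
  writeLines(lines, path)
  invisible(path)
}
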