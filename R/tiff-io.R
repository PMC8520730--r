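#' Write frames to a multi-page TIFF
#'
#' Pixels are written as 16-bit grayscale, one page per frame. Because the
#' available TIFF writer does not emit per-page description tags, page
#' metadata (z position, channel, exposure) is written alongside as a
#' tab-separated sidecar `<path>.meta.tsv` with one row per page.
#'
#' @param frames list of [Frame-class] objects (or integer matrices).
#' @param path output TIFF path.
#' @param metadata optional data.frame with one row per page (columns such
#'   as `z`, `channel`, `exposure`); written to the sidecar.
#' @return `path`, invisibly.
#' @export
writeFramesTIFF <- function(frames, path, metadata = NULL) {
  if (!length(frames)) vsError("ioError", "no frames to write")
  mats <- lapply(frames, function(fr) {
    px <- if (is(fr, "Frame")) fr@pixels else fr
    px / 65535
  })
  ok <- tryCatch({ tiff::writeTIFF(mats, path, bits.per.sample = 16L,
                                   compression = "none"); TRUE },
                 error = function(e) FALSE)
  if (!ok) vsError("ioError", sprintf("cannot write TIFF at '%s'", path))
  if (!is.null(metadata)) {
    meta <- cbind(page = seq_along(frames) - 1L, metadata)
    utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read frames back from a multi-page TIFF
#'
#' @param path TIFF path.
#' @return list of integer pixel matrices in [0, 65535].
#' @export
readFramesTIFF <- function(path) {
  if (!file.exists(path)) vsError("ioError", sprintf("no file at '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) clipU16(p * 65535))
}

#' Load a virtual sample from image files
#'
#' Accepts one multi-page TIFF (one page per channel) or several
#' single-image files (TIFF or PNG, one per channel) with equal shapes.
#'
#' @param paths one or more image paths.
#' @param unitsPerPixel stage units per mosaic pixel.
#' @param background pad intensity for out-of-bounds reads.
#' @return a [VirtualSample-class].
#' @export
readVirtualSample <- function(paths, unitsPerPixel = 1, background = 0) {
  readOne <- function(p) {
    ext <- tolower(tools::file_ext(p))
    if (ext == "png") {
      if (!requireNamespace("png", quietly = TRUE))
        vsError("ioError", "reading PNG requires the 'png' package")
      img <- png::readPNG(p)
      if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel
      list(clipU16(img * 65535))
    } else {
      pages <- tiff::readTIFF(p, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      lapply(pages, function(x) {
        if (length(dim(x)) == 3L) x <- x[, , 1L]
        clipU16(x * 65535)
      })
    }
  }
  planes <- unlist(lapply(paths, readOne), recursive = FALSE)
  shapes <- vapply(planes, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    vsError("ioError", "all channel images must share one shape")
  virtualSample(planes, unitsPerPixel = unitsPerPixel, background = background)
}
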