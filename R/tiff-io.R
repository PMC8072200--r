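# Multi-page TIFF I/O for stacks: 32-bit float pages, plane-major
# (frame-minor for raw SIM) page order. Stack geometry that TIFF tags cannot
# carry portably (plane/frame counts, spacings) is written to a JSON sidecar
# ("<file>.json") next to the image.

sidecarPath <- function(path) paste0(path, ".json")

#' Write a stack as multi-page 32-bit float TIFF
#'
#' [SIMStack-class] pages are ordered plane-major, frame-minor (7 pages per
#' plane); [VolumeStack-class] pages are the z-planes. Geometry metadata is
#' stored in a JSON sidecar next to the file.
#'
#' @param stack a [SIMStack-class] or [VolumeStack-class].
#' @param path output TIFF path.
#' @return the path, invisibly
#' @export
writeTiffStack <- function(stack, path) {
  if (is(stack, "SIMStack")) {
    d <- dim(stack@data)
    pages <- vector("list", d[1] * d[2])
    for (k in seq_len(d[1])) for (f in seq_len(d[2]))
      pages[[(k - 1L) * d[2] + f]] <- stack@data[k, f, , ]
    meta <- list(kind = "sim", nPlanes = d[1], nFrames = d[2],
      ny = d[3], nx = d[4], units = stack@units,
      samplePixelNm = samplePixel(stack@config), dzNm = stack@config@dz)
  } else if (is(stack, "VolumeStack")) {
    d <- dim(stack@data)
    pages <- lapply(seq_len(d[1]), function(k) stack@data[k, , ])
    meta <- list(kind = "volume", nPlanes = d[1], ny = d[2], nx = d[3],
      spacingNm = stack@spacing)
  } else stop("stack must be a SIMStack or VolumeStack")
  # pages are stored scaled to [0, 1]; the scale is recorded in the sidecar
  mx <- max(vapply(pages, max, numeric(1)))
  scale <- if (mx > 0) mx else 1
  meta$scale <- scale
  tiff::writeTIFF(lapply(pages, function(pg) pg / scale), path,
    bits.per.sample = 32L, compression = "none", reduce = FALSE)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}

#' Read a stack written by [writeTiffStack()]
#'
#' @param path TIFF path (the JSON sidecar must sit next to it).
#' @param config optional [OpticsConfig-class] to attach to a SIM stack; a
#'   default config is constructed from the sidecar geometry otherwise.
#' @return a [SIMStack-class] or [VolumeStack-class], per the sidecar
#' @export
readTiffStack <- function(path, config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(sidecarPath(path)))
    stop("missing geometry sidecar: ", sidecarPath(path))
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(pg) pg * meta$scale)
  if (meta$kind == "sim") {
    d <- c(meta$nPlanes, meta$nFrames, meta$ny, meta$nx)
    arr <- array(0, d)
    for (k in seq_len(d[1])) for (f in seq_len(d[2]))
      arr[k, f, , ] <- pages[[(k - 1L) * d[2] + f]]
    if (is.null(config)) stop("a SIMStack read requires its OpticsConfig")
    new("SIMStack", data = arr, config = config, units = meta$units)
  } else {
    d <- c(meta$nPlanes, meta$ny, meta$nx)
    arr <- array(0, d)
    for (k in seq_len(d[1])) arr[k, , ] <- pages[[k]]
    new("VolumeStack", data = arr, spacing = meta$spacingNm)
  }
}
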