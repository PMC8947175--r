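#' Three-channel field of view
#'
#' A `channel_stack` holds the three co-registered 2-D intensity images of
#' one field -- dsDNA, histone H2B and Hsp60 -- together with the physical
#' pixel size. All downstream steps (calibration, subtraction, detection)
#' consume this type only.
#'
#' Intensities are stored as base-R numeric matrices; integer input is
#' promoted on construction (subtraction produces negative intermediates
#' that integer storage cannot hold). The original storage class is kept in
#' `dtype` so that TIFF round trips of integer data are bit-exact.
#'
#' @param dsdna,h2b,hsp60 numeric matrices of identical dimension with
#'   finite, non-negative values (arbitrary intensity units).
#' @param pixel_size_um positive scalar, physical edge length of one pixel
#'   in micrometres. Area filters in um^2 are meaningless without it, so it
#'   is mandatory.
#' @param image_id character scalar identifying the field.
#' @param dtype storage class of the source data: `"float"`, `"uint8"` or
#'   `"uint16"`. Used only to restore exact integer values on file round
#'   trips.
#' @return An object of class `channel_stack`.
#' @seealso [read_stack()], [write_stack()], [render_scene()]
#' @examples
#' s <- channel_stack(matrix(0, 8, 8), matrix(0, 8, 8), matrix(0, 8, 8),
#'                    pixel_size_um = 0.31)
#' s
#' @export
channel_stack <- function(dsdna, h2b, hsp60, pixel_size_um,
                          image_id = "image",
                          dtype = c("float", "uint8", "uint16")) {
  dtype <- match.arg(dtype)
  chans <- list(dsdna = dsdna, h2b = h2b, hsp60 = hsp60)
  chans <- lapply(chans, function(m) {
    if (!is.matrix(m) || !is.numeric(m))
      stop("channels must be numeric matrices", call. = FALSE)
    storage.mode(m) <- "double"
    m
  })
  d <- dim(chans$dsdna)
  if (!identical(dim(chans$h2b), d) || !identical(dim(chans$hsp60), d))
    stop("all three channels must have identical dimensions", call. = FALSE)
  for (nm in names(chans)) {
    v <- chans[[nm]]
    if (anyNA(v) || any(!is.finite(v)))
      stop("channel '", nm, "' contains non-finite values", call. = FALSE)
    if (any(v < 0))
      stop("channel '", nm, "' contains negative intensities", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar", call. = FALSE)
  structure(
    list(dsdna = chans$dsdna, h2b = chans$h2b, hsp60 = chans$hsp60,
         pixel_size_um = as.numeric(pixel_size_um),
         image_id = as.character(image_id), dtype = dtype),
    class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$dsdna)
  cat("<channel_stack> ", x$image_id, "\n", sep = "")
  cat(sprintf("  %d x %d px, %.4g um/px (%.1f x %.1f um)\n",
              d[1], d[2], x$pixel_size_um,
              d[1] * x$pixel_size_um, d[2] * x$pixel_size_um))
  for (nm in c("dsdna", "h2b", "hsp60"))
    cat(sprintf("  %-6s range [%.4g, %.4g]\n", nm,
                min(x[[nm]]), max(x[[nm]])))
  invisible(x)
}

#' Channel-role map for multi-channel files
#'
#' Maps the biological roles dsDNA / histone H2B / Hsp60 onto channel
#' indices of a TIFF file, optionally overriding the pixel size recorded in
#' the file. Indices are 1-based.
#'
#' @param dsdna,h2b,hsp60 distinct positive channel indices.
#' @param pixel_size_um optional positive scalar overriding any pixel size
#'   found in file metadata (highest precedence).
#' @return An object of class `channel_map`.
#' @examples
#' channel_map(dsdna = 2, h2b = 1, hsp60 = 3)
#' @export
channel_map <- function(dsdna = 1, h2b = 2, hsp60 = 3, pixel_size_um = NULL) {
  idx <- c(dsdna = dsdna, h2b = h2b, hsp60 = hsp60)
  if (any(idx != round(idx)) || any(idx < 1))
    stop("channel indices must be positive integers", call. = FALSE)
  if (anyDuplicated(idx))
    stop("channel indices must be distinct", call. = FALSE)
  if (!is.null(pixel_size_um) &&
      (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
       pixel_size_um <= 0))
    stop("pixel_size_um override must be a positive scalar", call. = FALSE)
  structure(list(dsdna = as.integer(dsdna), h2b = as.integer(h2b),
                 hsp60 = as.integer(hsp60),
                 pixel_size_um = pixel_size_um),
            class = "channel_map")
}

#' Maximum-intensity projection
#'
#' Collapses a list of 2-D planes (a z-stack of one channel) to a single
#' plane by pixelwise maximum. Convenience for preparing 2-D input; the
#' analysis itself is strictly 2-D.
#'
#' @param planes list of numeric matrices of identical dimension.
#' @return A numeric matrix.
#' @export
max_project <- function(planes) {
  if (!is.list(planes) || length(planes) == 0L)
    stop("planes must be a non-empty list of matrices", call. = FALSE)
  Reduce(pmax, planes)
}
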