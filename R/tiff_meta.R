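# TIFF metadata plumbing.
#
# tiff::writeTIFF writes pixel data only; pixel-size metadata (an OME-XML
# ImageDescription plus classic resolution tags) is added afterwards by
# rewriting the first image file directory (IFD) at the end of the file and
# repointing the header at it.  The superseded IFD stays in the file as
# dead bytes, which baseline TIFF permits.  tiff::readTIFF exposes the
# added tags as attributes ("description", "x.resolution",
# "resolution.unit"), so reading needs no custom code.

# little-endian integer helpers operating on raw vectors
.le16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.le32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
.rd16 <- function(r, off) readBin(r[off + 1:2], "integer", size = 2,
                                  endian = "little", signed = FALSE)
.rd32 <- function(r, off) readBin(r[off + 1:4], "integer", size = 4,
                                  endian = "little")

# one 12-byte IFD entry
.ifd_entry <- function(tag, type, count, value_raw) {
  stopifnot(length(value_raw) <= 4L)
  pad <- raw(4L - length(value_raw))
  c(.le16(tag), .le16(type), .le32(count), value_raw, pad)
}

# Append description (tag 270, ASCII) and resolution (282/283 RATIONAL,
# pixels per centimetre; 296 SHORT = 3 for cm) to the first IFD of `path`.
tiff_patch_meta <- function(path, description = NULL, px_per_cm = NULL) {
  r <- readBin(path, "raw", file.size(path))
  if (!(r[1] == as.raw(0x49) && r[2] == as.raw(0x49)))
    stop("only little-endian TIFF supported", call. = FALSE)
  ifd0 <- .rd32(r, 4L)
  n <- .rd16(r, ifd0)
  entries <- lapply(seq_len(n) - 1L,
                    function(i) r[ifd0 + 2L + i * 12L + 1:12])
  next_off <- r[ifd0 + 2L + n * 12L + 1:4]

  if (length(r) %% 2L == 1L) r <- c(r, raw(1))  # word alignment
  tail_off <- length(r)
  extra <- raw(0)
  new_entries <- list()

  if (!is.null(description)) {
    bytes <- c(charToRaw(enc2utf8(description)), raw(1))
    new_entries <- c(new_entries, list(
      .ifd_entry(270L, 2L, length(bytes), .le32(tail_off + length(extra)))))
    extra <- c(extra, bytes, if (length(bytes) %% 2L) raw(1))
  }
  if (!is.null(px_per_cm)) {
    num <- as.integer(round(px_per_cm * 10000))
    for (tag in c(282L, 283L)) {
      new_entries <- c(new_entries, list(
        .ifd_entry(tag, 5L, 1L, .le32(tail_off + length(extra)))))
      extra <- c(extra, .le32(num), .le32(10000L))
    }
    new_entries <- c(new_entries, list(.ifd_entry(296L, 3L, 1L, .le16(3L))))
  }
  if (length(new_entries) == 0L) return(invisible(path))

  all_entries <- c(entries, new_entries)
  tags <- vapply(all_entries, function(e) .rd16(e, 0L), integer(1))
  all_entries <- all_entries[order(tags)]  # TIFF requires ascending tags

  ifd_off <- tail_off + length(extra)
  new_ifd <- c(.le16(length(all_entries)), unlist(all_entries), next_off)
  r <- c(r, extra, new_ifd)
  r[5:8] <- .le32(ifd_off)
  writeBin(r, path)
  invisible(path)
}

# Minimal OME-XML description for a 3-channel 2-D stack; carries the
# physical pixel size plus a private annotation with the intensity scale
# and source storage class needed for exact round trips.
ome_description <- function(stack, scale) {
  d <- dim(stack$dsdna)
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0" Name="', xml_escape(stack$image_id), '">',
    sprintf(paste0(
      '<Pixels ID="Pixels:0" DimensionOrder="XYCZT" Type="float"',
      ' SizeX="%d" SizeY="%d" SizeC="3" SizeZ="1" SizeT="1"',
      ' PhysicalSizeX="%.10g" PhysicalSizeY="%.10g"',
      ' PhysicalSizeXUnit="µm" PhysicalSizeYUnit="µm">'),
      d[2], d[1], stack$pixel_size_um, stack$pixel_size_um),
    '<Channel ID="Channel:0:0" Name="dsDNA" SamplesPerPixel="1"/>',
    '<Channel ID="Channel:0:1" Name="H2B" SamplesPerPixel="1"/>',
    '<Channel ID="Channel:0:2" Name="Hsp60" SamplesPerPixel="1"/>',
    '</Pixels></Image>',
    '<StructuredAnnotations>',
    '<XMLAnnotation ID="Annotation:0" Namespace="ectopuncta"><Value>',
    sprintf('<ectopuncta scale="%.17g" dtype="%s"/>', scale, stack$dtype),
    '</Value></XMLAnnotation></StructuredAnnotations>',
    '</OME>')
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Parse the pieces read_stack needs out of an ImageDescription string.
# Returns list(pixel_size_um, scale, dtype, image_id), entries NULL when
# absent. Tolerates arbitrary namespaces via local-name() matching.
parse_ome_description <- function(desc) {
  out <- list(pixel_size_um = NULL, scale = NULL, dtype = NULL,
              image_id = NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(out)
  px <- xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
  if (!inherits(px, "xml_missing")) {
    ps <- xml2::xml_attr(px, "PhysicalSizeX")
    if (!is.na(ps)) out$pixel_size_um <- as.numeric(ps)
  }
  img <- xml2::xml_find_first(doc, "//*[local-name()='Image']")
  if (!inherits(img, "xml_missing")) {
    nm <- xml2::xml_attr(img, "Name")
    if (!is.na(nm)) out$image_id <- nm
  }
  ann <- xml2::xml_find_first(doc, "//*[local-name()='ectopuncta']")
  if (!inherits(ann, "xml_missing")) {
    sc <- xml2::xml_attr(ann, "scale")
    dt <- xml2::xml_attr(ann, "dtype")
    if (!is.na(sc)) out$scale <- as.numeric(sc)
    if (!is.na(dt)) out$dtype <- dt
  }
  out
}

# Pixel size (um/px) from readTIFF attributes, honouring the precedence
# OME description > resolution tags. Returns NULL when unavailable.
pixel_size_from_attrs <- function(attrs) {
  desc <- attrs[["description"]]
  if (!is.null(desc)) {
    ps <- parse_ome_description(desc)$pixel_size_um
    if (!is.null(ps) && is.finite(ps) && ps > 0) return(ps)
  }
  xres <- attrs[["x.resolution"]]
  unit <- attrs[["resolution.unit"]]
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    um_per_unit <- switch(if (is.null(unit)) "none" else unit,
                          cm = 1e4, inch = 25400, NA_real_)
    if (is.finite(um_per_unit)) return(um_per_unit / xres)
  }
  NULL
}
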