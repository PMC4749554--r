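# Minimal baseline TIFF support: uncompressed, single-sample (grayscale)
# multi-page stacks, the form produced by segmentation pipelines exporting
# label masks. No R TIFF package is assumed; only readBin/writeBin are used.
# Reader: II/MM byte order, uint8/16/32 and float32, strip-organized.
# Writer: little-endian uint16 (labels) or float32 (intensities), one strip
# per page.

.tif_types <- c(BYTE = 1L, SHORT = 3L, LONG = 4L)
.tif_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

.rb <- function(raw, off, what, n, size, endian, signed = TRUE) {
  readBin(raw[(off + 1):(off + n * size)], what = what, n = n, size = size,
          endian = endian, signed = signed)
}

# Read one IFD entry's values (handles inline vs offset storage).
.tif_entry_values <- function(raw, entry_off, endian) {
  tag <- .rb(raw, entry_off, "integer", 1L, 2L, endian, signed = FALSE)
  type <- .rb(raw, entry_off + 2L, "integer", 1L, 2L, endian, signed = FALSE)
  count <- .rb(raw, entry_off + 4L, "integer", 1L, 4L, endian)
  tsize <- .tif_type_size[as.character(type)]
  if (is.na(tsize)) return(list(tag = tag, values = NULL))
  nbytes <- tsize * count
  voff <- if (nbytes <= 4L) entry_off + 8L
          else .rb(raw, entry_off + 8L, "integer", 1L, 4L, endian)
  values <- switch(as.character(type),
    `1` = .rb(raw, voff, "integer", count, 1L, endian, signed = FALSE),
    `3` = .rb(raw, voff, "integer", count, 2L, endian, signed = FALSE),
    `4` = .rb(raw, voff, "integer", count, 4L, endian),
    NULL)
  list(tag = tag, values = values)
}

#' Read a multi-page TIFF stack
#'
#' Reads an uncompressed grayscale multi-page TIFF into a list of numeric
#' matrices (row = image row). Supports uint8/16/32 and 32-bit float samples,
#' either byte order, and arbitrary strip layouts.
#'
#' @param path path to the TIFF file.
#' @return A list of matrices, one per page, in file order.
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  order <- rawToChar(raw[1:2])
  endian <- switch(order, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  magic <- .rb(raw, 2L, "integer", 1L, 2L, endian, signed = FALSE)
  if (magic != 42L) stop("not a TIFF file (bad magic number): ", path)
  ifd_off <- .rb(raw, 4L, "integer", 1L, 4L, endian)
  pages <- list()
  while (ifd_off != 0L) {
    n_entries <- .rb(raw, ifd_off, "integer", 1L, 2L, endian, signed = FALSE)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- .tif_entry_values(raw, ifd_off + 2L + (i - 1L) * 12L, endian)
      tags[[as.character(e$tag)]] <- e$values
    }
    width <- tags[["256"]]; height <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
    compression <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
    spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]]
    fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1]
    offsets <- tags[["273"]]; counts <- tags[["279"]]
    if (compression != 1L) stop("only uncompressed TIFF is supported")
    if (spp != 1L) stop("only single-sample (grayscale) TIFF is supported")
    pix_raw <- raw(0)
    for (s in seq_along(offsets))
      pix_raw <- c(pix_raw, raw[(offsets[s] + 1):(offsets[s] + counts[s])])
    n_pix <- width * height
    values <- if (fmt == 3L) {
      if (bits != 32L) stop("only 32-bit float samples supported")
      readBin(pix_raw, "double", n_pix, size = 4L, endian = endian)
    } else {
      switch(as.character(bits),
        `8` = readBin(pix_raw, "integer", n_pix, size = 1L, endian = endian,
                      signed = FALSE),
        `16` = readBin(pix_raw, "integer", n_pix, size = 2L, endian = endian,
                       signed = FALSE),
        `32` = readBin(pix_raw, "integer", n_pix, size = 4L, endian = endian),
        stop("unsupported bit depth: ", bits))
    }
    pages[[length(pages) + 1L]] <-
      matrix(values, nrow = height, ncol = width, byrow = TRUE)
    ifd_off <- .rb(raw, ifd_off + 2L + n_entries * 12L, "integer", 1L, 4L,
                   endian)
  }
  pages
}

.tif_entry <- function(tag, type, count, value) {
  # value must fit inline (<= 4 bytes); pad to 4
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.integer(tag), con, size = 2L, endian = "little")
  writeBin(as.integer(type), con, size = 2L, endian = "little")
  writeBin(as.integer(count), con, size = 4L, endian = "little")
  vsize <- .tif_type_size[as.character(type)]
  writeBin(as.integer(value), con, size = vsize, endian = "little")
  out <- rawConnectionValue(con)
  c(out, raw(12L - length(out)))
}

#' Write a multi-page TIFF stack
#'
#' Writes a list of matrices as an uncompressed little-endian multi-page TIFF,
#' one strip per page. Integer data are written as uint16 (label masks),
#' numeric data as 32-bit float (intensity stacks).
#'
#' @param frames list of matrices of identical dimensions.
#' @param path output file path.
#' @param type `"uint16"` or `"float32"`; default picks uint16 for
#'   whole-number data.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path, type = NULL) {
  stopifnot(is.list(frames), length(frames) > 0)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1) stop("all frames must have identical dimensions")
  h <- dims[[1]][1]; w <- dims[[1]][2]
  if (is.null(type)) {
    whole <- all(vapply(frames, function(f) all(f == round(f)), logical(1)))
    type <- if (whole) "uint16" else "float32"
  }
  if (type == "uint16" &&
      any(vapply(frames, function(f) any(f < 0 | f > 65535), logical(1))))
    stop("uint16 TIFF requires values in [0, 65535]")
  bps <- if (type == "uint16") 2L else 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  # header IFD pointer patched after layout is known
  data_bytes <- as.integer(h * w * bps)
  n <- length(frames)
  # layout: 8-byte header, then per page [pixel data][IFD]
  ifd_len <- 2L + 10L * 12L + 4L
  page_len <- data_bytes + ifd_len
  first_ifd <- 8L + data_bytes
  writeBin(first_ifd, con, size = 4L, endian = "little")
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    vec <- as.vector(t(fr))   # scanline order
    if (type == "uint16") {
      v <- as.integer(vec)
      # writeBin has no unsigned 16-bit mode; map 32768..65535 to signed
      v <- ifelse(v > 32767L, v - 65536L, v)
      writeBin(v, con, size = 2L, endian = "little")
    } else {
      writeBin(as.double(vec), con, size = 4L, endian = "little")
    }
    strip_off <- 8L + (i - 1L) * page_len
    next_ifd <- if (i < n) 8L + i * page_len + data_bytes else 0L
    writeBin(10L, con, size = 2L, endian = "little")
    ents <- list(
      .tif_entry(256L, 4L, 1L, w),                       # ImageWidth
      .tif_entry(257L, 4L, 1L, h),                       # ImageLength
      .tif_entry(258L, 3L, 1L, bps * 8L),                # BitsPerSample
      .tif_entry(259L, 3L, 1L, 1L),                      # Compression: none
      .tif_entry(262L, 3L, 1L, 1L),                      # BlackIsZero
      .tif_entry(273L, 4L, 1L, strip_off),               # StripOffsets
      .tif_entry(277L, 3L, 1L, 1L),                      # SamplesPerPixel
      .tif_entry(278L, 4L, 1L, h),                       # RowsPerStrip
      .tif_entry(279L, 4L, 1L, data_bytes),              # StripByteCounts
      .tif_entry(339L, 3L, 1L, if (type == "uint16") 1L else 3L)
    )
    for (e in ents) writeBin(e, con)
    writeBin(next_ifd, con, size = 4L, endian = "little")
  }
  invisible(path)
}
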