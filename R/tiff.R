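# Minimal baseline TIFF support: little-endian, uncompressed, grayscale,
# 8- or 16-bit unsigned, one or more strips per page.  This is deliberately
# narrow -- it exists only because no TIFF package is available in the
# supported environment, and it round-trips the stacks and masks this
# package writes (readable by any standard TIFF library).

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, description = 270L, strip_offsets = 273L,
               rows_per_strip = 278L, strip_byte_counts = 279L,
               sample_format = 339L)

write_uint <- function(con, x, size) {
  # writeBin truncates to the requested size; map values >= 2^(8*size-1)
  # onto their two's-complement integer so the byte pattern is correct
  x <- as.numeric(x)
  half <- 2^(8 * size - 1)
  x <- ifelse(x >= half, x - 2 * half, x)
  writeBin(as.integer(x), con, size = size, endian = "little")
}

write_ifd_entry <- function(con, tag, type, count, value) {
  write_uint(con, tag, 2L)
  write_uint(con, type, 2L)    # 3 = SHORT, 4 = LONG, 2 = ASCII
  write_uint(con, count, 4L)
  if (type == 3L) {            # SHORT packed into the 4-byte value field
    write_uint(con, value, 2L)
    write_uint(con, 0L, 2L)
  } else {
    write_uint(con, value, 4L)
  }
}

#' Write a list of integer matrices as a multipage grayscale TIFF
#' @param path output file.
#' @param frames list of integer matrices, all the same shape.
#' @param bits 8 or 16 (unsigned).
#' @param description optional character scalar stored in the first page's
#'   ImageDescription tag.
#' @keywords internal
write_tiff <- function(path, frames, bits = 16L, description = NULL) {
  stopifnot(length(frames) >= 1L, bits %in% c(8L, 16L))
  nr <- nrow(frames[[1L]]); nc <- ncol(frames[[1L]])
  maxval <- 2^bits - 1
  for (f in frames) {
    if (!is.matrix(f) || nrow(f) != nr || ncol(f) != nc)
      stop("all frames must be matrices of identical shape")
    if (any(f < 0) || any(f > maxval))
      stop("pixel values outside the ", bits, "-bit unsigned range")
  }
  n <- length(frames)
  bytes_px <- bits / 8L
  data_bytes <- nr * nc * bytes_px
  desc <- NULL
  if (!is.null(description)) {
    desc <- c(charToRaw(as.character(description)), as.raw(0L))
    if (length(desc) %% 2L) desc <- c(desc, as.raw(0L))  # even padding
  }
  n_entries <- ifelse(seq_len(n) == 1L & !is.null(desc), 10L, 9L)
  ifd_bytes <- 2L + 12L * n_entries + 4L

  pos <- 8
  data_off <- desc_off <- ifd_off <- numeric(n)
  for (p in seq_len(n)) {
    data_off[p] <- pos; pos <- pos + data_bytes
    if (p == 1L && !is.null(desc)) { desc_off[p] <- pos; pos <- pos + length(desc) }
    ifd_off[p] <- pos; pos <- pos + ifd_bytes[p]
  }

  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("II"), con)
  write_uint(con, 42L, 2L)
  write_uint(con, ifd_off[1L], 4L)
  for (p in seq_len(n)) {
    write_uint(con, as.vector(t(frames[[p]])), bytes_px)  # row-major
    if (p == 1L && !is.null(desc)) writeBin(desc, con)
    write_uint(con, n_entries[p], 2L)
    write_ifd_entry(con, TIFF_TAGS["width"], 3L, 1L, nc)
    write_ifd_entry(con, TIFF_TAGS["length"], 3L, 1L, nr)
    write_ifd_entry(con, TIFF_TAGS["bits"], 3L, 1L, bits)
    write_ifd_entry(con, TIFF_TAGS["compression"], 3L, 1L, 1L)
    write_ifd_entry(con, TIFF_TAGS["photometric"], 3L, 1L, 1L)
    if (p == 1L && !is.null(desc))
      write_ifd_entry(con, TIFF_TAGS["description"], 2L, length(desc), desc_off[p])
    write_ifd_entry(con, TIFF_TAGS["strip_offsets"], 4L, 1L, data_off[p])
    write_ifd_entry(con, TIFF_TAGS["rows_per_strip"], 3L, 1L, nr)
    write_ifd_entry(con, TIFF_TAGS["strip_byte_counts"], 4L, 1L, data_bytes)
    write_ifd_entry(con, TIFF_TAGS["sample_format"], 3L, 1L, 1L)
    write_uint(con, if (p < n) ifd_off[p + 1L] else 0L, 4L)
  }
  invisible(path)
}

read_uint <- function(con, size, n = 1L) {
  if (size == 4L) {
    x <- readBin(con, integer(), n = n, size = 4L, endian = "little")
    ifelse(x < 0, x + 2^32, as.numeric(x))
  } else {
    readBin(con, integer(), n = n, size = size, signed = FALSE,
            endian = "little")
  }
}

read_tag_values <- function(con, type, count, value_field_pos) {
  size <- switch(as.character(type), "1" = 1L, "2" = 1L, "3" = 2L, "4" = 4L,
                 stop("unsupported TIFF tag type: ", type))
  total <- size * count
  if (total <= 4L) {
    seek(con, value_field_pos)
  } else {
    seek(con, value_field_pos)
    off <- read_uint(con, 4L)
    seek(con, off)
  }
  if (type == 2L) {
    raw <- readBin(con, raw(), n = count)
    return(rawToChar(raw[raw != as.raw(0L)]))
  }
  read_uint(con, size, count)
}

#' Read a baseline grayscale TIFF into a list of integer matrices
#' @param path TIFF file (little-endian, uncompressed, 8/16-bit grayscale).
#' @return list with `frames` (list of matrices) and `description`
#'   (character or `NULL`).
#' @keywords internal
read_tiff <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- rawToChar(readBin(con, raw(), 2L))
  if (magic != "II")
    stop("unsupported TIFF byte order (only little-endian 'II' supported)")
  if (read_uint(con, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd_off <- read_uint(con, 4L)
  frames <- list(); description <- NULL
  while (ifd_off != 0) {
    seek(con, ifd_off)
    n_entries <- read_uint(con, 2L)
    entries <- lapply(seq_len(n_entries), function(i) {
      pos <- ifd_off + 2 + (i - 1) * 12
      seek(con, pos)
      list(tag = read_uint(con, 2L), type = read_uint(con, 2L),
           count = read_uint(con, 4L), value_pos = pos + 8)
    })
    seek(con, ifd_off + 2 + n_entries * 12)
    next_ifd <- read_uint(con, 4L)
    tagval <- function(tag, default = NULL) {
      e <- Filter(function(x) x$tag == tag, entries)
      if (!length(e)) return(default)
      read_tag_values(con, e[[1L]]$type, e[[1L]]$count, e[[1L]]$value_pos)
    }
    nc <- tagval(TIFF_TAGS[["width"]]); nr <- tagval(TIFF_TAGS[["length"]])
    if (is.null(nc) || is.null(nr)) stop("TIFF page missing image dimensions")
    bits <- tagval(TIFF_TAGS[["bits"]], 1L)[1L]
    if (!bits %in% c(8, 16)) stop("only 8/16-bit grayscale TIFF supported")
    if (tagval(TIFF_TAGS[["compression"]], 1L) != 1)
      stop("compressed TIFF not supported")
    if (is.null(description))
      description <- tagval(TIFF_TAGS[["description"]])
    offs <- tagval(TIFF_TAGS[["strip_offsets"]])
    cnts <- tagval(TIFF_TAGS[["strip_byte_counts"]],
                   nr * nc * bits / 8)
    px <- integer(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      px <- c(px, read_uint(con, bits / 8, cnts[s] / (bits / 8)))
    }
    if (length(px) != nr * nc) stop("TIFF strip data does not match dimensions")
    frames[[length(frames) + 1L]] <- matrix(px, nrow = nr, ncol = nc,
                                            byrow = TRUE)
    ifd_off <- next_ifd
  }
  list(frames = frames, description = description)
}
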