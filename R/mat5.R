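# Minimal MATLAB Level-5 MAT-file reader/writer.
#
# Supports what the epoch containers need: named double-precision numeric
# arrays of any rank and character matrices, uncompressed on write, with
# transparent zlib decompression of miCOMPRESSED elements on read. The
# HDF5-backed v7.3 dialect is detected and rejected with a clear message.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_CHAR <- 4L; MX_DOUBLE <- 6L

pad8 <- function(n) (8L - n %% 8L) %% 8L

write_mat5 <- function(vars, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, created by ssvepkit on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(desc)
  length(hdr) <- 116L
  hdr[is.na(hdr)] <- as.raw(32L)
  writeBin(hdr, con)
  writeBin(raw(8L), con)                          # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)            # version 0x0100 (LE)
  writeBin(charToRaw("IM"), con)                  # endian indicator
  for (nm in names(vars)) {
    writeBin(mat5_element(nm, vars[[nm]]), con)
  }
  invisible(path)
}

mat5_element <- function(name, value) {
  if (is.character(value)) {
    body <- mat5_char_body(name, value)
  } else {
    body <- mat5_numeric_body(name, value)
  }
  c(tag_raw(MI_MATRIX, length(body)), body)
}

tag_raw <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4, endian = "little"))
}

subelt <- function(type, payload) {
  p <- pad8(length(payload))
  c(tag_raw(type, length(payload)), payload, raw(p))
}

flags_subelt <- function(class_id) {
  fl <- writeBin(c(as.integer(class_id), 0L), raw(), size = 4,
                 endian = "little")
  subelt(MI_UINT32, fl)
}

dims_subelt <- function(dims) {
  subelt(MI_INT32, writeBin(as.integer(dims), raw(), size = 4,
                            endian = "little"))
}

name_subelt <- function(name) subelt(MI_INT8, charToRaw(name))

mat5_numeric_body <- function(name, value) {
  dims <- if (is.array(value)) dim(value) else c(1L, length(value))
  if (length(dims) == 1L) dims <- c(1L, dims)
  payload <- writeBin(as.numeric(value), raw(), size = 8, endian = "little")
  c(flags_subelt(MX_DOUBLE), dims_subelt(dims), name_subelt(name),
    subelt(MI_DOUBLE, payload))
}

# character vector -> char matrix (rows = elements, padded with spaces)
mat5_char_body <- function(name, value) {
  nr <- length(value)
  nc <- max(nchar(value), 1L)
  padded <- formatC(value, width = nc, flag = "-")
  codes <- matrix(32L, nr, nc)
  for (i in seq_len(nr)) codes[i, ] <- utf8ToInt(padded[i])
  # column-major order of the nr x nc matrix, as uint16 code units
  payload <- writeBin(as.integer(as.vector(codes)), raw(), size = 2,
                      endian = "little")
  c(flags_subelt(MX_CHAR), dims_subelt(c(nr, nc)), name_subelt(name),
    subelt(MI_UINT16, payload))
}

read_mat5 <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (length(raw_all) < 128L) stop("not a MAT-file: too short", call. = FALSE)
  magic <- rawToChar(raw_all[1:4])
  if (identical(magic, "MATL")) {
    # fine: v5 text header starts "MATLAB 5.0 ..."
  } else if (identical(rawToChar(raw_all[1:8]), "\x89HDF\r\n\032\n")) {
    stop("this .mat file uses the HDF5-backed v7.3 dialect, which is not supported; re-save it as v5 (e.g. `save(..., '-v6')` in MATLAB or `scipy.io.savemat`)",
         call. = FALSE)
  } else {
    stop("not a recognisable MAT v5 file", call. = FALSE)
  }
  endian <- rawToChar(raw_all[127:128])
  if (!identical(endian, "IM")) {
    stop("big-endian MAT-files are not supported", call. = FALSE)
  }
  pos <- 129L
  out <- list()
  n <- length(raw_all)
  while (pos + 7L <= n) {
    type <- readBin(raw_all[pos:(pos + 3L)], "integer", size = 4,
                    endian = "little")
    nbytes <- readBin(raw_all[(pos + 4L):(pos + 7L)], "integer", size = 4,
                      endian = "little")
    body <- raw_all[(pos + 8L):(pos + 7L + nbytes)]
    if (type == MI_COMPRESSED) {
      body <- decompress_zlib(body)
      type2 <- readBin(body[1:4], "integer", size = 4, endian = "little")
      if (type2 != MI_MATRIX) stop("unexpected element in MAT-file",
                                   call. = FALSE)
      body <- body[-(1:8)]
      type <- MI_MATRIX
    }
    if (type == MI_MATRIX) {
      v <- parse_matrix(body)
      out[[v$name]] <- v$value
    }
    pos <- pos + 8L + nbytes + pad8(nbytes)
  }
  out
}

decompress_zlib <- function(bytes) {
  for (ty in c("gzip", "unknown")) {
    res <- tryCatch(memDecompress(bytes, type = ty), error = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  stop("failed to decompress a miCOMPRESSED MAT element", call. = FALSE)
}

# parse subelements of one miMATRIX body
parse_matrix <- function(body) {
  pos <- 1L
  nexts <- function() {
    type <- readBin(body[pos:(pos + 3L)], "integer", size = 4,
                    endian = "little")
    small_len <- bitwAnd(bitwShiftR(type, 16L), 0xFFFFL)
    if (small_len > 0L) {            # small data element format
      stype <- bitwAnd(type, 0xFFFFL)
      payload <- body[(pos + 4L):(pos + 3L + small_len)]
      pos <<- pos + 8L
      return(list(type = stype, payload = payload))
    }
    nbytes <- readBin(body[(pos + 4L):(pos + 7L)], "integer", size = 4,
                      endian = "little")
    payload <- if (nbytes > 0L) body[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
    pos <<- pos + 8L + nbytes + pad8(nbytes)
    list(type = type, payload = payload)
  }
  flags <- nexts()
  class_id <- bitwAnd(readBin(flags$payload[1:4], "integer", size = 4,
                              endian = "little"), 0xFFL)
  dims_e <- nexts()
  dims <- readBin(dims_e$payload, "integer", size = 4, endian = "little",
                  n = length(dims_e$payload) / 4L)
  name_e <- nexts()
  name <- rawToChar(name_e$payload)
  data_e <- nexts()
  value <- decode_data(data_e$type, data_e$payload)
  if (class_id == MX_CHAR) {
    codes <- matrix(as.integer(value), dims[1], dims[2])
    value <- apply(codes, 1, function(r) trimws(intToUtf8(r), "right"))
  } else {
    if (length(dims) > 2L || (length(dims) == 2L && dims[1] > 1L && dims[2] > 1L)) {
      value <- array(as.numeric(value), dims)
    } else {
      value <- as.numeric(value)
    }
  }
  list(name = name, value = value)
}

decode_data <- function(type, payload) {
  switch(as.character(type),
    "9" = readBin(payload, "double", size = 8, endian = "little",
                  n = length(payload) / 8L),
    "7" = readBin(payload, "double", size = 4, endian = "little",
                  n = length(payload) / 4L),
    "5" = readBin(payload, "integer", size = 4, endian = "little",
                  n = length(payload) / 4L),
    "6" = readBin(payload, "integer", size = 4, endian = "little",
                  n = length(payload) / 4L),
    "3" = readBin(payload, "integer", size = 2, endian = "little",
                  n = length(payload) / 2L),
    "4" = readBin(payload, "integer", size = 2, endian = "little",
                  n = length(payload) / 2L, signed = FALSE),
    "1" = readBin(payload, "integer", size = 1, endian = "little",
                  n = length(payload)),
    "2" = as.integer(payload),
    stop("unsupported MAT data type ", type, call. = FALSE)
  )
}
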