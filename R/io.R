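# NPY (v1.0) read/write and a minimal 16-bit grayscale PNG encoder.
# Label maps travel as 16-bit PNG or NPY; distance maps as float32 NPY.

npy_dtype_info <- function(descr) {
  switch(descr,
    "<f8" = , "|f8" = list(what = "double", size = 8L, signed = TRUE, float = TRUE),
    "<f4" = list(what = "double", size = 4L, signed = TRUE, float = TRUE),
    "<i8" = list(what = "integer", size = 8L, signed = TRUE, float = FALSE),
    "<i4" = list(what = "integer", size = 4L, signed = TRUE, float = FALSE),
    "<i2" = list(what = "integer", size = 2L, signed = TRUE, float = FALSE),
    "|i1" = , "<i1" = list(what = "integer", size = 1L, signed = TRUE, float = FALSE),
    "<u2" = list(what = "integer", size = 2L, signed = FALSE, float = FALSE),
    "|u1" = , "<u1" = list(what = "integer", size = 1L, signed = FALSE, float = FALSE),
    stop("unsupported NPY dtype: ", descr)
  )
}

#' Read / write NPY arrays
#'
#' Minimal NumPy `.npy` (format version 1.0) support for numeric arrays of
#' any rank, handling both C and Fortran element order. `npy_write` stores
#' doubles as little-endian float32 by default (`dtype = "<f4"`) and
#' integers as int32.
#'
#' @param path file path.
#' @param x numeric/integer array.
#' @param dtype NPY dtype string (`"<f4"`, `"<f8"`, `"<i4"`).
#' @return `npy_read` returns the array; `npy_write` the path, invisibly.
#' @export
npy_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59)))) {
    stop("not an NPY file: ", path)
  }
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1]) >= 2L) {
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  if (length(shape) == 0L || (length(shape) == 1L && is.na(shape[1]))) shape <- integer(0)
  info <- npy_dtype_info(descr)
  n <- if (length(shape)) prod(shape) else 1L
  v <- readBin(con, info$what, n,
    size = info$size, endian = "little",
    signed = if (info$size < 4L) info$signed else TRUE
  )
  attr(v, "npy_descr") <- descr
  if (length(shape) <= 1L) return(v)
  if (fortran) {
    dim(v) <- shape
  } else {
    dim(v) <- rev(shape)
    v <- aperm(v, rev(seq_along(shape)))
  }
  attr(v, "npy_descr") <- descr
  v
}

#' @rdname npy_read
#' @export
npy_write <- function(x, path, dtype = if (is.integer(x)) "<i4" else "<f4") {
  info <- npy_dtype_info(dtype)
  d <- if (is.null(dim(x))) length(x) else dim(x)
  # C element order: reverse dims, transpose
  v <- if (length(d) > 1L) as.vector(aperm(x, rev(seq_along(d)))) else as.vector(x)
  shape_str <- if (length(d) == 1L) {
    paste0("(", d, ",)")
  } else {
    paste0("(", paste(d, collapse = ", "), ")")
  }
  dict <- sprintf(
    "{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
    dtype, shape_str
  )
  base_len <- 6L + 2L + 2L
  pad <- 64L - ((base_len + nchar(dict) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(dict, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(nchar(header), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  if (info$float) {
    writeBin(as.double(v), con, size = info$size, endian = "little")
  } else {
    writeBin(as.integer(v), con, size = info$size, endian = "little")
  }
  invisible(path)
}

# big-endian uint32 from a double (values can exceed .Machine$integer.max)
be_uint32 <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  crc <- crc32_cpp(td, 0)
  c(be_uint32(length(data)), td, be_uint32(crc))
}

# 16-bit grayscale PNG encoder (deflate via memCompress, zlib-wrapped).
write_png16 <- function(m, path) {
  stopifnot(all(m >= 0), all(m <= 65535))
  H <- nrow(m)
  W <- ncol(m)
  v <- as.integer(t(m)) # raster scan order
  bytes <- as.raw(rbind(v %/% 256L, v %% 256L)) # big-endian uint16
  scan <- rbind(as.raw(0L), matrix(bytes, 2L * W, H)) # filter byte per row
  stream <- as.vector(scan)
  zlib <- memCompress(stream, type = "gzip") # R emits an RFC-1950 zlib stream
  ihdr <- c(be_uint32(W), be_uint32(H), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", zlib), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

#' Read / write instance label maps
#'
#' Label maps are H x W matrices of non-negative integer ids (0 =
#' background), stored as 16-bit grayscale PNG or as NPY. Round-trip
#' write-then-read is the identity. Reading rejects float NPY inputs and
#' PNGs whose bit depth cannot hold the ids; writing to 8-bit PNG errors
#' when ids exceed 255.
#'
#' @param m H x W integer matrix.
#' @param path file ending in `.png` or `.npy`.
#' @param bits PNG bit depth (16 default; 8 allowed for small id ranges).
#' @return `read_label_map` returns the integer matrix.
#' @export
write_label_map <- function(m, path, bits = 16L) {
  if (any(m < 0)) stop("label maps must be non-negative")
  if (any(m != round(m))) stop("label maps must be integer-valued")
  storage.mode(m) <- "integer"
  ext <- tolower(tools::file_ext(path))
  if (ext == "npy") {
    npy_write(m, path, "<i4")
  } else if (ext == "png") {
    if (bits == 8L) {
      if (max(m) > 255L) stop("8-bit PNG cannot hold ids above 255")
      png::writePNG(m / 255, path)
    } else if (bits == 16L) {
      if (max(m) > 65535L) stop("16-bit PNG cannot hold ids above 65535")
      write_png16(m, path)
    } else {
      stop("unsupported bit depth: ", bits)
    }
  } else {
    stop("unsupported label map format: .", ext)
  }
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "npy") {
    m <- npy_read(path)
    descr <- attr(m, "npy_descr")
    if (grepl("f", descr)) stop("label maps must be integer NPY, got ", descr)
    if (any(m < 0)) stop("label maps must be non-negative")
    attr(m, "npy_descr") <- NULL
    storage.mode(m) <- "integer"
    m
  } else if (ext == "png") {
    v <- png::readPNG(path, info = TRUE)
    info <- attr(v, "info")
    depth <- if (is.null(info$bit.depth)) 16L else info$bit.depth
    if (length(dim(v)) == 3L) stop("label maps must be single-channel PNG")
    m <- round(v * (2^depth - 1))
    attr(m, "info") <- NULL
    storage.mode(m) <- "integer"
    m
  } else {
    stop("unsupported label map format: .", ext)
  }
}

#' Read / write horizontal-vertical distance maps
#'
#' Stored as H x W x 2 float32 NPY.
#'
#' @param hv H x W x 2 array.
#' @param path `.npy` file path.
#' @export
write_hv_map <- function(hv, path) {
  stopifnot(length(dim(hv)) == 3L, dim(hv)[3] == 2L)
  npy_write(hv, path, "<f4")
}

#' @rdname write_hv_map
#' @export
read_hv_map <- function(path) {
  hv <- npy_read(path)
  attr(hv, "npy_descr") <- NULL
  stopifnot(length(dim(hv)) == 3L, dim(hv)[3] == 2L)
  hv
}

#' Read / write 8-bit RGB image patches
#'
#' @param img H x W x 3 array with values in 0..255.
#' @param path `.png` file path.
#' @export
write_image_patch <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname write_image_patch
#' @export
read_image_patch <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 2L) v <- array(rep(v, 3L), c(dim(v), 3L))
  if (dim(v)[3] == 4L) v <- v[, , 1:3]
  round(v * 255)
}
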