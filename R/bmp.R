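# Minimal 24-bit uncompressed BMP codec (BITMAPINFOHEADER, BI_RGB,
# bottom-up rows, BGR byte order, rows padded to 4 bytes). Written by hand
# because the annotation protocol stores decomposed images as BMP and
# round-trips must be bit-exact.

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

#' Write an RGB raster as a 24-bit BMP file
#'
#' @param img h x w x 3 numeric/integer array with values 0..255.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bmp <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (any(img < 0 | img > 255)) stop("BMP requires 8-bit channel values")
  row_bytes <- w * 3
  pad <- (4 - row_bytes %% 4) %% 4
  data_size <- (row_bytes + pad) * h
  header <- c(
    as.raw(c(0x42, 0x4D)),            # "BM"
    .u32(54 + data_size), .u16(0), .u16(0), .u32(54),
    .u32(40), .u32(w), .u32(h), .u16(1), .u16(24),
    .u32(0), .u32(data_size), .u32(2835), .u32(2835), .u32(0), .u32(0)
  )
  # bottom-up rows, BGR order
  px <- array(as.integer(round(img)), dim = dim(img))
  body <- raw((row_bytes + pad) * h)
  pos <- 1L
  for (r in seq(h, 1)) {
    row <- as.raw(as.vector(rbind(px[r, , 3], px[r, , 2], px[r, , 1])))
    body[pos:(pos + row_bytes - 1)] <- row
    pos <- pos + row_bytes + pad
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body), con)
  invisible(path)
}

#' Read a 24-bit uncompressed BMP file
#'
#' Supports the dialect written by [write_bmp()] (BITMAPINFOHEADER, BI_RGB,
#' 24 bits per pixel); anything else is rejected as a format error.
#'
#' @param path File path.
#' @return h x w x 3 integer array with values 0..255.
#' @export
read_bmp <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 54 || bytes[1] != as.raw(0x42) || bytes[2] != as.raw(0x4D)) {
    stop("not a BMP file: ", path)
  }
  rd_u32 <- function(off) readBin(bytes[off + 1:4], "integer", size = 4,
                                  endian = "little")
  rd_u16 <- function(off) readBin(bytes[off + 1:2], "integer", size = 2,
                                  endian = "little", signed = FALSE)
  offset <- rd_u32(10)
  w <- rd_u32(18); h <- rd_u32(22)
  bpp <- rd_u16(28); compression <- rd_u32(30)
  if (bpp != 24 || compression != 0) {
    stop("unsupported BMP variant (need 24-bit uncompressed): ", path)
  }
  row_bytes <- w * 3
  pad <- (4 - row_bytes %% 4) %% 4
  img <- array(0L, dim = c(h, w, 3))
  pos <- offset
  for (r in seq(h, 1)) {
    row <- as.integer(bytes[(pos + 1):(pos + row_bytes)])
    m <- matrix(row, nrow = 3)   # BGR columns
    img[r, , 1] <- m[3, ]
    img[r, , 2] <- m[2, ]
    img[r, , 3] <- m[1, ]
    pos <- pos + row_bytes + pad
  }
  img
}
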