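# Grayscale image input/output: PNG, TIFF, PGM (8- or 16-bit). Pixels are
# read in their native integer range with no silent rescaling; the bit
# depth becomes the declared value_range. Multi-channel inputs are reduced
# to luminance with the Rec.601 weights.

.rec601 <- c(0.299, 0.587, 0.114)

img_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("pgm", "pnm")) return("pgm")
  stop(sprintf("unsupported image format '.%s' (use png, tiff or pgm)", ext),
       call. = FALSE)
}

to_gray <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  ch <- dim(arr)[3]
  if (ch == 1L) arr[, , 1]
  else if (ch %in% c(3L, 4L))
    .rec601[1] * arr[, , 1] + .rec601[2] * arr[, , 2] + .rec601[3] * arr[, , 3]
  else stop(sprintf("cannot convert %d-channel image to luminance", ch),
            call. = FALSE)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (expected P2 or P5 magic)", call. = FALSE)
  # read header tokens, skipping comments
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1)
    if (length(ch) == 0 || nchar(ch) == 0) stop("truncated PGM header", call. = FALSE)
    if (ch == "#") { repeat { c2 <- readChar(con, 1); if (c2 == "\n" || nchar(c2) == 0) break } ; next }
    if (grepl("[0-9]", ch)) buf <- c(buf, ch)
    else if (length(buf)) { tokens <- c(tokens, as.integer(paste(buf, collapse = ""))); buf <- character(0) }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  if (w < 1 || h < 1) stop("zero-size PGM image", call. = FALSE)
  n <- w * h
  vals <- if (magic == "P5") {
    if (maxval > 255)
      readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "big")
    else
      as.integer(readBin(con, "raw", n = n))
  } else {
    rest <- readChar(con, file.size(path), useBytes = TRUE)
    rest <- gsub("#[^\n]*", " ", rest)
    toks <- strsplit(trimws(rest), "\\s+")[[1]]
    as.integer(toks[seq_len(min(n, length(toks)))])
  }
  if (length(vals) < n) stop("truncated PGM pixel data", call. = FALSE)
  image2d(matrix(vals, nrow = h, ncol = w, byrow = TRUE), c(0, maxval))
}

write_pgm <- function(m, path, maxval) {
  lines <- c("P2", sprintf("%d %d", ncol(m), nrow(m)), sprintf("%d", maxval),
             apply(m, 1, paste, collapse = " "))
  writeLines(lines, path)
}

#' Read a grayscale image
#'
#' Loads a PNG, TIFF or PGM file as an `image2d`. Pixel values are kept in
#' their native integer scale — an 8-bit file gives values in
#' `[0, 255]` with that declared range, a 16-bit file `[0, 65535]` — and
#' color inputs are converted to luminance with the Rec.601 weights
#' (0.299 R + 0.587 G + 0.114 B).
#'
#' @param path File path ending in `.png`, `.tif(f)`, `.pgm` or `.pnm`.
#' @return An `image2d`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path),
                               call. = FALSE)
  fmt <- img_format(path)
  if (fmt == "pgm") return(read_pgm(path))
  if (fmt == "png") {
    arr <- png::readPNG(path, info = TRUE)
    depth <- attr(arr, "info")$bit.depth
    maxval <- 2^depth - 1
    return(image2d(round(to_gray(arr) * maxval), c(0, maxval)))
  }
  info <- tiff::readTIFF(path, payload = FALSE)
  depth <- info$bits.per.sample
  arr <- tiff::readTIFF(path)                 # normalized [0,1]
  maxval <- 2^depth - 1
  image2d(round(to_gray(arr) * maxval), c(0, maxval))
}

#' Write a grayscale image
#'
#' Clips the image to its declared value range, quantizes to the requested
#' bit depth and writes PNG (8-bit), TIFF (8- or 16-bit) or ASCII PGM
#' (8- or 16-bit). Output bytes are deterministic for a fixed input.
#'
#' @param image An `image2d` (or matrix, assumed `[0, 255]`).
#' @param path Destination path; the extension selects the format.
#' @param bit_depth 8 or 16; defaults to 16 when the declared range exceeds
#'   255, else 8.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = NULL) {
  image <- as_image2d(image)
  vr <- value_range(image)
  if (is.null(bit_depth)) bit_depth <- if (vr[2] - vr[1] > 255) 16L else 8L
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  fmt <- img_format(path)
  maxval <- 2L^bit_depth - 1L
  clipped <- pmin(pmax(px(image), vr[1]), vr[2])
  q <- round((clipped - vr[1]) / (vr[2] - vr[1]) * maxval)
  if (fmt == "png") {
    if (bit_depth != 8L)
      stop("PNG export is 8-bit here; use TIFF or PGM for 16-bit output",
           call. = FALSE)
    png::writePNG(q / maxval, path)
  } else if (fmt == "tiff") {
    tiff::writeTIFF(q / maxval, path, bits.per.sample = bit_depth,
                    compression = "none")
  } else {
    write_pgm(q, path, maxval)
  }
  invisible(path)
}
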