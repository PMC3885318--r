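#' Single-channel image container
#'
#' An `image2d` is a numeric matrix of pixel intensities carrying a declared
#' intensity domain (`value_range`). The declared range matters for the
#' histogram-based metrics (entropy, mutual information), for the SSIM
#' stabilizing constants and for quantization on export; pixel values are
#' stored in double precision and are never rescaled implicitly.
#'
#' @param pixels Numeric matrix (rows = image height, columns = width).
#' @param value_range Length-2 numeric, the declared intensity domain,
#'   e.g. `c(0, 255)` for 8-bit data or `c(0, 1)` for unit-range data.
#' @return An `image2d` object (a matrix with a `value_range` attribute).
#' @examples
#' img <- image2d(matrix(runif(64, 0, 255), 8, 8))
#' dim(img)
#' value_range(img)
#' @export
image2d <- function(pixels, value_range = c(0, 255)) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image contains non-finite pixel values", call. = FALSE)
  if (length(value_range) != 2L || !is.numeric(value_range) ||
      value_range[2] <= value_range[1])
    stop("`value_range` must be c(lo, hi) with hi > lo", call. = FALSE)
  storage.mode(pixels) <- "double"
  structure(unclass(pixels), value_range = as.numeric(value_range),
            class = c("image2d", "matrix", "array"))
}

#' @rdname image2d
#' @param x An object to coerce or query.
#' @export
as_image2d <- function(x, value_range = NULL) {
  if (inherits(x, "image2d")) {
    if (!is.null(value_range)) attr(x, "value_range") <- as.numeric(value_range)
    return(x)
  }
  image2d(as.matrix(x), if (is.null(value_range)) c(0, 255) else value_range)
}

#' @rdname image2d
#' @export
value_range <- function(x) {
  vr <- attr(x, "value_range")
  if (is.null(vr)) c(0, 255) else vr
}

#' @export
print.image2d <- function(x, ...) {
  vr <- value_range(x)
  cat(sprintf("<image2d> %d x %d, value_range [%g, %g]\n",
              nrow(x), ncol(x), vr[1], vr[2]))
  cat(sprintf("  intensity min %.4g, max %.4g, mean %.4g\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

# strip class, keep plain matrix for arithmetic-heavy internals
px <- function(x) {
  m <- unclass(x)
  attr(m, "value_range") <- NULL
  class(m) <- NULL
  dim(m) <- dim(x)
  m
}

# rebuild an image2d around new pixels, inheriting the declared range
rewrap <- function(pixels, template) image2d(pixels, value_range(template))

# Two fusion inputs must live on the same intensity scale for the max rule
# to compare like with like; mismatched declared ranges are rescaled to [0,1]
# with a warning.
harmonize_ranges <- function(a, b) {
  a <- as_image2d(a); b <- as_image2d(b)
  ra <- value_range(a); rb <- value_range(b)
  if (!isTRUE(all.equal(ra, rb))) {
    warning("inputs declare different value ranges; rescaling both to [0, 1]",
            call. = FALSE)
    a <- image2d((px(a) - ra[1]) / diff(ra), c(0, 1))
    b <- image2d((px(b) - rb[1]) / diff(rb), c(0, 1))
  }
  list(a = a, b = b)
}

check_same_shape <- function(..., what = "images") {
  imgs <- list(...)
  d <- vapply(imgs, dim, integer(2))
  if (any(d[1, ] != d[1, 1]) || any(d[2, ] != d[2, 1]))
    stop(sprintf("%s must share dimensions (got %s)", what,
                 paste(apply(d, 2, paste, collapse = "x"), collapse = " vs ")),
         call. = FALSE)
  invisible(TRUE)
}
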