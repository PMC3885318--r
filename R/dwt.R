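# ---- 1-D analysis/synthesis along the rows of a matrix -----------------
#
# Conventions (fixed for reproducibility):
#   * analysis is "filter, then keep the even-indexed samples of the full
#     convolution": a[i] = sum_k filt[k] x[2i - k] (0-based), the index taken
#     modulo n in periodic mode and over the zero-extended symmetric
#     extension otherwise;
#   * synthesis is the exact adjoint of analysis, which for an orthonormal
#     bank is the exact inverse;
#   * separable 2-D order is rows (width axis) first, then columns.
#
# Periodic mode filters the axis circularly; an odd-length axis is first
# padded by replicating its last sample (and cropped back at synthesis), so
# each band has ceil(n/2) samples. Symmetric mode extends the axis by
# (filterlen - 1) samples of half-point reflection on each side and applies
# the zero-extension transform to the extended signal; its adjoint
# reconstructs the extension exactly and the center is cropped out, so both
# modes invert to machine precision.

# half-point symmetric reflection index (1-based), period 2n
reflect_index <- function(j, n) {
  j0 <- (j - 1L) %% (2L * n)
  ifelse(j0 < n, j0 + 1L, 2L * n - j0)
}

sub_len <- function(n, flen, mode) {
  if (mode == "periodic") ceiling(n / 2)
  else floor((n + 3L * flen - 4L) / 2) + 1L
}

# analysis along columns' index (i.e. down the rows) of matrix X
dwt1d_cols <- function(X, lo, hi, mode) {
  n <- nrow(X); flen <- length(lo)
  if (mode == "periodic") {
    if (n %% 2L == 1L) { X <- rbind(X, X[n, , drop = FALSE]); }
    np <- nrow(X)
    m <- np %/% 2L
    A <- matrix(0, m, ncol(X)); D <- A
    base <- 2L * (seq_len(m) - 1L)
    for (k in seq_len(flen) - 1L) {
      idx <- ((base - k) %% np) + 1L
      Xi <- X[idx, , drop = FALSE]
      A <- A + lo[k + 1L] * Xi
      D <- D + hi[k + 1L] * Xi
    }
    list(a = A, d = D)
  } else {
    p <- flen - 1L
    ext_idx <- reflect_index(seq.int(1L - p, n + p), n)
    E <- X[ext_idx, , drop = FALSE]
    N <- nrow(E)
    m <- floor((N + flen - 2L) / 2) + 1L
    A <- matrix(0, m, ncol(X)); D <- A
    i_all <- seq_len(m) - 1L
    for (k in seq_len(flen) - 1L) {
      src <- 2L * i_all - k            # 0-based position in E
      keep <- src >= 0L & src <= N - 1L
      if (!any(keep)) next
      Ei <- E[src[keep] + 1L, , drop = FALSE]
      A[keep, ] <- A[keep, ] + lo[k + 1L] * Ei
      D[keep, ] <- D[keep, ] + hi[k + 1L] * Ei
    }
    list(a = A, d = D)
  }
}

# adjoint synthesis along rows; n_out is the pre-analysis axis length
idwt1d_cols <- function(A, D, lo, hi, mode, n_out) {
  m <- nrow(A); flen <- length(lo)
  if (mode == "periodic") {
    np <- 2L * m
    out <- matrix(0, np, ncol(A))
    base <- 2L * (seq_len(m) - 1L)
    for (k in seq_len(flen) - 1L) {
      idx <- ((base - k) %% np) + 1L
      out[idx, ] <- out[idx, ] + lo[k + 1L] * A + hi[k + 1L] * D
    }
    out[seq_len(n_out), , drop = FALSE]
  } else {
    p <- flen - 1L
    N <- n_out + 2L * p
    out <- matrix(0, N, ncol(A))
    i_all <- seq_len(m) - 1L
    for (k in seq_len(flen) - 1L) {
      dst <- 2L * i_all - k
      keep <- dst >= 0L & dst <= N - 1L
      if (!any(keep)) next
      idx <- dst[keep] + 1L
      out[idx, ] <- out[idx, ] + lo[k + 1L] * A[keep, , drop = FALSE] +
        hi[k + 1L] * D[keep, , drop = FALSE]
    }
    out[p + seq_len(n_out), , drop = FALSE]
  }
}

check_mode <- function(boundary_mode) {
  match.arg(boundary_mode, c("periodic", "symmetric"))
}

# one separable analysis step: rows (width) first, then columns (height)
dwt2_step <- function(X, bank, mode) {
  lo <- bank$analysis_low; hi <- bank$analysis_high
  r <- dwt1d_cols(t(X), lo, hi, mode)       # along width
  rL <- t(r$a); rH <- t(r$d)
  cL <- dwt1d_cols(rL, lo, hi, mode)        # along height
  cH <- dwt1d_cols(rH, lo, hi, mode)
  # horizontal detail: low along width, high along height (horizontal edges)
  list(ll = cL$a, horizontal = cL$d, vertical = cH$a, diagonal = cH$d)
}

idwt2_step <- function(ll, horizontal, vertical, diagonal, bank, mode, out_shape) {
  lo <- bank$analysis_low; hi <- bank$analysis_high
  rL <- idwt1d_cols(ll, horizontal, lo, hi, mode, out_shape[1])
  rH <- idwt1d_cols(vertical, diagonal, lo, hi, mode, out_shape[1])
  t(idwt1d_cols(t(rL), t(rH), lo, hi, mode, out_shape[2]))
}

#' Multilevel 2-D discrete wavelet analysis
#'
#' Decomposes a single-channel image into a `wavelet_pyramid`: one
#' approximation band at the deepest level plus, per level, three detail
#' bands in the horizontal, vertical and diagonal orientations. The
#' transform is the separable decimated filter-bank construction — each axis
#' is filtered with the analysis low/high pair and downsampled by two, and
#' the recursion continues on the low-low band.
#'
#' @param image An `image2d` or numeric matrix.
#' @param levels Number of decomposition levels, between 1 and
#'   [max_decomposition_level()] of the image.
#' @param bank A `filter_bank` or wavelet name (default `"db3"`).
#' @param boundary_mode `"periodic"` (default; circular extension, preserves
#'   the energy identity and reaches the full dyadic depth) or `"symmetric"`
#'   (half-point reflection).
#' @return A `wavelet_pyramid` object.
#' @seealso [idwt2()], [fuse_pyramids_max()]
#' @examples
#' img <- image2d(matrix(runif(1024, 0, 255), 32, 32))
#' p <- dwt2(img, levels = 3)
#' max(abs(idwt2(p) - img)) < 1e-8
#' @export
dwt2 <- function(image, levels, bank = "db3", boundary_mode = "periodic") {
  image <- as_image2d(image)
  mode <- check_mode(boundary_mode)
  bank <- as_filter_bank(bank)
  h <- nrow(image); w <- ncol(image)
  lmax <- max_decomposition_level(h, w)
  if (!is.numeric(levels) || length(levels) != 1L || levels != round(levels) ||
      levels < 1L || levels > lmax)
    stop(sprintf("levels must be an integer in [1, %d] for a %dx%d image",
                 lmax, h, w), call. = FALSE)
  levels <- as.integer(levels)

  cur <- px(image)
  details <- vector("list", levels)
  shapes <- vector("list", levels)   # input shape feeding each level
  for (j in seq_len(levels)) {
    shapes[[j]] <- dim(cur)
    s <- dwt2_step(cur, bank, mode)
    details[[j]] <- list(horizontal = s$horizontal,
                         vertical = s$vertical,
                         diagonal = s$diagonal)
    cur <- s$ll
  }
  structure(list(levels = levels,
                 approximation = cur,
                 details = details,
                 boundary_mode = mode,
                 bank_name = bank$name,
                 original_shape = c(h, w),
                 level_input_shapes = shapes,
                 value_range = value_range(image)),
            class = "wavelet_pyramid")
}

#' @export
print.wavelet_pyramid <- function(x, ...) {
  cat(sprintf("<wavelet_pyramid> %s, %d level(s), %s boundary, source %dx%d\n",
              x$bank_name, x$levels, x$boundary_mode,
              x$original_shape[1], x$original_shape[2]))
  cat(sprintf("  approximation %dx%d; details per level: horizontal, vertical, diagonal\n",
              nrow(x$approximation), ncol(x$approximation)))
  invisible(x)
}

# expected subband shape of level j given its input shape
expected_sub_shape <- function(shape, flen, mode) {
  c(sub_len(shape[1], flen, mode), sub_len(shape[2], flen, mode))
}

validate_pyramid <- function(p, bank) {
  if (!inherits(p, "wavelet_pyramid")) stop("not a wavelet_pyramid", call. = FALSE)
  if (bank$name != p$bank_name)
    stop(sprintf("filter bank '%s' does not match pyramid bank '%s'",
                 bank$name, p$bank_name), call. = FALSE)
  flen <- length(bank$analysis_low)
  if (length(p$details) != p$levels || length(p$level_input_shapes) != p$levels)
    stop("corrupt pyramid: level bookkeeping is inconsistent", call. = FALSE)
  shape <- p$original_shape
  for (j in seq_len(p$levels)) {
    if (!identical(as.integer(p$level_input_shapes[[j]]), as.integer(shape)))
      stop(sprintf("corrupt pyramid: level %d input shape mismatch", j),
           call. = FALSE)
    exp_shape <- expected_sub_shape(shape, flen, p$boundary_mode)
    for (ori in c("horizontal", "vertical", "diagonal")) {
      b <- p$details[[j]][[ori]]
      if (is.null(b) || !identical(as.integer(dim(b)), as.integer(exp_shape)))
        stop(sprintf("corrupt pyramid: level %d %s band has unexpected shape", j, ori),
             call. = FALSE)
    }
    shape <- exp_shape
  }
  if (!identical(as.integer(dim(p$approximation)), as.integer(shape)))
    stop("corrupt pyramid: approximation band has unexpected shape", call. = FALSE)
  invisible(TRUE)
}

#' Multilevel 2-D inverse discrete wavelet transform
#'
#' Inverts [dwt2()] level by level with the adjoint synthesis bank; an
#' unmodified pyramid reconstructs its source image to machine precision
#' (well inside 1e-8).
#'
#' @param pyramid A `wavelet_pyramid`.
#' @param bank Filter bank or name; must match `pyramid$bank_name`.
#' @return An `image2d` with the pyramid's original shape and value range.
#' @export
idwt2 <- function(pyramid, bank = pyramid$bank_name) {
  bank <- as_filter_bank(bank)
  validate_pyramid(pyramid, bank)
  cur <- pyramid$approximation
  for (j in rev(seq_len(pyramid$levels))) {
    d <- pyramid$details[[j]]
    cur <- idwt2_step(cur, d$horizontal, d$vertical, d$diagonal,
                      bank, pyramid$boundary_mode,
                      pyramid$level_input_shapes[[j]])
  }
  image2d(cur, pyramid$value_range)
}
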