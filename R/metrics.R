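# Non-reference fusion quality metrics. All metrics operate on the
# floating-point image; the declared value_range fixes histogram bin edges
# and the SSIM stabilizing constants. Conventions that the source
# literature leaves open are pinned down here and documented per function.

bin_index <- function(v, vr, bins) {
  i <- floor((as.vector(v) - vr[1]) / (vr[2] - vr[1]) * bins)
  pmin(pmax(i, 0), bins - 1L) + 1L
}

#' Shannon entropy of an image
#'
#' Entropy in bits of the normalized intensity histogram over `bins`
#' equal-width bins spanning the declared value range; empty bins
#' contribute zero. A constant image has entropy 0.
#'
#' @param image `image2d` or matrix (matrices assume range `[0, 255]`).
#' @param bins Number of histogram bins (default 256, the 8-bit convention).
#' @return Entropy in bits.
#' @export
metric_entropy <- function(image, bins = 256L) {
  image <- as_image2d(image)
  if (bins < 2L) stop("bins must be >= 2", call. = FALSE)
  counts <- tabulate(bin_index(image, value_range(image), bins), nbins = bins)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Standard deviation of an image
#'
#' Population standard deviation over all pixels (normalized by N, not
#' N - 1).
#'
#' @inheritParams metric_entropy
#' @return Standard deviation in intensity units.
#' @export
metric_sd <- function(image) {
  v <- as.vector(px(as_image2d(image)))
  sqrt(mean((v - mean(v))^2))
}

#' Spatial frequency of an image
#'
#' `SF = sqrt(RF^2 + CF^2)` with the row frequency RF the root mean square
#' of the horizontal (along-row) first differences and the column frequency
#' CF the same for vertical differences — an overall activity measure.
#'
#' @inheritParams metric_entropy
#' @return Spatial frequency (intensity units per pixel).
#' @export
metric_spatial_frequency <- function(image) {
  m <- px(as_image2d(image))
  h <- nrow(m); w <- ncol(m)
  rf2 <- if (w > 1) mean((m[, -1, drop = FALSE] - m[, -w, drop = FALSE])^2) else 0
  cf2 <- if (h > 1) mean((m[-1, , drop = FALSE] - m[-h, , drop = FALSE])^2) else 0
  sqrt(rf2 + cf2)
}

#' Average gradient of an image
#'
#' Mean over the (H-1) x (W-1) interior of
#' `sqrt((dx^2 + dy^2) / 2)` with forward differences — a sharpness
#' measure.
#'
#' @inheritParams metric_entropy
#' @return Average gradient (intensity units per pixel).
#' @export
metric_average_gradient <- function(image) {
  m <- px(as_image2d(image))
  h <- nrow(m); w <- ncol(m)
  if (h < 2 || w < 2) return(0)
  dx <- m[-h, -1, drop = FALSE] - m[-h, -w, drop = FALSE]
  dy <- m[-1, -w, drop = FALSE] - m[-h, -w, drop = FALSE]
  mean(sqrt((dx^2 + dy^2) / 2))
}

mi_pair <- function(x, y, vrx, vry, bins) {
  ix <- bin_index(x, vrx, bins)
  iy <- bin_index(y, vry, bins)
  joint <- tabulate((ix - 1L) * bins + iy, nbins = bins * bins)
  n <- sum(joint)
  pj <- joint / n
  dim(pj) <- c(bins, bins)           # [iy, ix]
  py <- rowSums(pj); pxm <- colSums(pj)
  nz <- which(pj > 0, arr.ind = TRUE)
  pv <- pj[nz]
  sum(pv * log2(pv / (py[nz[, 1]] * pxm[nz[, 2]])))
}

#' Fusion mutual information
#'
#' `MI = I(F;A) + I(F;B)`: how much intensity information of each source
#' survives in the fused image, each term computed from the `bins` x `bins`
#' joint histogram of paired pixels, in bits.
#'
#' @param a,b Source `image2d`s.
#' @param f Fused `image2d`.
#' @param bins Bins per axis of the joint histograms (default 256).
#' @return Mutual information in bits.
#' @export
metric_mutual_information <- function(a, b, f, bins = 256L) {
  a <- as_image2d(a); b <- as_image2d(b); f <- as_image2d(f)
  check_same_shape(a, b, f, what = "metric inputs")
  mi_pair(f, a, value_range(f), value_range(a), bins) +
    mi_pair(f, b, value_range(f), value_range(b), bins)
}

# 3x3 correlation with edge replication, via clamped index shifts
shift_clamp <- function(m, di, dj) {
  h <- nrow(m); w <- ncol(m)
  m[pmin(pmax(seq_len(h) + di, 1L), h), pmin(pmax(seq_len(w) + dj, 1L), w),
    drop = FALSE]
}

sobel_gradients <- function(m) {
  sx <- (shift_clamp(m, -1, 1) + 2 * shift_clamp(m, 0, 1) + shift_clamp(m, 1, 1)) -
    (shift_clamp(m, -1, -1) + 2 * shift_clamp(m, 0, -1) + shift_clamp(m, 1, -1))
  sy <- (shift_clamp(m, 1, -1) + 2 * shift_clamp(m, 1, 0) + shift_clamp(m, 1, 1)) -
    (shift_clamp(m, -1, -1) + 2 * shift_clamp(m, -1, 0) + shift_clamp(m, -1, 1))
  g <- sqrt(sx^2 + sy^2)
  ratio <- sy / sx
  ratio[sx == 0 & sy == 0] <- 0
  list(g = g, alpha = atan(ratio))
}

#' Xydeas-Petrovic default constants for the edge-strength metric
#' @return Named list of sigmoid gains, slopes and offsets.
#' @export
q_constants <- function() {
  list(gamma_g = 0.9994, kappa_g = -15, sigma_g = 0.5,
       gamma_a = 0.9879, kappa_a = -22, sigma_a = 0.8, L = 1)
}

edge_preservation <- function(src, fus, k) {
  G <- pmin(src$g, fus$g) / pmax(src$g, fus$g)
  G[pmax(src$g, fus$g) == 0] <- 1            # no edge in either: trivially kept
  A <- 1 - abs(src$alpha - fus$alpha) / (pi / 2)
  qg <- (1 + exp(k$kappa_g * (1 - k$sigma_g))) /
    (1 + exp(k$kappa_g * (G - k$sigma_g)))
  qa <- (1 + exp(k$kappa_a * (1 - k$sigma_a))) /
    (1 + exp(k$kappa_a * (A - k$sigma_a)))
  qg * qa
}

#' Edge-strength fusion metric Q
#'
#' The Xydeas-Petrovic gradient-based score in `[0, 1]`: Sobel gradient
#' magnitude and orientation are computed for both sources and the fused
#' image; per-pixel magnitude- and orientation-preservation ratios pass
#' through the published sigmoids (here normalized so that perfect
#' preservation scores exactly 1); the final Q averages the per-source
#' preservation weighted by source gradient magnitude.
#'
#' @inheritParams metric_mutual_information
#' @param constants Sigmoid constants, see [q_constants()].
#' @return Q in `[0, 1]`; `NA` when both sources are fully constant (the
#'   gradient-weighted average is then 0/0).
#' @export
metric_edge_strength_q <- function(a, b, f, constants = q_constants()) {
  a <- as_image2d(a); b <- as_image2d(b); f <- as_image2d(f)
  check_same_shape(a, b, f, what = "metric inputs")
  ga <- sobel_gradients(px(a)); gb <- sobel_gradients(px(b))
  gf <- sobel_gradients(px(f))
  qaf <- edge_preservation(ga, gf, constants)
  qbf <- edge_preservation(gb, gf, constants)
  wa <- ga$g^constants$L; wb <- gb$g^constants$L
  denom <- sum(wa + wb)
  if (denom == 0) {
    warning("both sources are constant; Q is undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(qaf * wa + qbf * wb) / denom
}

# windowed sums of every wh x ww window (stride 1) via an integral image
window_sums <- function(m, wh, ww) {
  S <- apply(apply(m, 2, cumsum), 1, cumsum)      # transposed integral image
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  h <- nrow(m); w <- ncol(m)
  i <- seq_len(h - wh + 1L); j <- seq_len(w - ww + 1L)
  S[i + wh, j + ww, drop = FALSE] - S[i, j + ww, drop = FALSE] -
    S[i + wh, j, drop = FALSE] + S[i, j, drop = FALSE]
}

ssim_map <- function(x, y, wh, ww, c1, c2) {
  n <- wh * ww
  mx <- window_sums(x, wh, ww) / n
  my <- window_sums(y, wh, ww) / n
  vx <- window_sums(x * x, wh, ww) / n - mx^2
  vy <- window_sums(y * y, wh, ww) / n - my^2
  cxy <- window_sums(x * y, wh, ww) / n - mx * my
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Blind structural similarity of a fused image
#'
#' SSIM of the fused image against each source over sliding windows
#' (uniform `window` x `window`, unit stride; a window larger than the
#' image degenerates to one global window), combined per window by the
#' unweighted mean of the two SSIM values and averaged. Stabilizing
#' constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2` use the declared dynamic
#' range L with K1 = 0.01, K2 = 0.03.
#'
#' @inheritParams metric_mutual_information
#' @param window Window side in pixels (default 8).
#' @return BSSIM in `[-1, 1]`.
#' @export
metric_bssim <- function(a, b, f, window = 8L) {
  a <- as_image2d(a); b <- as_image2d(b); f <- as_image2d(f)
  check_same_shape(a, b, f, what = "metric inputs")
  L <- diff(value_range(f))
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  wh <- min(window, nrow(f)); ww <- min(window, ncol(f))
  saf <- ssim_map(px(a), px(f), wh, ww, c1, c2)
  sbf <- ssim_map(px(b), px(f), wh, ww, c1, c2)
  mean((saf + sbf) / 2)
}

#' All seven fusion metrics for one fused image
#'
#' Evaluates Q, MI, E, SD, BSSIM, SF and AG for a fused image against its
#' two sources; the single-image metrics (E, SD, SF, AG) describe the fused
#' image itself. Degenerate cases (fully constant sources) yield `NA` for Q
#' with a warning rather than NaN propagation.
#'
#' @inheritParams metric_mutual_information
#' @param bins Histogram bins for E and MI.
#' @param window SSIM window for BSSIM.
#' @param constants Edge-strength constants, see [q_constants()].
#' @param method_label,level Optional annotations carried into the row.
#' @return A one-row tibble with columns `method`, `level`, `Q`, `MI`, `E`,
#'   `SD`, `BSSIM`, `SF`, `AG` (the column order of a fusion comparison
#'   table).
#' @export
evaluate_metrics <- function(a, b, f, bins = 256L, window = 8L,
                             constants = q_constants(),
                             method_label = NA_character_,
                             level = NA_integer_) {
  tibble::tibble(
    method = method_label,
    level = as.integer(level),
    Q = metric_edge_strength_q(a, b, f, constants),
    MI = metric_mutual_information(a, b, f, bins),
    E = metric_entropy(f, bins),
    SD = metric_sd(f),
    BSSIM = metric_bssim(a, b, f, window),
    SF = metric_spatial_frequency(f),
    AG = metric_average_gradient(f)
  )
}
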