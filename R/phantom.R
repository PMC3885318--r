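#' Synthetic two-modality phantom pair
#'
#' Deterministic, seeded generator of co-registered image pairs that mimic
#' the complementary content of CT/MRI pairs on a shared anatomy: both
#' modalities show the same elliptical "head" (background 20, interior 90,
#' bright rim) while modality A additionally carries thin high-contrast
#' line features (bone-like structure, intensity 230) and modality B
#' carries smooth Gaussian blobs (soft-tissue-like, peak near 230). The
#' exclusive features live in disjoint masks — A's features on the left
#' half of the head, B's on the right — so each source genuinely lacks the
#' other's information, and the pixelwise maximum of the two feature
#' layouts over the shared base is returned as the ideal fusion reference.
#'
#' @param size Image side in pixels (>= 32).
#' @param seed Integer seed; fixed `(size, seed, n_features)` reproduce the
#'   pair bit for bit without touching the global RNG stream.
#' @param n_features Number of exclusive features per modality (>= 1).
#' @param noise_sd Optional additive Gaussian noise (standard deviation in
#'   intensity units, applied to both modalities; 0 = none).
#' @return A `phantom_pair`: list with `modality_a`, `modality_b`
#'   (`image2d`, range `[0, 255]`), binary masks `mask_a`, `mask_b`,
#'   `composite_reference` and `seed`.
#' @examples
#' ph <- phantom_pair(64, seed = 1)
#' ph$modality_a
#' @export
phantom_pair <- function(size, seed = 1L, n_features = 3L, noise_sd = 0) {
  if (size < 32) stop("phantoms need size >= 32 for multiscale structure",
                      call. = FALSE)
  if (n_features < 1) stop("n_features must be >= 1", call. = FALSE)
  size <- as.integer(size)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  cx <- size / 2; cy <- size / 2
  rx <- 0.42 * size; ry <- 0.36 * size
  r2 <- ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2
  base <- matrix(20, size, size)
  base[r2 <= 1] <- 90
  base[r2 <= 1 & r2 > 0.88] <- 150          # shared skull-like rim

  a <- base; b <- base
  mask_a <- matrix(FALSE, size, size)
  mask_b <- matrix(FALSE, size, size)
  inside <- r2 <= 0.8                        # feature territory, off the rim

  # thin bright segments in the left half of the head (modality A)
  for (i in seq_len(n_features)) {
    for (try in 1:50) {
      px0 <- runif(1, cx - 0.8 * rx, cx - 0.08 * rx)
      py0 <- runif(1, cy - 0.7 * ry, cy + 0.7 * ry)
      theta <- runif(1, 0, pi)
      len <- runif(1, 0.12, 0.22) * size
      tt <- seq(-len / 2, len / 2, by = 0.3)
      sx <- round(px0 + tt * cos(theta)); sy <- round(py0 + tt * sin(theta))
      wpix <- sample(1:2, 1)
      pts <- unique(cbind(rep(sy, each = wpix) + seq_len(wpix) - 1L, rep(sx, each = wpix)))
      ok <- pts[, 1] >= 1 & pts[, 1] <= size & pts[, 2] >= 1 & pts[, 2] <= size
      pts <- pts[ok, , drop = FALSE]
      pts <- pts[inside[pts] & pts[, 2] < cx, , drop = FALSE]
      if (nrow(pts) >= 5) {
        a[pts] <- 230
        # exclusivity mask: footprint dilated by one pixel
        for (di in -1:1) for (dj in -1:1) {
          q <- cbind(pmin(pmax(pts[, 1] + di, 1L), size),
                     pmin(pmax(pts[, 2] + dj, 1L), size))
          mask_a[q] <- TRUE
        }
        break
      }
    }
  }

  # smooth bright blobs in the right half of the head (modality B)
  for (i in seq_len(n_features)) {
    for (try in 1:50) {
      sg <- runif(1, 2, 6) * max(size / 128, 0.5)
      bx <- runif(1, cx + 0.15 * rx, cx + 0.75 * rx)
      by <- runif(1, cy - 0.6 * ry, cy + 0.6 * ry)
      foot <- (xx - bx)^2 + (yy - by)^2 <= (2.5 * sg)^2
      if (all(inside[foot]) && all(xx[foot] > cx)) {
        b <- b + 140 * exp(-((xx - bx)^2 + (yy - by)^2) / (2 * sg^2))
        mask_b <- mask_b | foot
        break
      }
    }
  }
  # guarantee at least one exclusive feature per modality even if rejection
  # sampling exhausted its tries on a cramped layout
  if (!any(mask_a)) {
    sy <- round(cy) + (-4:4); sx <- rep(round(cx - 0.4 * rx), 9)
    pts <- cbind(sy, sx)
    a[pts] <- 230
    for (di in -1:1) for (dj in -1:1)
      mask_a[cbind(pts[, 1] + di, pts[, 2] + dj)] <- TRUE
  }
  if (!any(mask_b)) {
    bx <- cx + 0.4 * rx; by <- cy; sg <- 2
    foot <- (xx - bx)^2 + (yy - by)^2 <= (2.5 * sg)^2
    b <- b + 140 * exp(-((xx - bx)^2 + (yy - by)^2) / (2 * sg^2))
    mask_b <- mask_b | foot
  }
  b <- pmin(b, 255)

  if (noise_sd > 0) {
    a <- pmin(pmax(a + matrix(stats::rnorm(size^2, 0, noise_sd), size, size), 0), 255)
    b <- pmin(pmax(b + matrix(stats::rnorm(size^2, 0, noise_sd), size, size), 0), 255)
  }

  structure(list(modality_a = image2d(a, c(0, 255)),
                 modality_b = image2d(b, c(0, 255)),
                 mask_a = mask_a, mask_b = mask_b,
                 composite_reference = image2d(pmax(a, b), c(0, 255)),
                 seed = as.integer(seed)),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("<phantom_pair> %dx%d, seed %d; exclusive pixels A: %d, B: %d\n",
              nrow(x$modality_a), ncol(x$modality_a), x$seed,
              sum(x$mask_a), sum(x$mask_b)))
  invisible(x)
}

#' Root-mean-square error between two images
#'
#' @param x,y Images or matrices of equal size.
#' @param mask Optional logical matrix restricting the comparison.
#' @return RMSE in intensity units.
#' @export
rmse <- function(x, y, mask = NULL) {
  dx <- px(as_image2d(x)) - px(as_image2d(y))
  if (!is.null(mask)) dx <- dx[mask]
  sqrt(mean(dx^2))
}
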