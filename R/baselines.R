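# Classic comparison fusion methods: pixel averaging, PCA-weighted
# averaging, band-pass (Laplacian-backbone) pyramid fusion with gradient /
# contrast / ratio activity, and shift-invariant undecimated Haar wavelet
# fusion.

#' Pixelwise average fusion
#' @param a,b Co-registered `image2d` inputs of equal size.
#' @return The fused `image2d`.
#' @export
fuse_average <- function(a, b) {
  hb <- harmonize_ranges(a, b)
  check_same_shape(hb$a, hb$b)
  rewrap((px(hb$a) + px(hb$b)) / 2, hb$a)
}

#' PCA fusion weights
#'
#' Weights of the leading eigenvector of the 2 x 2 covariance matrix of the
#' two flattened images, sign-corrected to be non-negative and normalized
#' to sum to one. Two constant images carry no variance; the weights then
#' fall back to 0.5/0.5 (with a message).
#'
#' @inheritParams fuse_average
#' @return Named numeric `c(w_a = ..., w_b = ...)`.
#' @export
pca_weights <- function(a, b) {
  va <- as.vector(px(as_image2d(a))); vb <- as.vector(px(as_image2d(b)))
  C <- stats::cov(cbind(va, vb))
  if (!all(is.finite(C)) || sum(abs(C)) == 0) {
    message("both inputs are constant; PCA weights fall back to 0.5/0.5")
    return(c(w_a = 0.5, w_b = 0.5))
  }
  ev <- eigen(C, symmetric = TRUE)$vectors[, 1]
  if (sum(ev) < 0) ev <- -ev
  if (any(ev < 0)) {
    # anti-correlated inputs: the leading eigenvector has mixed signs, so a
    # convex weighting cannot follow it exactly; clamp and renormalize
    message("negatively correlated inputs; PCA weights clamped to [0, 1]")
    ev <- pmax(ev, 0)
  }
  w <- ev / sum(ev)
  c(w_a = w[1], w_b = w[2])
}

#' PCA-weighted fusion
#'
#' Weighted average `w_a * A + w_b * B` with weights from [pca_weights()]:
#' the modality carrying more variance dominates.
#'
#' @inheritParams fuse_average
#' @return The fused `image2d`.
#' @export
fuse_pca <- function(a, b) {
  hb <- harmonize_ranges(a, b)
  check_same_shape(hb$a, hb$b)
  w <- pca_weights(hb$a, hb$b)
  rewrap(w[1] * px(hb$a) + w[2] * px(hb$b), hb$a)
}

# ---- Gaussian / band-pass pyramid machinery ----------------------------

.gp_kernel <- c(1, 4, 6, 4, 1) / 16

# 5-tap filtering down the rows with half-point reflection
gp_filter_cols <- function(X, kernel = .gp_kernel) {
  n <- nrow(X)
  out <- matrix(0, n, ncol(X))
  for (t in -2:2) {
    idx <- reflect_index(seq_len(n) + t, n)
    out <- out + kernel[t + 3L] * X[idx, , drop = FALSE]
  }
  out
}

gp_reduce <- function(X) {
  Y <- t(gp_filter_cols(t(gp_filter_cols(X))))
  Y[seq(1, nrow(Y), by = 2), seq(1, ncol(Y), by = 2), drop = FALSE]
}

gp_expand <- function(C, out_shape) {
  U <- matrix(0, out_shape[1], out_shape[2])
  U[seq(1, out_shape[1], by = 2), seq(1, out_shape[2], by = 2)] <- C
  4 * t(gp_filter_cols(t(gp_filter_cols(U))))
}

check_pyr_levels <- function(levels, h, w) {
  lmax <- max_decomposition_level(h, w)
  if (!is.numeric(levels) || levels < 1L || levels > lmax)
    stop(sprintf("levels must be in [1, %d] for a %dx%d image", lmax, h, w),
         call. = FALSE)
  as.integer(levels)
}

# Gaussian levels G_0 .. G_L
gauss_pyramid <- function(m, levels) {
  G <- vector("list", levels + 1L)
  G[[1]] <- m
  for (k in seq_len(levels)) G[[k + 1L]] <- gp_reduce(G[[k]])
  G
}

# directional derivative energy (4 orientations) — the gradient-pyramid
# activity measure used to select between sources
grad_energy <- function(m) {
  n <- nrow(m); w <- ncol(m)
  down <- reflect_index(seq_len(n) + 1L, n)
  right <- reflect_index(seq_len(w) + 1L, w)
  dh <- m - m[, right, drop = FALSE]
  dv <- m - m[down, , drop = FALSE]
  dd1 <- (m - m[down, right, drop = FALSE]) / sqrt(2)
  dd2 <- (m[, right, drop = FALSE] - m[down, , drop = FALSE]) / sqrt(2)
  dh^2 + dv^2 + dd1^2 + dd2^2
}

#' Pyramid-domain baseline fusion
#'
#' Multiresolution fusion on a band-pass pyramid with a Gaussian (5-tap
#' binomial kernel) backbone, in one of three classic flavors:
#' \describe{
#'   \item{gradient}{band layers are the Laplacian differences
#'     `G_k - expand(G_{k+1})`; at each position the layer of the source
#'     with larger 4-orientation directional-derivative energy is selected
#'     (ties to A). The pyramid is exactly invertible, so fusing an image
#'     with itself returns it unchanged.}
#'   \item{contrast}{layers are local contrast `G_k / expand(G_{k+1}) - 1`,
#'     selected by maximum absolute value.}
#'   \item{ratio}{layers are the low-pass ratio `G_k / expand(G_{k+1})`,
#'     selected by maximum absolute value.}
#' }
#' The base (coarsest Gaussian) layer is fused by the arithmetic mean.
#' Ratio and contrast divisions are guarded by clamping the denominator at
#' `1e-6` of the declared intensity range.
#'
#' @inheritParams fuse_average
#' @param variant `"gradient"`, `"contrast"` or `"ratio"`.
#' @param levels Pyramid depth (within the dyadic capacity).
#' @return The fused `image2d`.
#' @export
fuse_pyramid <- function(a, b, variant = c("gradient", "contrast", "ratio"),
                         levels = 4L) {
  variant <- match.arg(variant)
  hb <- harmonize_ranges(a, b)
  check_same_shape(hb$a, hb$b)
  ma <- px(hb$a); mb <- px(hb$b)
  levels <- check_pyr_levels(levels, nrow(ma), ncol(ma))
  eps <- 1e-6 * diff(value_range(hb$a))

  GA <- gauss_pyramid(ma, levels)
  GB <- gauss_pyramid(mb, levels)
  fused_base <- (GA[[levels + 1L]] + GB[[levels + 1L]]) / 2

  layer <- function(G, k, denom) {
    switch(variant,
           gradient = G[[k]] - denom,
           contrast = G[[k]] / pmax(denom, eps) - 1,
           ratio    = G[[k]] / pmax(denom, eps))
  }
  uncollapse <- function(Lk, denom) {
    switch(variant,
           gradient = Lk + denom,
           contrast = (Lk + 1) * pmax(denom, eps),
           ratio    = Lk * pmax(denom, eps))
  }

  cur <- fused_base
  for (k in rev(seq_len(levels))) {
    shape <- dim(GA[[k]])
    ea <- gp_expand(GA[[k + 1L]], shape)
    eb <- gp_expand(GB[[k + 1L]], shape)
    la <- layer(GA, k, ea); lb <- layer(GB, k, eb)
    take_a <- if (variant == "gradient")
      grad_energy(GA[[k]]) >= grad_energy(GB[[k]])
    else
      abs(la) >= abs(lb)
    lf <- ifelse(take_a, la, lb)
    denom_f <- gp_expand(cur, shape)
    cur <- uncollapse(lf, denom_f)
  }
  rewrap(cur, hb$a)
}

# ---- shift-invariant (undecimated, a trous) Haar fusion ----------------

crot_rows <- function(m, s) {
  n <- nrow(m)
  m[((seq_len(n) - 1L - s) %% n) + 1L, , drop = FALSE]
}
crot_cols <- function(m, s) {
  n <- ncol(m)
  m[, ((seq_len(n) - 1L - s) %% n) + 1L, drop = FALSE]
}

sidwt_decompose <- function(m, levels) {
  details <- vector("list", levels)
  A <- m
  for (j in seq_len(levels)) {
    s <- 2L^(j - 1L)
    Lx <- (A + crot_cols(A, s)) / sqrt(2)
    Hx <- (A - crot_cols(A, s)) / sqrt(2)
    LL <- (Lx + crot_rows(Lx, s)) / sqrt(2)
    details[[j]] <- list(h = (Lx - crot_rows(Lx, s)) / sqrt(2),
                         v = (Hx + crot_rows(Hx, s)) / sqrt(2),
                         d = (Hx - crot_rows(Hx, s)) / sqrt(2))
    A <- LL
  }
  list(approx = A, details = details)
}

sidwt_reconstruct <- function(dec) {
  A <- dec$approx
  for (j in rev(seq_along(dec$details))) {
    s <- 2L^(j - 1L)
    d <- dec$details[[j]]
    adv <- function(m) crot_rows(m, -s)
    Lx <- (A + adv(A) + d$h - adv(d$h)) / (2 * sqrt(2))
    advc <- function(m) crot_cols(m, -s)
    Hx <- (d$v + crot_rows(d$v, -s) + d$d - crot_rows(d$d, -s)) / (2 * sqrt(2))
    A <- (Lx + advc(Lx) + Hx - advc(Hx)) / (2 * sqrt(2))
  }
  A
}

#' Shift-invariant Haar wavelet fusion
#'
#' Undecimated (a trous) Haar transform of both sources with periodic
#' boundaries, maximum-absolute selection on every detail plane (ties to
#' A), arithmetic mean on the residual low-pass, inverse transform. Because
#' no decimation takes place, the whole pipeline commutes exactly with
#' circular shifts of the inputs.
#'
#' @inheritParams fuse_average
#' @param levels Transform depth (within the dyadic capacity).
#' @return The fused `image2d`.
#' @export
fuse_sidwt_haar <- function(a, b, levels = 3L) {
  hb <- harmonize_ranges(a, b)
  check_same_shape(hb$a, hb$b)
  ma <- px(hb$a); mb <- px(hb$b)
  levels <- check_pyr_levels(levels, nrow(ma), ncol(ma))
  da <- sidwt_decompose(ma, levels)
  db <- sidwt_decompose(mb, levels)
  fused <- list(approx = (da$approx + db$approx) / 2,
                details = vector("list", levels))
  for (j in seq_len(levels)) {
    fused$details[[j]] <- Map(function(wa, wb) ifelse(abs(wa) >= abs(wb), wa, wb),
                              da$details[[j]], db$details[[j]])
  }
  rewrap(sidwt_reconstruct(fused), hb$a)
}
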