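# Independent brute-force oracles. Everything here is written as plainly
# (and slowly) as possible — explicit extension, explicit loops — and never
# calls into the package's transform internals.

rand_img <- function(n, m = n, lo = 0, hi = 255, range = c(0, 255)) {
  image2d(matrix(runif(n * m, lo, hi), n, m), range)
}

# 1-D analysis by explicit boundary extension + full convolution + keeping
# every second sample. Mirrors the documented convention: a[i] is the
# even-indexed (0-based) sample of the convolution sum(filt[k] x[t - k]).
oracle_dwt1d <- function(x, filt, mode) {
  n <- length(x)
  flen <- length(filt)
  if (mode == "periodic") {
    if (n %% 2 == 1) { x <- c(x, x[n]); n <- n + 1 }
    out <- numeric(n / 2)
    for (i in seq_along(out)) {
      t <- 2 * (i - 1)
      s <- 0
      for (k in seq_len(flen) - 1) s <- s + filt[k + 1] * x[((t - k) %% n) + 1]
      out[i] <- s
    }
    out
  } else {
    p <- flen - 1
    refl <- function(j) { j0 <- (j - 1) %% (2 * n); if (j0 < n) j0 + 1 else 2 * n - j0 }
    ext <- vapply(seq(1 - p, n + p), refl, 1)
    ext <- x[ext]
    N <- length(ext)
    m <- floor((N + flen - 2) / 2) + 1
    out <- numeric(m)
    for (i in seq_len(m)) {
      t <- 2 * (i - 1)
      s <- 0
      for (k in seq_len(flen) - 1) {
        j <- t - k
        if (j >= 0 && j <= N - 1) s <- s + filt[k + 1] * ext[j + 1]
      }
      out[i] <- s
    }
    out
  }
}

# level-1 separable 2-D analysis: every row, then every column
oracle_dwt2_level1 <- function(m, bank, mode) {
  lo <- bank$analysis_low; hi <- bank$analysis_high
  rowpass <- function(filt) t(apply(m, 1, oracle_dwt1d, filt = filt, mode = mode))
  rl <- rowpass(lo); rh <- rowpass(hi)
  colpass <- function(mm, filt) apply(mm, 2, oracle_dwt1d, filt = filt, mode = mode)
  list(ll = colpass(rl, lo), horizontal = colpass(rl, hi),
       vertical = colpass(rh, lo), diagonal = colpass(rh, hi))
}

oracle_entropy <- function(img, bins) {
  vr <- value_range(img)
  v <- as.vector(unclass(img))
  idx <- pmin(pmax(floor((v - vr[1]) / (vr[2] - vr[1]) * bins), 0), bins - 1)
  e <- 0
  for (b in 0:(bins - 1)) {
    p <- sum(idx == b) / length(idx)
    if (p > 0) e <- e - p * log2(p)
  }
  e
}

oracle_sd <- function(img) {
  v <- as.vector(unclass(img))
  mu <- sum(v) / length(v)
  sqrt(sum((v - mu)^2) / length(v))
}

oracle_sf <- function(img) {
  m <- unclass(img)
  h <- nrow(m); w <- ncol(m)
  rf <- cf <- 0
  for (i in 1:h) for (j in 2:w) rf <- rf + (m[i, j] - m[i, j - 1])^2
  for (i in 2:h) for (j in 1:w) cf <- cf + (m[i, j] - m[i - 1, j])^2
  sqrt(rf / (h * (w - 1)) + cf / ((h - 1) * w))
}

oracle_ag <- function(img) {
  m <- unclass(img)
  h <- nrow(m); w <- ncol(m)
  acc <- 0
  for (i in 1:(h - 1)) for (j in 1:(w - 1)) {
    dx <- m[i, j + 1] - m[i, j]
    dy <- m[i + 1, j] - m[i, j]
    acc <- acc + sqrt((dx^2 + dy^2) / 2)
  }
  acc / ((h - 1) * (w - 1))
}

oracle_mi_pair <- function(x, y, bins) {
  vrx <- value_range(x); vry <- value_range(y)
  ix <- pmin(pmax(floor((as.vector(unclass(x)) - vrx[1]) / (vrx[2] - vrx[1]) * bins), 0), bins - 1)
  iy <- pmin(pmax(floor((as.vector(unclass(y)) - vry[1]) / (vry[2] - vry[1]) * bins), 0), bins - 1)
  n <- length(ix)
  mi <- 0
  for (a in unique(ix)) for (b in unique(iy)) {
    pxy <- sum(ix == a & iy == b) / n
    if (pxy > 0) {
      pa <- sum(ix == a) / n
      pb <- sum(iy == b) / n
      mi <- mi + pxy * log2(pxy / (pa * pb))
    }
  }
  mi
}

# literal per-pixel transcription of the gradient-preservation metric,
# loops and all
oracle_q <- function(a, b, f) {
  k <- q_constants()
  sob <- function(m) {
    h <- nrow(m); w <- ncol(m)
    cl <- function(i, n) min(max(i, 1), n)
    g <- al <- matrix(0, h, w)
    for (i in 1:h) for (j in 1:w) {
      p <- function(di, dj) m[cl(i + di, h), cl(j + dj, w)]
      sx <- p(-1, 1) + 2 * p(0, 1) + p(1, 1) - p(-1, -1) - 2 * p(0, -1) - p(1, -1)
      sy <- p(1, -1) + 2 * p(1, 0) + p(1, 1) - p(-1, -1) - 2 * p(-1, 0) - p(-1, 1)
      g[i, j] <- sqrt(sx^2 + sy^2)
      al[i, j] <- if (sx == 0 && sy == 0) 0 else atan(sy / sx)
    }
    list(g = g, al = al)
  }
  sa <- sob(unclass(a)); sb <- sob(unclass(b)); sf <- sob(unclass(f))
  pres <- function(s, fz) {
    h <- nrow(s$g); w <- ncol(s$g)
    q <- matrix(0, h, w)
    for (i in 1:h) for (j in 1:w) {
      gs <- s$g[i, j]; gf <- fz$g[i, j]
      G <- if (max(gs, gf) == 0) 1 else min(gs, gf) / max(gs, gf)
      A <- 1 - abs(s$al[i, j] - fz$al[i, j]) / (pi / 2)
      qg <- (1 + exp(k$kappa_g * (1 - k$sigma_g))) / (1 + exp(k$kappa_g * (G - k$sigma_g)))
      qa <- (1 + exp(k$kappa_a * (1 - k$sigma_a))) / (1 + exp(k$kappa_a * (A - k$sigma_a)))
      q[i, j] <- qg * qa
    }
    q
  }
  qaf <- pres(sa, sf); qbf <- pres(sb, sf)
  num <- sum(qaf * sa$g + qbf * sb$g)
  den <- sum(sa$g + sb$g)
  num / den
}

# direct sliding-window SSIM mean, one window at a time
oracle_ssim_mean <- function(x, y, win, L) {
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  mx <- unclass(x); my <- unclass(y)
  h <- nrow(mx); w <- ncol(mx)
  wh <- min(win, h); ww <- min(win, w)
  vals <- c()
  for (i in 1:(h - wh + 1)) for (j in 1:(w - ww + 1)) {
    px <- mx[i:(i + wh - 1), j:(j + ww - 1)]
    py <- my[i:(i + wh - 1), j:(j + ww - 1)]
    n <- length(px)
    mux <- mean(px); muy <- mean(py)
    vx <- sum((px - mux)^2) / n
    vy <- sum((py - muy)^2) / n
    cv <- sum((px - mux) * (py - muy)) / n
    vals <- c(vals, ((2 * mux * muy + c1) * (2 * cv + c2)) /
                ((mux^2 + muy^2 + c1) * (vx + vy + c2)))
  }
  mean(vals)
}

oracle_bssim <- function(a, b, f, win = 8) {
  L <- diff(value_range(f))
  (oracle_ssim_mean(a, f, win, L) + oracle_ssim_mean(b, f, win, L)) / 2
}

# undecimated Haar analysis by direct circular convolution with the
# zero-upsampled filters (a trous), independent of the package's shifts
oracle_sidwt <- function(m, levels) {
  n <- nrow(m); w <- ncol(m)
  cconv_rows <- function(X, taps, lags) {
    out <- matrix(0, nrow(X), ncol(X))
    for (t in seq_along(taps)) {
      idx <- ((seq_len(nrow(X)) - 1 - lags[t]) %% nrow(X)) + 1
      out <- out + taps[t] * X[idx, , drop = FALSE]
    }
    out
  }
  cconv_cols <- function(X, taps, lags) t(cconv_rows(t(X), taps, lags))
  A <- m
  details <- list()
  for (j in seq_len(levels)) {
    s <- 2^(j - 1)
    lo <- c(1, 1) / sqrt(2); hi <- c(1, -1) / sqrt(2); lags <- c(0, s)
    Lx <- cconv_cols(A, lo, lags); Hx <- cconv_cols(A, hi, lags)
    details[[j]] <- list(h = cconv_rows(Lx, hi, lags),
                         v = cconv_rows(Hx, lo, lags),
                         d = cconv_rows(Hx, hi, lags))
    A <- cconv_rows(Lx, lo, lags)
  }
  list(approx = A, details = details)
}

# number of 4-connected components in a logical mask
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i0 in seq_len(nrow(mask))) for (j0 in seq_len(ncol(mask))) {
    if (mask[i0, j0] && lab[i0, j0] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i0, j0))
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        i <- p[1]; j <- p[2]
        if (i < 1 || j < 1 || i > nrow(mask) || j > ncol(mask)) next
        if (!mask[i, j] || lab[i, j] != 0L) next
        lab[i, j] <- cur
        stack <- c(stack, list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1)))
      }
    }
  }
  cur
}

# circular shift of a matrix by s rows and s columns
circ_shift <- function(m, s) {
  n <- nrow(m); w <- ncol(m)
  m[((seq_len(n) - 1 - s) %% n) + 1, ((seq_len(w) - 1 - s) %% w) + 1, drop = FALSE]
}

# plain matrix view of an image (attributes stripped) for identical() checks
mat <- function(x) {
  m <- unclass(x)
  attr(m, "value_range") <- NULL
  m
}
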