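checkerboard <- function(n) {
  m <- outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2)
  image2d(m, c(0, 1))
}

test_that("entropy matches the two-point and histogram oracles", {
  expect_identical(metric_entropy(image2d(matrix(128, 16, 16))), 0)
  half <- image2d(matrix(c(rep(0, 128), rep(255, 128)), 16, 16))
  expect_equal(metric_entropy(half, bins = 256), 1)
  set.seed(4)
  img <- image2d(matrix(sample(0:255, 256, TRUE), 16, 16))
  expect_equal(metric_entropy(img, 256), oracle_entropy(img, 256), tolerance = 1e-12)
  expect_error(metric_entropy(img, bins = 1), "bins")
})

test_that("standard deviation uses population normalization", {
  expect_identical(metric_sd(image2d(matrix(9, 8, 8))), 0)
  half01 <- image2d(matrix(c(rep(0, 32), rep(1, 32)), 8, 8), c(0, 1))
  expect_equal(metric_sd(half01), 0.5)
  set.seed(6)
  img <- rand_img(16)
  expect_equal(metric_sd(img), oracle_sd(img), tolerance = 1e-10)
})

test_that("spatial frequency resolves stripes and checkerboards", {
  expect_identical(metric_spatial_frequency(image2d(matrix(3, 8, 8))), 0)
  vert <- matrix(0, 16, 16); vert[, seq(2, 16, 2)] <- 1     # alternating columns
  expect_equal(metric_spatial_frequency(image2d(vert, c(0, 1))), 1)
  expect_equal(metric_spatial_frequency(checkerboard(16)), sqrt(2), tolerance = 1e-12)
  set.seed(8)
  img <- rand_img(16)
  expect_equal(metric_spatial_frequency(img), oracle_sf(img), tolerance = 1e-10)
})

test_that("average gradient matches the forward-difference oracle", {
  expect_identical(metric_average_gradient(image2d(matrix(3, 8, 8))), 0)
  ramp <- image2d(matrix(rep(0:15, each = 16), 16, 16))     # unit step along x
  expect_equal(metric_average_gradient(ramp), sqrt(1 / 2))
  set.seed(10)
  img <- rand_img(16)
  expect_equal(metric_average_gradient(img), oracle_ag(img), tolerance = 1e-12)
})

test_that("fusion mutual information behaves like I(F;A) + I(F;B)", {
  set.seed(12)
  a <- image2d(matrix(sample(0:255, 256, TRUE), 16, 16))
  expect_equal(metric_mutual_information(a, a, a), 2 * metric_entropy(a),
               tolerance = 1e-10)
  # 2x2 toy with a hand-computable 4-entry joint histogram
  ta <- image2d(matrix(c(0, 0, 255, 255), 2, 2, byrow = TRUE))
  tb <- image2d(matrix(c(0, 255, 0, 255), 2, 2, byrow = TRUE))
  expect_equal(metric_mutual_information(ta, tb, ta, bins = 2), 1)
  # a fused image independent of both sources carries almost no MI
  set.seed(13)
  big <- function() image2d(matrix(runif(128 * 128, 0, 255), 128, 128))
  expect_lt(metric_mutual_information(big(), big(), big(), bins = 16), 0.1)
  # oracle agreement on small seeded images
  f <- image2d(matrix(sample(0:255, 256, TRUE), 16, 16))
  b <- image2d(matrix(sample(0:255, 256, TRUE), 16, 16))
  expect_equal(metric_mutual_information(a, b, f, bins = 8),
               oracle_mi_pair(f, a, 8) + oracle_mi_pair(f, b, 8),
               tolerance = 1e-9)
})

test_that("edge strength Q rewards perfect and punishes absent edge transfer", {
  set.seed(14)
  img <- image2d(matrix(sample(0:255, 256, TRUE), 16, 16))
  expect_equal(metric_edge_strength_q(img, img, img), 1, tolerance = 1e-6)
  flat <- image2d(matrix(100, 16, 16))
  expect_lt(metric_edge_strength_q(img, img, flat), 0.01)
  expect_warning(qv <- metric_edge_strength_q(flat, flat, img), "constant")
  expect_true(is.na(qv))
})

test_that("edge strength Q equals its literal per-pixel transcription", {
  set.seed(15)
  for (rep in 1:3) {
    a <- rand_img(8); b <- rand_img(8)
    f <- fuse_average(a, b)
    expect_equal(metric_edge_strength_q(a, b, f), oracle_q(a, b, f),
                 tolerance = 1e-6)
  }
})

test_that("blind SSIM matches the direct sliding-window oracle", {
  set.seed(16)
  a <- rand_img(16); b <- rand_img(16)
  expect_equal(metric_bssim(a, a, a), 1, tolerance = 1e-9)
  # f = a: per-window score is (1 + SSIM(B,A)) / 2 under the mean combination
  expect_equal(metric_bssim(a, b, a), oracle_bssim(a, b, a), tolerance = 1e-9)
  f <- fuse_average(a, b)
  expect_equal(metric_bssim(a, b, f), oracle_bssim(a, b, f), tolerance = 1e-9)
  # degenerate window: larger than the image collapses to one global window
  small <- rand_img(6)
  expect_equal(metric_bssim(small, small, small, window = 64), 1, tolerance = 1e-9)
})

test_that("metrics agree with their oracles on seeded 16x16 triples", {
  set.seed(17)
  for (rep in 1:10) {
    a <- rand_img(16); b <- rand_img(16)
    f <- fuse_images(a, b, 2)$fused_image
    expect_equal(metric_entropy(f, 64), oracle_entropy(f, 64), tolerance = 1e-9)
    expect_equal(metric_sd(f), oracle_sd(f), tolerance = 1e-9)
    expect_equal(metric_spatial_frequency(f), oracle_sf(f), tolerance = 1e-9)
    expect_equal(metric_average_gradient(f), oracle_ag(f), tolerance = 1e-9)
    expect_equal(metric_mutual_information(a, b, f, 8),
                 oracle_mi_pair(f, a, 8) + oracle_mi_pair(f, b, 8), tolerance = 1e-9)
    expect_equal(metric_bssim(a, b, f), oracle_bssim(a, b, f), tolerance = 1e-9)
    expect_equal(metric_edge_strength_q(a, b, f), oracle_q(a, b, f), tolerance = 1e-6)
  }
})

test_that("source-order symmetry and intensity scaling behave as documented", {
  set.seed(18)
  a <- rand_img(16); b <- rand_img(16)
  f <- fuse_average(a, b)
  expect_equal(metric_edge_strength_q(a, b, f), metric_edge_strength_q(b, a, f))
  expect_equal(metric_mutual_information(a, b, f), metric_mutual_information(b, a, f))
  expect_equal(metric_bssim(a, b, f), metric_bssim(b, a, f))
  # SD, SF, AG scale linearly with intensity
  s <- image2d(3 * unclass(f), c(0, 765))
  expect_equal(metric_sd(s), 3 * metric_sd(f), tolerance = 1e-10)
  expect_equal(metric_spatial_frequency(s), 3 * metric_spatial_frequency(f), tolerance = 1e-10)
  expect_equal(metric_average_gradient(s), 3 * metric_average_gradient(f), tolerance = 1e-10)
  # entropy is invariant under a bin-respecting affine relabeling
  expect_equal(metric_entropy(s, 64), metric_entropy(f, 64), tolerance = 1e-12)
})

test_that("evaluate_metrics assembles a valid seven-metric row", {
  set.seed(19)
  a <- rand_img(16); b <- rand_img(16)
  f <- fuse_images(a, b, 2)$fused_image
  row <- evaluate_metrics(a, b, f, method_label = "proposed level 2", level = 2L)
  expect_identical(names(row),
                   c("method", "level", "Q", "MI", "E", "SD", "BSSIM", "SF", "AG"))
  expect_true(all(vapply(row[, 3:9], is.finite, TRUE)))
  expect_true(row$Q >= 0 && row$Q <= 1)
  expect_true(row$BSSIM >= -1 && row$BSSIM <= 1)
  expect_true(all(unlist(row[, c("MI", "E", "SD", "SF", "AG")]) >= 0))
  # degenerate all-constant triple: activity metrics zero, Q flagged NA
  flat <- image2d(matrix(50, 16, 16))
  expect_warning(drow <- evaluate_metrics(flat, flat, flat), "constant")
  expect_true(is.na(drow$Q))
  expect_identical(unname(unlist(drow[, c("E", "SD", "SF", "AG")])), rep(0, 4))
})
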