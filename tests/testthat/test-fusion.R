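make_pyr_pair <- function(seed = 1, n = 16, levels = 2) {
  set.seed(seed)
  list(p1 = dwt2(rand_img(n), levels), p2 = dwt2(rand_img(n), levels))
}

test_that("fusing a pyramid with itself or with zeros returns it exactly", {
  pp <- make_pyr_pair(3)
  expect_identical(fuse_pyramids_max(pp$p1, pp$p1), pp$p1)
  zero <- dwt2(image2d(matrix(0, 16, 16)), 2)
  f <- fuse_pyramids_max(pp$p1, zero)
  expect_identical(f$approximation, pp$p1$approximation)
  for (j in 1:2) for (ori in c("horizontal", "vertical", "diagonal"))
    expect_identical(f$details[[j]][[ori]], pp$p1$details[[j]][[ori]])
})

test_that("every fused coefficient is one of the candidates and attains the max modulus", {
  for (seed in 1:5) {
    pp <- make_pyr_pair(seed)
    f <- fuse_pyramids_max(pp$p1, pp$p2)
    check_band <- function(w1, w2, wf) {
      expect_true(all(wf == w1 | wf == w2))
      expect_identical(abs(wf), pmax(abs(w1), abs(w2)))
    }
    check_band(pp$p1$approximation, pp$p2$approximation, f$approximation)
    for (j in 1:2) for (ori in c("horizontal", "vertical", "diagonal"))
      check_band(pp$p1$details[[j]][[ori]], pp$p2$details[[j]][[ori]],
                 f$details[[j]][[ori]])
  }
})

test_that("exact modulus ties go to the first source", {
  pp <- make_pyr_pair(8)
  # negate source B so |W1| == |W2| everywhere but signs differ
  neg <- pp$p1
  neg$approximation <- -neg$approximation
  for (j in 1:2) for (ori in c("horizontal", "vertical", "diagonal"))
    neg$details[[j]][[ori]] <- -neg$details[[j]][[ori]]
  f <- fuse_pyramids_max(pp$p1, neg)
  expect_identical(f$approximation, pp$p1$approximation)
  for (j in 1:2) for (ori in c("horizontal", "vertical", "diagonal"))
    expect_identical(f$details[[j]][[ori]], pp$p1$details[[j]][[ori]])
})

test_that("fuse(A,B) and fuse(B,A) differ only where the moduli tie exactly", {
  pp <- make_pyr_pair(12)
  fab <- fuse_pyramids_max(pp$p1, pp$p2)
  fba <- fuse_pyramids_max(pp$p2, pp$p1)
  cmp <- function(w1, w2, ab, ba) {
    differs <- ab != ba
    expect_true(all(abs(w1)[differs] == abs(w2)[differs]))
  }
  cmp(pp$p1$approximation, pp$p2$approximation, fab$approximation, fba$approximation)
  for (j in 1:2) for (ori in c("horizontal", "vertical", "diagonal"))
    cmp(pp$p1$details[[j]][[ori]], pp$p2$details[[j]][[ori]],
        fab$details[[j]][[ori]], fba$details[[j]][[ori]])
})

test_that("structurally incompatible pyramids are refused", {
  set.seed(2)
  p1 <- dwt2(rand_img(16), 2)
  p2 <- dwt2(rand_img(16), 3)
  expect_error(fuse_pyramids_max(p1, p2), "levels")
  p3 <- dwt2(rand_img(16), 2, "haar")
  expect_error(fuse_pyramids_max(p1, p3), "bank")
  p4 <- dwt2(rand_img(32), 2)
  expect_error(fuse_pyramids_max(p1, p4), "shapes differ")
})

test_that("image-level fusion is idempotent and absorbs a zero image", {
  set.seed(21)
  img <- rand_img(32)
  zero <- image2d(matrix(0, 32, 32))
  for (L in 1:max_decomposition_level(32, 32)) {
    expect_lt(max(abs(fuse_images(img, img, L)$fused_image - img)), 1e-8)
    expect_lt(max(abs(fuse_images(img, zero, L)$fused_image - img)), 1e-8)
  }
})

test_that("complementary half-field features are both carried into the fused image", {
  n <- 64
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  disc <- function(cx, cy) 200 * (((xx - cx)^2 + (yy - cy)^2) <= 8^2)
  A <- image2d(disc(18, 32))   # left-half bright disc on black
  B <- image2d(disc(46, 32))   # right-half bright disc on black
  f <- fuse_images(A, B, 3)$fused_image
  left <- xx <= 32
  expect_lt(rmse(f, A, left), rmse(f, B, left))
  expect_lt(rmse(f, B, !left), rmse(f, A, !left))
})

test_that("the average approximation rule averages only the approximation band", {
  pp <- make_pyr_pair(31)
  f <- fuse_pyramids_max(pp$p1, pp$p2, approximation_rule = "average")
  expect_identical(f$approximation,
                   (pp$p1$approximation + pp$p2$approximation) / 2)
  fmax <- fuse_pyramids_max(pp$p1, pp$p2)
  for (j in 1:2) for (ori in c("horizontal", "vertical", "diagonal"))
    expect_identical(f$details[[j]][[ori]], fmax$details[[j]][[ori]])
})

test_that("the multiscale sweep equals independent single-level calls", {
  set.seed(77)
  A <- rand_img(32); B <- rand_img(32)
  res <- fuse_multiscale(A, B, level_min = 2, level_max = 5)
  expect_length(res, 4)
  expect_identical(vapply(res, `[[`, 1L, "level"), 2:5)
  for (r in res)
    expect_identical(unclass(r$fused_image),
                     unclass(fuse_images(A, B, r$level)$fused_image))
  single <- fuse_multiscale(A, B, level_min = 3, level_max = 3)
  expect_length(single, 1)
  samei <- fuse_multiscale(A, A, level_min = 1, level_max = 5)
  for (r in samei) expect_lt(max(abs(r$fused_image - A)), 1e-8)
})

test_that("mismatched or out-of-capacity requests fail fast", {
  expect_error(fuse_images(rand_img(16), rand_img(32), 1), "dimensions")
  expect_error(fuse_images(rand_img(16), rand_img(16), 9), "\\[1, 4\\]")
  expect_error(fuse_multiscale(rand_img(16), rand_img(16), level_min = 0),
               "level_min")
})

test_that("inputs with different declared ranges are rescaled with a warning", {
  a <- image2d(matrix(runif(256, 0, 255), 16, 16), c(0, 255))
  b <- image2d(matrix(runif(256, 0, 1), 16, 16), c(0, 1))
  expect_warning(f <- fuse_images(a, b, 2), "rescaling")
  expect_identical(value_range(f$fused_image), c(0, 1))
})
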