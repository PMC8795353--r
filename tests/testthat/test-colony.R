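test_that("Gaussian scale space: constant image, identity limit, impulse response", {
  const <- matrix(0.4, 64, 64)
  expect_equal(gaussian_scale_space(const, 3)$smoothed, const, tolerance = 1e-12)
  ## sigma -> 0 limit on a smooth image
  xg <- matrix(seq_len(64), 64, 64)
  smooth_img <- 0.5 + 0.3 * sin(xg / 15) * sin(t(xg) / 12)
  ss <- gaussian_scale_space(smooth_img, 0.3)
  expect_lt(max(abs(ss$smoothed - smooth_img)), 0.01)
  ## point impulse reproduces the sampled (finite-support) Gaussian kernel
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  sm <- gaussian_scale_space(imp, 2)$smoothed
  g <- stats::dnorm(-8:8, 0, 2); g <- g / sum(g)
  gfull <- numeric(41); gfull[13:29] <- g
  expect_equal(sm, outer(gfull, gfull), tolerance = 1e-9)
  expect_error(gaussian_scale_space(matrix(0, 8, 8), 10), "too large")
})

test_that("Hessian field reproduces analytic derivatives of polynomials", {
  n <- 48
  xg <- matrix(seq_len(n), n, n); yg <- t(xg)
  hf <- hessian_field(xg^2 + yg^2, 2)
  i <- 15:34
  expect_equal(hf$ixx[i, i], matrix(2, 20, 20), tolerance = 1e-6)
  expect_equal(hf$iyy[i, i], matrix(2, 20, 20), tolerance = 1e-6)
  expect_equal(hf$ixy[i, i], matrix(0, 20, 20), tolerance = 1e-6)
  hf2 <- hessian_field(xg * yg, 2)
  expect_equal(hf2$ixy[i, i], matrix(1, 20, 20), tolerance = 1e-6)
  expect_equal(hf2$ixx[i, i], matrix(0, 20, 20), tolerance = 1e-6)
})

test_that("inverted Gaussian blob has the analytic positive-definite Hessian at centre", {
  n <- 61; w <- 4; A <- 0.5; sg <- 2
  xg <- matrix(seq_len(n) - 31, n, n); yg <- t(xg)
  img <- 0.8 - A * exp(-(xg^2 + yg^2) / (2 * w^2))
  hf <- hessian_field(img, sg)
  ## smoothing widens the blob: curvature A w^2/(w^2+sg^2)^2 at the centre
  expected <- A * w^2 / (w^2 + sg^2)^2
  expect_equal(hf$ixx[31, 31], expected, tolerance = 0.02)
  expect_equal(hf$iyy[31, 31], expected, tolerance = 0.02)
  expect_equal(hf$ixy[31, 31], 0, tolerance = 1e-8)
  expect_identical(classify_elliptic(hf)[31, 31], "DARK")
})

test_that("elliptic classification matches the eigenvalue oracle", {
  expect_identical(classify_elliptic(matrix(c(2, 0, 0, 3), 2)), "DARK")
  expect_identical(classify_elliptic(matrix(c(-2, 0, 0, -3), 2)), "BRIGHT")
  expect_identical(classify_elliptic(matrix(c(1, 2, 2, 1), 2)), "NEITHER")
  set.seed(4)
  n <- 2e4
  ixx <- rnorm(n); ixy <- rnorm(n); iyy <- rnorm(n)
  got <- classify_elliptic(ixx, ixy, iyy)
  oracle <- vapply(seq_len(n), function(i) {
    ev <- eigen(matrix(c(ixx[i], ixy[i], ixy[i], iyy[i]), 2), symmetric = TRUE,
                only.values = TRUE)$values
    if (all(ev > 0)) "DARK" else if (all(ev < 0)) "BRIGHT" else "NEITHER"
  }, "")
  expect_identical(got, oracle)
})

test_that("contrast inversion swaps DARK and BRIGHT exactly", {
  img <- make_plate_image(30, size_px = 256, margin_px = 14, seed = 21)
  h1 <- hessian_field(img, 2)
  h2 <- hessian_field(1 - img, 2)
  c1 <- classify_elliptic(h1); c2 <- classify_elliptic(h2)
  expect_identical(c1 == "DARK", c2 == "BRIGHT")
  expect_identical(c1 == "BRIGHT", c2 == "DARK")
})

test_that("DARK pixels always have a positive Laplacian", {
  img <- make_plate_image(60, size_px = 256, margin_px = 14, seed = 22)
  hf <- hessian_field(img, 2)
  dark <- classify_elliptic(hf) == "DARK"
  expect_true(all((hf$ixx + hf$iyy)[dark] > 0))
})

test_that("well boundary voting finds a perfect disc to pixel accuracy", {
  n <- 160
  xg <- matrix(seq_len(n) - 80.5, n, n); yg <- t(xg)
  r <- sqrt(xg^2 + yg^2)
  img <- 0.85 - 0.7 * (r < 55)          # dark disc on bright field
  img <- gaussian_scale_space(img, 1)$smoothed
  ws <- enhance_well_boundary(img)
  d <- sqrt((ws$points$x - 80.5)^2 + (ws$points$y - 80.5)^2)
  expect_true(all(abs(d - 55) < 1.5))
  ## saliency at true-boundary pixels grows as the aperture narrows
  s1 <- ws$saliency_history[[1]]; s2 <- ws$saliency_history[[2]]
  eidx <- ws$edge_idx
  ex <- ((eidx - 1) %% n) + 1; ey <- ((eidx - 1) %/% n) + 1
  onb <- abs(sqrt((ex - 80.5)^2 + (ey - 80.5)^2) - 55) < 1.5
  expect_gt(mean(s2[onb]), mean(s1[onb]))
  expect_gt(mean(s2[onb] > s1[onb]), 0.9)
})

test_that("boundary detection is equivariant under quarter-turn rotation", {
  img <- make_plate_image(0, size_px = 192, seed = 23)
  r1 <- count_plate(img)$well
  rot <- t(img)[ncol(img):1, ]       # 90 degree rotation
  r2 <- count_plate(rot)$well
  expect_equal(r2$cx, nrow(img) + 1 - r1$cy, tolerance = 1.5)
  expect_equal(r2$cy, r1$cx, tolerance = 1.5)
  expect_equal(sort(c(r2$major, r2$minor)), sort(c(r1$major, r1$minor)),
               tolerance = 0.02)
})

test_that("direct ellipse fit: exact circle, noisy ellipse, degenerate input", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  we <- fit_ellipse(200 + 50 * cos(th), 180 + 50 * sin(th))
  expect_equal(c(we$cx, we$cy, we$major, we$minor), c(200, 180, 50, 50),
               tolerance = 1e-6)
  set.seed(8)
  a <- 80; b <- 50; ang <- pi / 6
  x0 <- a * cos(th); y0 <- b * sin(th)
  xe <- 300 + x0 * cos(ang) - y0 * sin(ang) + rnorm(100, 0, 0.5)
  ye <- 250 + x0 * sin(ang) + y0 * cos(ang) + rnorm(100, 0, 0.5)
  wf <- fit_ellipse(xe, ye)
  expect_equal(c(wf$cx, wf$cy, wf$major, wf$minor) / c(300, 250, 80, 50),
               rep(1, 4), tolerance = 0.01)
  expect_equal(wf$angle, ang, tolerance = 0.02)
  expect_error(fit_ellipse(1:5, c(2, 4, 1, 7, 3)), "at least 6")
  expect_error(fit_ellipse(1:20, 2 * (1:20) + 3), "degenerate|ellipse")
})

test_that("colony mask: blank well, exact recovery, noise rejection", {
  cfg <- plate_config(sigma = 2, min_area = 12)
  blank <- make_plate_image(0, size_px = 256, seed = 31)
  expect_equal(count_plate(blank, cfg)$result$count, 0L)

  img <- make_plate_image(25, size_px = 256, margin_px = 14, seed = 32)
  cp <- count_plate(img, cfg)
  expect_equal(cp$result$count, 25L)
  ## all detected centroids lie inside the well
  tr <- attr(img, "truth")$well
  expect_true(all(inside_ellipse(tr, cp$result$centroids$x, cp$result$centroids$y)))

  ## salt-and-pepper noise: isolated flipped pixels stay below the
  ## size/intensity filters and leave the count unchanged
  set.seed(33)
  sp_img <- img
  idx <- sample(length(sp_img), 200)
  sp_img[idx] <- rep(c(0, 1), each = 100)
  expect_equal(count_plate(sp_img, cfg)$result$count, 25L)
})

test_that("plate counting is deterministic and gain-invariant", {
  img <- make_plate_image(40, size_px = 256, margin_px = 14, seed = 34)
  cfg <- plate_config(sigma = 2, min_area = 12)
  c1 <- count_plate(img, cfg); c2 <- count_plate(img, cfg)
  expect_identical(c1$result$count, c2$result$count)
  expect_identical(c1$result$centroids, c2$result$centroids)
  ## positive affine intensity rescaling preserves the count
  c3 <- count_plate(0.7 * img + 0.1, cfg)
  expect_identical(c3$result$count, c1$result$count)
})

test_that("features outside the well are never counted", {
  img <- make_plate_image(15, size_px = 256, margin_px = 14, seed = 35)
  ## dark blob well outside the well ellipse (corner)
  xg <- matrix(seq_len(256) - 20, 256, 256); yg <- t(matrix(seq_len(256) - 20, 256, 256))
  img2 <- pmin(pmax(img - 0.5 * exp(-(xg^2 + yg^2) / 8), 0), 1)
  dim(img2) <- dim(img)
  cp <- count_plate(img2, plate_config(sigma = 2, min_area = 12))
  expect_equal(cp$result$count, 15L)
  expect_true(all(inside_ellipse(cp$well, cp$result$centroids$x,
                                 cp$result$centroids$y)))
})
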