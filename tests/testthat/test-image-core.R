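test_that("HSB gate is inclusive on the 0-255 scale", {
  px <- function(h, s, b) {
    rgb <- array(0, c(1, 1, 3))
    cols <- grDevices::col2rgb(grDevices::hsv(h / 255, s / 255, b / 255))
    for (k in 1:3) rgb[1, 1, k] <- cols[k]
    section_image(rgb, 1)
  }
  gate <- hsb_range(140, 200, 10, 255, 0, 255)
  expect_true(hsb_threshold(px(150, 128, 200), gate)$mask[1, 1])
  expect_false(hsb_threshold(px(139, 128, 200), gate)$mask[1, 1])
  expect_false(hsb_threshold(px(150, 0, 200), gate)$mask[1, 1])  # sat below
  expect_error(hsb_range(-1, 100), "0, 255")
})

test_that("widening an HSB gate never removes pixels (monotonicity)", {
  set.seed(11)
  rgb <- array(runif(48 * 48 * 3) * 255, c(48, 48, 3))
  img <- section_image(rgb, 1)
  narrow <- hsb_threshold(img, hsb_range(80, 160, 40, 200, 40, 200))
  wide <- hsb_threshold(img, hsb_range(60, 180, 20, 255, 20, 255))
  expect_true(all(wide$mask[narrow$mask]))
})

test_that("auto thresholds equal their exhaustive brute-force criteria", {
  set.seed(42)
  for (i in 1:20) {
    img <- matrix(pmin(pmax(round(c(rnorm(2048, 50, 10 + i),
                                    rnorm(2048, 200, 10 + i))), 0), 255), 64, 64)
    h <- hist256_oracle(img)
    expect_identical(attr(auto_threshold(img, "default_isodata"), "threshold"),
                     bf_isodata(h))
    expect_identical(attr(auto_threshold(img, "yen"), "threshold"), bf_yen(h))
    expect_identical(attr(auto_threshold(img, "triangle"), "threshold"),
                     bf_triangle(h))
    expect_identical(attr(auto_threshold(img, "moments"), "threshold"),
                     bf_moments_numeric(h))
  }
})

test_that("every method separates a two-level image exactly", {
  img <- matrix(rep(c(20, 220), each = 2048), 64, 64)
  for (m in c("default_isodata", "yen", "triangle", "moments")) {
    mask <- auto_threshold(img, m)$mask
    expect_identical(mask, img > 100, label = m)
  }
  expect_error(auto_threshold(matrix(7, 8, 8), "yen"), "degenerate")
})

test_that("thresholds on a bimodal mixture land between the modes", {
  set.seed(1)
  img <- matrix(pmin(pmax(round(c(rnorm(2048, 50, 10),
                                  rnorm(2048, 200, 10))), 0), 255), 64, 64)
  truth <- rep(c(FALSE, TRUE), each = 2048)
  for (m in c("default_isodata", "yen", "triangle", "moments")) {
    t <- attr(auto_threshold(img, m), "threshold")
    expect_gt(t, 50); expect_lt(t, 200)
    miscls <- mean((as.vector(img) > t) != truth)
    expect_lt(miscls, 0.02)
  }
})

test_that("rolling-ball subtraction flattens backgrounds, keeps small features", {
  expect_equal(max(rolling_ball_subtract(matrix(100, 64, 64), 20)), 0)
  grad <- matrix(rep(seq(50, 100, length.out = 128), each = 128), 128, 128)
  img <- grad
  spots <- list(c(30, 30), c(90, 64), c(50, 100))
  for (p in spots) img[(p[1] - 2):(p[1] + 2), (p[2] - 2):(p[2] + 2)] <-
      img[p[1], p[2]] + 50
  rb <- rolling_ball_subtract(img, 25)
  for (p in spots)
    expect_equal(rb[p[1], p[2]], 50, tolerance = 0.1)
  expect_true(all(rb >= 0))
  expect_error(rolling_ball_subtract(grad, 0), "radius")
})

test_that("filters behave on constants, impulses, and obey the unsharp formula", {
  const <- matrix(42, 32, 32)
  expect_equal(median_filter(const, 1), const)
  expect_equal(gaussian_blur(const, 3), const, tolerance = 1e-6)
  expect_equal(unsharp_mask(const, 2, 0.6), const, tolerance = 1e-6)

  imp <- matrix(0, 32, 32); imp[16, 16] <- 255
  expect_equal(max(median_filter(imp, 1)), 0)

  set.seed(3)
  img <- matrix(rep(1:64, each = 64), 64, 64) * 2
  img[20:24, 40:44] <- img[20:24, 40:44] + 60
  expect_equal(unsharp_mask(img, 2, 0.6),
               (img - 0.6 * gaussian_blur(img, 2)) / 0.4, tolerance = 1e-9)

  g <- matrix(runif(128 * 128) * 255, 128)
  expect_lt(abs(mean(gaussian_blur(g, 3)) - mean(g)) / mean(g), 0.005)
})

test_that("filters commute with translation away from borders", {
  set.seed(5)
  img <- matrix(runif(80 * 80) * 255, 80, 80)
  shift <- function(m, d) rbind(m[(d + 1):nrow(m), ], m[1:d, ])
  inner <- 20:60
  for (f in list(function(x) median_filter(x, 1),
                 function(x) gaussian_blur(x, 2))) {
    a <- f(shift(img, 7))[inner, inner]
    b <- shift(f(img), 7)[inner, inner]
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("skeleton topology counts branches and junctions", {
  bar <- matrix(FALSE, 21, 21); bar[11, 3:19] <- TRUE
  s1 <- skeleton_stats(binary_mask(bar))
  expect_equal(s1$n_branches, 1L); expect_equal(s1$n_junctions, 0L)

  plus <- matrix(FALSE, 21, 21)
  plus[11, 3:19] <- TRUE; plus[3:19, 11] <- TRUE
  s2 <- skeleton_stats(binary_mask(plus))
  expect_equal(s2$n_branches, 4L); expect_equal(s2$n_junctions, 1L)

  # 2 x 2 grid of segments: 4 junction sites at the crossings
  grid <- matrix(FALSE, 31, 31)
  grid[c(10, 20), 4:28] <- TRUE
  grid[4:28, c(10, 20)] <- TRUE
  s3 <- skeleton_stats(binary_mask(grid))
  expect_equal(s3$n_junctions, 4L)
  expect_equal(s3$n_branches, 12L)  # 4 horizontal + 4 vertical stubs + 4 inner

  s0 <- skeleton_stats(binary_mask(matrix(FALSE, 5, 5)))
  expect_equal(s0$n_branches, 0L); expect_equal(s0$n_junctions, 0L)

  # a thick bar is thinned to a single 1-px branch
  thick <- matrix(FALSE, 30, 30); thick[12:18, 4:26] <- TRUE
  st <- skeleton_stats(binary_mask(thick))
  expect_equal(st$n_branches, 1L)
  nb <- sum(st$skeleton$mask)
  expect_lt(nb, 30)  # roughly 1-px wide path
})

test_that("particle analysis excludes border components and fills holes", {
  m <- matrix(FALSE, 40, 40)
  m[5:15, 5:15] <- TRUE; m[8:12, 8:12] <- FALSE  # square with a hole
  m[1:6, 30:39] <- TRUE                          # touches the border
  parts <- analyze_particles(binary_mask(m))
  expect_equal(parts$n, 1L)
  expect_equal(parts$areas_px, 11 * 11)          # hole included
  parts2 <- analyze_particles(binary_mask(m), include_holes = FALSE)
  expect_equal(parts2$areas_px, 11 * 11 - 25)
})
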