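test_that("scar fraction is recovered from synthetic trichrome sections", {
  gs <- gen_section(section_sim_spec(image_size = 400,
                                     scar_fraction_target = 0.30,
                                     hue_jitter = 10, seed = 2))
  sf <- scar_area_fraction(gs$image)
  expect_equal(sf$fraction, 0.30, tolerance = 0.02 / 0.30)
  expect_true(abs(sf$fraction - gs$true_scar_fraction) <= 0.02)

  g0 <- gen_section(section_sim_spec(image_size = 200, scar_fraction_target = 0))
  expect_equal(scar_area_fraction(g0$image)$fraction, 0)

  # fraction invariant to pixel size; areas scale with its square
  img2 <- section_image(gs$image$rgb, gs$image$pixel_size * 2)
  sf2 <- scar_area_fraction(img2)
  expect_equal(sf2$fraction, sf$fraction)
  expect_equal(sf2$tissue_area, 4 * sf$tissue_area)

  blank <- section_image(array(255, c(32, 32, 3)), 1)
  expect_error(scar_area_fraction(blank), "tissue area is zero")
})

test_that("stack scar fraction is the unweighted mean over levels", {
  targets <- c(0.1, 0.2, 0.3, 0.2, 0.1, 0.3)
  secs <- lapply(seq_along(targets), function(i)
    gen_section(section_sim_spec(image_size = 200,
                                 scar_fraction_target = targets[i],
                                 seed = i))$image)
  st <- stack_scar_fraction(section_stack(secs))
  expect_equal(st$mean_fraction_percent, 20, tolerance = 0.1)
  expect_equal(nrow(st$per_level), 6)

  # permutation invariance of the mean
  st2 <- stack_scar_fraction(section_stack(secs[c(3, 1, 6, 2, 5, 4)]))
  expect_equal(st2$mean_fraction_percent, st$mean_fraction_percent)

  one <- gen_section(section_sim_spec(image_size = 150,
                                      scar_fraction_target = 0.25, seed = 9))$image
  expect_warning(s1 <- stack_scar_fraction(section_stack(rep(list(one), 3))),
                 "6 levels")
  expect_equal(s1$per_level$fraction[1], s1$per_level$fraction[2])
})

test_that("heart size recovers the analytic disk area", {
  # blur sigma must be small relative to the section radius (as it is for
  # the full-resolution scans the recipe was written for)
  sec <- disk_section(2100, 1000, pixel_size = 0.5)
  hs <- heart_size(sec, sigma = 4)
  expect_equal(hs$area_um2, pi * 500^2, tolerance = 0.02)
})

test_that("heart size includes internal holes and rejects border sections", {
  sec <- disk_section(900, 360, pixel_size = 0.5, hole_r = 120)
  hs <- heart_size(sec, sigma = 3)
  full_disk <- pi * (360 * 0.5)^2
  holed <- full_disk - pi * (120 * 0.5)^2
  expect_gt(hs$area_um2, 0.97 * full_disk)   # hole was included
  expect_gt(hs$area_um2, holed * 1.1)

  border <- disk_section(400, 150, pixel_size = 1, center = c(200, 60))
  expect_error(heart_size(border, sigma = 3), "border")
})

test_that("wall thickness measures the annulus width at five points", {
  s <- 600
  x <- matrix(rep(1:s, each = s), s, s); y <- matrix(rep(1:s, s), s, s)
  ctr <- (s + 1) / 2
  d2 <- (x - ctr)^2 + (y - ctr)^2
  annulus <- d2 <= 250^2 & d2 >= 200^2
  wt <- wall_thickness(binary_mask(annulus, 2), binary_mask(annulus, 2))
  expect_length(wt, 5)
  expect_true(all(abs(wt - 100) <= 2))  # 1 px at 2 um/px

  disk <- d2 <= 250^2
  wt2 <- wall_thickness(binary_mask(disk, 2), binary_mask(disk, 2))
  expect_true(all(abs(wt2 - 500) <= 2))

  # scar restricted to a 90-degree arc: all rays fall inside that arc
  theta <- atan2(y - ctr, x - ctr)
  arc <- annulus & theta >= 0 & theta <= pi / 2
  wt3 <- wall_thickness(binary_mask(disk, 2), binary_mask(arc, 2))
  expect_true(all(abs(wt3 - 500) <= 2))  # rays hit the full disk
  expect_error(wall_thickness(binary_mask(disk, 2),
                              binary_mask(matrix(FALSE, s, s), 2)),
               "empty scar")
})

test_that("Evans-blue unstained fraction averages over four levels", {
  ge <- gen_section(section_sim_spec(image_size = 300,
                                     scar_fraction_target = 0.25, seed = 4),
                    mode = "evans")
  ev <- evans_blue_infarct(section_stack(rep(list(ge$image), 4)))
  expect_equal(ev$mean_unstained_percent, 25, tolerance = 2 / 25)
  expect_equal(ev$per_level$unstained_fraction[1],
               ev$per_level$unstained_fraction[3])

  full <- gen_section(section_sim_spec(image_size = 200,
                                       scar_fraction_target = 0, seed = 5),
                      mode = "evans")
  expect_warning(e0 <- evans_blue_infarct(section_stack(rep(list(full$image), 3))),
                 "4 levels")
  expect_equal(e0$mean_unstained_percent, 0, tolerance = 0.01)
})

test_that("birefringence hue fractions recover planted compositions", {
  # build an image whose four hue populations have prescribed pixel shares
  comp <- c(red = 0.50, orange = 0.30, yellow = 0.15, green = 0.05)
  hues <- c(red = 6, orange = 20, yellow = 40, green = 80)
  n <- 40000
  counts <- round(comp * n)
  hs <- rep(hues, counts)
  cols <- t(grDevices::col2rgb(grDevices::hsv(hs / 255, 0.7, 0.8)))
  rgb <- array(255, c(200, 200, 3))
  for (k in 1:3) rgb[, , k] <- matrix(cols[, k], 200, 200)
  prof <- birefringence_hue_fractions(section_image(rgb, 1))
  expect_equal(sum(prof$fractions_percent), 100, tolerance = 1e-6)
  expect_equal(unname(prof$fractions_percent),
               unname(comp * 100), tolerance = 0.02)

  # single-hue image: 100% in one bin
  rgb1 <- array(0, c(50, 50, 3))
  c1 <- grDevices::col2rgb(grDevices::hsv(5 / 255, 0.7, 0.8))
  for (k in 1:3) rgb1[, , k] <- c1[k]
  p1 <- birefringence_hue_fractions(section_image(rgb1, 1))
  expect_equal(unname(p1$fractions_percent["red"]), 100)

  blank <- section_image(array(255, c(20, 20, 3)), 1)
  expect_error(birefringence_hue_fractions(blank), "zero total birefringent")
})
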