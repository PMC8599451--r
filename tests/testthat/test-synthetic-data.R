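test_that("ECG generator places the prescribed beats with exact truth", {
  g <- gen_ecg(ecg_sim_spec(heart_rate = 60, duration = 10,
                            noise_sd = 0, baseline_wander_amp = 0))
  expect_equal(nrow(g$truth), 10)
  expect_equal(g$truth$r_amp, rep(1.0, 10), tolerance = 1e-4)
  expect_equal(g$truth$q_amp, rep(-0.2, 10), tolerance = 5e-3)

  g2 <- gen_ecg(ecg_sim_spec(heart_rate = 480, duration = 60, noise_sd = 0))
  expect_true(abs(nrow(g2$truth) - 480) <= 1)
})

test_that("generators are deterministic in the seed", {
  a <- gen_ecg(ecg_sim_spec(snr_db = 10, seed = 7))
  b <- gen_ecg(ecg_sim_spec(snr_db = 10, seed = 7))
  c <- gen_ecg(ecg_sim_spec(snr_db = 10, seed = 8))
  expect_identical(a$trace$voltage, b$trace$voltage)
  expect_false(identical(a$trace$voltage, c$trace$voltage))

  s1 <- gen_section(section_sim_spec(image_size = 128, hue_jitter = 8, seed = 3))
  s2 <- gen_section(section_sim_spec(image_size = 128, hue_jitter = 8, seed = 3))
  expect_identical(s1$image$rgb, s2$image$rgb)

  e1 <- gen_expression(expr_block_fixture(5))
  e2 <- gen_expression(expr_block_fixture(5))
  expect_identical(e1$matrix, e2$matrix)

  m1 <- gen_multichannel(cell_field_spec(n_nuclei = 30, seed = 4))
  m2 <- gen_multichannel(cell_field_spec(n_nuclei = 30, seed = 4))
  expect_identical(m1$stack$channels, m2$stack$channels)
})

test_that("section generator renders the target scar fraction and area", {
  gs <- gen_section(section_sim_spec(image_size = 400,
                                     scar_fraction_target = 0.30,
                                     hue_jitter = 0))
  expect_true(abs(gs$true_scar_fraction - 0.30) <= 0.01)

  g0 <- gen_section(section_sim_spec(image_size = 200, scar_fraction_target = 0))
  scar_px <- hsb_threshold(g0$image, morphometry_gates()$scar)
  expect_equal(sum(scar_px$mask), 0)

  # disk radius 100 px at 5 um/px -> pi * (500 um)^2
  gd <- gen_section(section_sim_spec(image_size = 256, pixel_size = 5,
                                     disk_radius_px = 100,
                                     scar_fraction_target = 0.2))
  expect_equal(gd$true_tissue_area, pi * 500^2, tolerance = 0.02)

  expect_error(section_sim_spec(scar_fraction_target = 1.2), "scar_fraction_target")
})

test_that("fiber generator hits the target waviness and orientation spread", {
  gf <- gen_fiber_field(fiber_field_spec(n_fibers = 60, target_waviness = 1.5,
                                         seed = 2))
  per_fiber <- vapply(split(gf$traces, gf$traces$fiber_id),
                      function(d) waviness(d$x, d$y), numeric(1))
  expect_true(all(abs(per_fiber - 1.5) <= 0.02 * 1.5))
  expect_true(mean(per_fiber) >= 1.47 && mean(per_fiber) <= 1.53)

  g1 <- gen_fiber_field(fiber_field_spec(n_fibers = 10, target_waviness = 1))
  pf <- vapply(split(g1$traces, g1$traces$fiber_id),
               function(d) waviness(d$x, d$y), numeric(1))
  expect_equal(unname(pf), rep(1, 10))

  gk <- gen_fiber_field(fiber_field_spec(n_fibers = 200, orientation_kappa = 50,
                                         seed = 3))
  a2 <- 2 * gk$angles_deg * pi / 180
  circ_var <- 1 - sqrt(mean(cos(a2))^2 + mean(sin(a2))^2)
  expect_lt(circ_var, 0.05)

  expect_error(fiber_field_spec(target_waviness = 0.9), "target_waviness")
})

test_that("fractal patterns carry their analytic dimensions", {
  expect_equal(gen_fractal_pattern("line")$theoretical_dimension, 1.0)
  expect_equal(gen_fractal_pattern("filled_square")$theoretical_dimension, 2.0)
  sp <- gen_fractal_pattern("sierpinski_triangle", depth = 7)
  expect_equal(sp$theoretical_dimension, log(3) / log(2))
  expect_equal(sum(sp$mask$mask), 3^7)  # exactly 3^depth filled cells
  expect_error(gen_fractal_pattern("line", depth = 0), "depth")
})

test_that("multichannel generator renders exact marker counts", {
  gm <- gen_multichannel(cell_field_spec(n_nuclei = 100,
                                         marker_fractions = c(edu = 0.04),
                                         seed = 5))
  expect_equal(gm$truth$markers$edu$positive_cm, 4)
  expect_equal(sum(gm$stack$channels$edu > 0) > 0, TRUE)

  g0 <- gen_multichannel(cell_field_spec(n_nuclei = 50,
                                         marker_fractions = c(edu = 0),
                                         seed = 5))
  expect_equal(max(g0$stack$channels$edu), 0)

  gv <- gen_multichannel(cell_field_spec(
    n_nuclei = 0, marker_fractions = NULL, wga_band_fraction = 0.5,
    vessel_diameters_um = c(8, 12, 20), pixel_size = 0.5, seed = 8))
  expect_equal(sort(gv$truth$vessels$diameter_um), c(8, 12, 20))
  expect_true(all(gv$truth$vessels$in_scar))

  expect_error(
    gen_multichannel(cell_field_spec(n_nuclei = 4000, image_size = 128)),
    "cannot place")
})

test_that("expression generator plants recoverable group effects", {
  # one set with +2 log2 between ages in mus only -> ratio ~4 in mus, ~1 in acomys
  spec <- expr_sim_spec(n_genes = 300, baseline_meanlog = 5, dispersion = 0,
                        maturation_gene_sets = list(s = 1:20),
                        effect_log2fc = list(s = c(mus = 2, acomys = 0)),
                        seed = 2)
  ge <- gen_expression(spec)
  grp <- function(sp, age) rowMeans(ge$matrix[1:20, ge$samples$species == sp &
                                                ge$samples$age == age])
  expect_equal(mean(grp("mus", "adult") / grp("mus", "neonate")), 4, tolerance = 1e-6)
  expect_equal(mean(grp("acomys", "adult") / grp("acomys", "neonate")), 1,
               tolerance = 1e-6)
  # 4 groups x 3 samples -> 12 columns
  spec12 <- expr_sim_spec(n_genes = 50, groups = data.frame(
    species = rep(c("a", "b"), each = 2), age = rep(c("n", "ad"), 2),
    n_samples = 3), seed = 1)
  expect_equal(ncol(gen_expression(spec12)$matrix), 12)
  expect_error(expr_sim_spec(groups = data.frame()), "empty")
})
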