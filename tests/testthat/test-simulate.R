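test_that("cumulative retardation follows 2*pi*dn*z/lambda at depth", {
  # n = 1 and 2.5-um pixels put physical depth 650 um exactly on the grid:
  # delta = 2*pi * 1e-4 * 650e-6 / 1.3e-6 rad = 0.31416 rad = 18.0 deg
  cfg <- imaging_config(axial_pixel_spacing_um = 2.5, depth_pixels = 512,
                        lateral_pixels = 4)
  slab <- slab_model(delta_n = 1e-4, refractive_index = 1)
  bs <- simulate_bscan(slab, cfg, noise_off(), surface_standoff_um = 0)
  expect_equal(bs$retardation[1 + 260, 1], 18, tolerance = 1e-12)
  # and inside a medium of n = 1.4 the same physical depth maps to pixel
  # round(n * z / spacing)
  cfg2 <- imaging_config(axial_pixel_spacing_um = 2.275, depth_pixels = 512,
                         lateral_pixels = 4)
  slab2 <- slab_model(delta_n = 1e-4, refractive_index = 1.4)
  bs2 <- simulate_bscan(slab2, cfg2, noise_off(), surface_standoff_um = 0)
  expect_equal(bs2$retardation[1 + 400, 1], 18, tolerance = 1e-12)  # 910/2.275
})

test_that("intensity decays as Beer-Lambert with the layer attenuation coefficient", {
  cfg <- imaging_config(axial_pixel_spacing_um = 2.5, depth_pixels = 512,
                        lateral_pixels = 4)
  slab <- slab_model(delta_n = 0, attenuation_mm = 1.5, refractive_index = 1)
  bs <- simulate_bscan(slab, cfg, noise_off(), surface_standoff_um = 0)
  expect_equal(bs$intensity[1 + 400, 1] / bs$intensity[1, 1], exp(-1.5),
               tolerance = 1e-12)  # 1 mm at 1.5 /mm
})

test_that("multi-layer attenuation accumulates per-layer path", {
  cfg <- imaging_config(axial_pixel_spacing_um = 2.5, depth_pixels = 600,
                        lateral_pixels = 2)
  m <- sample_model(list(
    layer_spec("a", 500, 0.8),
    layer_spec("b", 400, 3.5)
  ), refractive_index = 1)
  bs <- simulate_bscan(m, cfg, noise_off(), surface_standoff_um = 0)
  # at 800 um: 500 um through mu=0.8 plus 300 um through mu=3.5
  expect_equal(bs$intensity[1 + 320, 1], exp(-(0.5 * 0.8 + 0.3 * 3.5)),
               tolerance = 1e-12)
})

test_that("zero birefringence gives an identically zero retardation map", {
  cfg <- small_config()
  bs <- simulate_bscan(slab_model(delta_n = 0), cfg, noise_off())
  expect_true(all(bs$retardation == 0))
})

test_that("retardation is nondecreasing with depth before the fold", {
  cfg <- small_config(depth_pixels = 512)
  bs <- simulate_bscan(slab_model(delta_n = 1e-4), cfg, noise_off())
  s <- attr(bs, "surface_row")[1]
  col <- bs$retardation[s:512, 1]
  expect_true(all(diff(col) >= -1e-12))
  expect_lt(max(col), 90)
})

test_that("the retardation channel never leaves [0, 90] under any noise", {
  cfg <- small_config(depth_pixels = 128, lateral_pixels = 32)
  bs <- simulate_bscan(
    slab_model(delta_n = 2.1e-4), cfg,
    noise_model(retardation_noise_sd_deg = 45, seed = 3)
  )
  expect_gte(min(bs$retardation), 0)
  expect_lte(max(bs$retardation), 90)
})

test_that("folding reflects at 0 and 90 like a triangle wave", {
  expect_equal(fold_retardation(c(-10, 18, 100, 180, 200)),
               c(10, 18, 80, 0, 20))
  x <- seq(-400, 400, by = 7.3)
  f <- fold_retardation(x)
  expect_true(all(f >= 0 & f <= 90))
  expect_equal(fold_retardation(-x), f)  # even function
})

test_that("identical seeds give bit-identical B-scans, different seeds differ", {
  cfg <- small_config(depth_pixels = 96, lateral_pixels = 16)
  m <- slab_model()
  a <- simulate_bscan(m, cfg, noise_model(seed = 11))
  b <- simulate_bscan(m, cfg, noise_model(seed = 11))
  c <- simulate_bscan(m, cfg, noise_model(seed = 12))
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$retardation, b$retardation)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("simulation does not disturb the caller's RNG stream", {
  cfg <- small_config(depth_pixels = 64, lateral_pixels = 8)
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_bscan(slab_model(), cfg, noise_model(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("speckle is multiplicative with unit mean", {
  cfg <- small_config(depth_pixels = 64, lateral_pixels = 32)
  m <- slab_model(delta_n = 0, attenuation_mm = 1.0)
  clean <- simulate_bscan(m, cfg, noise_off())
  s <- attr(clean, "surface_row")[1]
  rows <- s:64
  acc <- matrix(0, length(rows), 32)
  nseeds <- 120
  for (k in seq_len(nseeds)) {
    sp <- simulate_bscan(m, cfg, noise_model(
      speckle_enabled = TRUE, retardation_noise_sd_deg = 0, seed = k
    ))
    acc <- acc + sp$intensity[rows, ] / clean$intensity[rows, ]
  }
  ratio <- acc / nseeds
  expect_equal(mean(ratio), 1, tolerance = 0.02)
  expect_true(all(abs(rowMeans(ratio) - 1) < 0.1))
})

test_that("pixels above the surface carry background intensity only", {
  cfg <- small_config()
  bs <- simulate_bscan(slab_model(), cfg,
                       noise_model(seed = 1, background_level = 5e-4),
                       surface_standoff_um = 200)
  s <- attr(bs, "surface_row")[1]
  expect_true(all(bs$intensity[seq_len(s - 1L), ] == 5e-4))
})

test_that("a stack too deep for the imaging window errors when truncation is disallowed", {
  cfg <- small_config(depth_pixels = 64)
  expect_error(
    simulate_bscan(slab_model(thickness_um = 2000), cfg, noise_off(),
                   allow_truncated_bottom = FALSE),
    "deeper"
  )
  expect_error(noise_model(retardation_noise_sd_deg = -1), ">= 0")
  expect_error(noise_model(background_level = -1), ">= 0")
})

test_that("manipulation scenes scale birefringence only inside the affected region", {
  base <- slab_model(delta_n = 1.01e-4, thickness_um = 600)
  scene <- simulate_manipulation_scene(base, site_column = 32,
                                       affected_halfwidth = 10,
                                       delta_n_factor = 1.386,
                                       lateral_pixels = 64)
  expect_equal(sum(scene$delta_n_factor > 1), 21)
  cfg <- small_config(depth_pixels = 512, lateral_pixels = 64)
  bs <- simulate_bscan(scene, cfg, noise_off())
  seg <- detect_surfaces(bs)
  flat <- flatten(bs, seg)
  at_site <- fit_birefringence(
    lateral_average(flat, columns = 23:42), cfg
  )$delta_n
  away <- fit_birefringence(
    lateral_average(flat, columns = 45:64), cfg
  )$delta_n
  expect_equal(at_site, 1.01e-4 * 1.386, tolerance = 1e-6)
  expect_equal(away, 1.01e-4, tolerance = 1e-6)
  # factor 1 reduces to the uniform model
  flat1 <- simulate_manipulation_scene(base, 32, 10, 1, 64)
  expect_true(all(flat1$delta_n_factor == 1))
  expect_error(simulate_manipulation_scene(base, 99, 10, 1.4, 64), "outside")
  expect_error(simulate_manipulation_scene(base, 32, 10, 0.9, 64), ">= 1")
})
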