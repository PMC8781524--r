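test_that("Otsu separates a two-point histogram between its modes", {
  h <- numeric(256)
  h[10 + 1] <- 40   # bin value 10
  h[200 + 1] <- 60  # bin value 200
  t <- otsu_threshold(h)
  expect_gt(t, 10)
  expect_lte(t, 200)
  # the induced classes are exactly {10} and {200}
  expect_true(all(which(h > 0) - 1 < t | which(h > 0) - 1 >= t))
  expect_equal(sum(h[seq_len(t)]), 40)
})

test_that("Otsu equals exhaustive between-class-variance maximization", {
  set.seed(42)
  for (i in 1:200) {
    nb <- sample(c(16L, 64L, 256L), 1)
    h <- numeric(nb)
    occupied <- sample(nb, sample(2:nb, 1))
    h[occupied] <- rpois(length(occupied), lambda = sample(1:50, 1)) + 1
    expect_identical(otsu_threshold(h), otsu_oracle(h))
  }
})

test_that("mirrored histograms have co-optimal mirrored thresholds; the lower wins", {
  set.seed(7)
  h <- rpois(256, 3)
  hs <- h + rev(h)  # symmetric about bin 127.5
  t <- otsu_threshold(hs)
  tm <- 256L - t
  expect_equal(between_class_variance(hs, t), between_class_variance(hs, tm),
               tolerance = 1e-9)
  expect_lte(t, tm)
})

test_that("single-valued images and degenerate histograms are rejected", {
  expect_error(otsu_threshold(c(0, 5, 0, 0)), "fewer than two")
  img <- matrix(1, 8, 8)
  pair <- psoct:::new_bscan_pair(img, img * 0, small_config(8L, 8L))
  expect_error(detect_surfaces(pair, use_log = FALSE), "separable")
})

test_that("the 3x3 median network matches a direct median computation", {
  set.seed(5)
  x <- matrix(rnorm(30 * 17), 30, 17)
  fast <- psoct:::median3x3(x)
  pad <- rbind(x[1, ], x, x[nrow(x), ])
  pad <- cbind(pad[, 1], pad, pad[, ncol(pad)])
  slow <- x
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      slow[i, j] <- median(pad[i:(i + 2), j:(j + 2)])
    }
  }
  expect_equal(fast, slow)
})

test_that("a flat noise-free surface is detected at its exact row in every column", {
  # standoff 97.5 um at 2.5 um/px puts the surface at row 40
  cfg <- imaging_config(axial_pixel_spacing_um = 2.5, depth_pixels = 256,
                        lateral_pixels = 32)
  bs <- simulate_bscan(slab_model(thickness_um = 400, refractive_index = 1),
                       cfg, noise_off(), surface_standoff_um = 97.5)
  seg <- detect_surfaces(bs)
  expect_true(all(seg$valid))
  expect_true(all(seg$top == 40))
  # slab bottom: 400 um = 160 px below the surface
  expect_true(all(seg$bottom == 40 + 160))
})

test_that("whole-pixel surface profiles are recovered exactly on noise-free slabs", {
  set.seed(31)
  dz <- 2.75
  for (rep in 1:5) {
    offs <- dz * sample(0:15, 24, replace = TRUE)
    cfg <- imaging_config(depth_pixels = 256, lateral_pixels = 24)
    m <- slab_model(thickness_um = 300)
    m$surface_profile <- offs
    bs <- simulate_bscan(m, cfg, noise_off(), surface_standoff_um = 2 * dz)
    seg <- detect_surfaces(bs, smoothing_halfwidth = 0)
    expect_identical(seg$top, attr(bs, "surface_row"))
  }
})

test_that("speckled surfaces are found within 2 px in at least 99% of columns", {
  cfg <- small_config(depth_pixels = 320, lateral_pixels = 128)
  bs <- simulate_bscan(make_bladder_model("normal"), cfg,
                       noise_model(seed = 17))
  seg <- detect_surfaces(bs)
  truth <- attr(bs, "surface_row")
  ok <- seg$valid & abs(seg$top - truth) <= 2
  expect_gte(mean(ok), 0.99)
})

test_that("columns with no suprathreshold run are flagged invalid, not fatal", {
  cfg <- small_config(depth_pixels = 40L, lateral_pixels = 4L)
  img <- matrix(1e-3, 40, 4)
  img[15:30, 1:3] <- 1  # tissue in columns 1-3 only
  pair <- psoct:::new_bscan_pair(img, img * 0, cfg)
  seg <- detect_surfaces(pair, smoothing_halfwidth = 0)
  expect_equal(seg$valid, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(is.na(seg$top[4])))
})

test_that("an invisible bottom yields a maximum detection depth instead", {
  cfg <- small_config(depth_pixels = 128)
  bs <- simulate_bscan(slab_model(thickness_um = 2000), cfg, noise_off())
  seg <- detect_surfaces(bs)
  expect_true(all(is.na(seg$bottom[seg$valid])))
  expect_true(all(seg$max_depth[seg$valid] == 128))
})

test_that("flattening makes a 1 px/column ramped surface perfectly horizontal", {
  dz <- 2.75
  cfg <- imaging_config(depth_pixels = 256, lateral_pixels = 32)
  m <- slab_model(thickness_um = 300)
  m$surface_profile <- dz * (0:31)  # 1 px per column tilt
  bs <- simulate_bscan(m, cfg, noise_off(), surface_standoff_um = 2 * dz)
  seg <- detect_surfaces(bs, smoothing_halfwidth = 0)
  expect_equal(var(seg$top), var(0:31))
  flat <- flatten(bs, seg)
  # after flattening the surface row of every column is row 1: the intensity
  # there is the (identical) surface value in all columns
  expect_equal(var(flat$intensity[1, ]), 0)
  expect_equal(flat$shifts, seg$top - 1L)
})

test_that("an already-flat input flattens with zero shifts and equal arrays", {
  cfg <- imaging_config(axial_pixel_spacing_um = 2.5, depth_pixels = 128,
                        lateral_pixels = 16)
  bs <- simulate_bscan(slab_model(thickness_um = 250, refractive_index = 1),
                       cfg, noise_off(), surface_standoff_um = 0)
  seg <- detect_surfaces(bs)
  expect_true(all(seg$top == 1))
  flat <- flatten(bs, seg, mask_below_max_depth = FALSE)
  expect_true(all(flat$shifts == 0))
  expect_equal(flat$retardation, bs$retardation)
})

test_that("unflatten inverts flatten exactly", {
  cfg <- small_config(depth_pixels = 192, lateral_pixels = 24)
  m <- slab_model(thickness_um = 350)
  m$surface_profile <- 2.75 * sample(0:10, 24, replace = TRUE)
  bs <- simulate_bscan(m, cfg, noise_model(seed = 4))
  seg <- detect_surfaces(bs)
  flat <- flatten(bs, seg)
  back <- unflatten(flat)
  expect_identical(back$intensity, bs$intensity)
  expect_identical(back$retardation, bs$retardation)
})

test_that("pixel counts convert to physical thickness through the refractive index", {
  cfg <- imaging_config()  # 2.75 um/px
  expect_equal(pixels_to_physical_thickness(0, cfg), 0)
  expect_equal(pixels_to_physical_thickness(140, cfg), 275)  # / 1.4
  expect_equal(pixels_to_physical_thickness(140, cfg, refractive_index = 1),
               140 * 2.75)
  expect_error(pixels_to_physical_thickness(10, cfg, refractive_index = 0.9),
               ">= 1")
  expect_error(pixels_to_physical_thickness(-1, cfg), ">= 0")
})
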