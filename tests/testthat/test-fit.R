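test_that("lateral averaging of a single column reproduces that column", {
  cfg <- small_config(depth_pixels = 128, lateral_pixels = 8)
  bs <- simulate_bscan(slab_model(thickness_um = 300), cfg, noise_off())
  seg <- detect_surfaces(bs)
  flat <- flatten(bs, seg)
  prof <- lateral_average(flat, columns = 3L)
  keep <- which(!is.na(flat$retardation[, 3]))
  expect_equal(prof$retardation_deg, flat$retardation[keep, 3])
  expect_equal(attr(prof, "n_columns"), 1L)
})

test_that("averaging identical columns is idempotent and counts them", {
  cfg <- small_config(depth_pixels = 128, lateral_pixels = 8)
  bs <- simulate_bscan(slab_model(thickness_um = 300), cfg, noise_off())
  flat <- flatten(bs, detect_surfaces(bs))
  one <- lateral_average(flat, columns = 2L)
  three <- lateral_average(flat, columns = c(2L, 4L, 6L))  # identical columns
  expect_equal(three$retardation_deg, one$retardation_deg)
  expect_equal(attr(three, "n_columns"), 3L)
})

test_that("a 2-mm region at 7.8 um lateral spacing averages 256 columns", {
  cfg <- imaging_config(depth_pixels = 128, lateral_pixels = 300)
  bs <- simulate_bscan(slab_model(thickness_um = 300), cfg, noise_off())
  flat <- flatten(bs, detect_surfaces(bs))
  prof <- lateral_average(flat, width_um = 2000)
  expect_equal(attr(prof, "n_columns"), 256L)
})

test_that("depth axes are strictly increasing physical micrometres", {
  cfg <- small_config(depth_pixels = 128, lateral_pixels = 8)
  bs <- simulate_bscan(slab_model(thickness_um = 300), cfg, noise_off())
  flat <- flatten(bs, detect_surfaces(bs))
  prof <- lateral_average(flat)
  expect_true(all(diff(prof$depth_um) > 0))
  expect_equal(prof$depth_um[2] - prof$depth_um[1], 2.75 / 1.4)
})

test_that("averaging with no valid columns is an error", {
  cfg <- small_config(depth_pixels = 40L, lateral_pixels = 4L)
  img <- matrix(1e-3, 40, 4)
  img[15:30, 1:2] <- 1
  pair <- psoct:::new_bscan_pair(img, img * 0, cfg)
  flat <- flatten(pair, detect_surfaces(pair, smoothing_halfwidth = 0))
  expect_error(lateral_average(flat, columns = c(3L, 4L)), "No valid columns")
})

test_that("a constant profile fits to zero birefringence", {
  prof <- tibble::tibble(depth_um = seq(0, 200, by = 2), retardation_deg = 7)
  est <- fit_birefringence(prof, imaging_config())
  expect_equal(est$delta_n, 0)
  expect_equal(est$slope_deg_per_um, 0)
})

test_that("forward simulation and slope inversion round-trip delta-n to 0.5%", {
  cfg <- small_config(depth_pixels = 512, lateral_pixels = 16)
  for (dn in c(1e-5, 5e-5, 1e-4, 2.1e-4)) {
    pair <- simulate_bscan(slab_model(delta_n = dn), cfg, noise_off())
    rec <- extract_slab_delta_n(pair, cfg, width_um = 100)
    expect_lt(abs(rec - dn) / dn, 0.005)
  }
})

test_that("recovered delta-n scales linearly with the model delta-n", {
  cfg <- small_config(depth_pixels = 512, lateral_pixels = 16)
  base <- extract_slab_delta_n(
    simulate_bscan(slab_model(delta_n = 5e-5), cfg, noise_off()), cfg, 100
  )
  for (k in c(2, 3.5)) {
    scaled <- extract_slab_delta_n(
      simulate_bscan(slab_model(delta_n = k * 5e-5), cfg, noise_off()), cfg, 100
    )
    expect_equal(scaled / base, k, tolerance = 1e-9)
  }
})

test_that("recovery is invariant to wavelength when forward and inverse agree", {
  for (wl in c(1000, 1300, 1550)) {
    cfg <- imaging_config(wavelength_nm = wl, depth_pixels = 512,
                          lateral_pixels = 16)
    pair <- simulate_bscan(slab_model(delta_n = 1e-4), cfg, noise_off())
    rec <- extract_slab_delta_n(pair, cfg, width_um = 100)
    expect_equal(rec, 1e-4, tolerance = 1e-6)
  }
})

test_that("fits stop at the retardation fold", {
  # 1500 um at 2.1e-4 reaches 87 deg of retardation; with a thicker slab the
  # profile folds and the fitted points must stay on the pre-fold branch
  cfg <- small_config(depth_pixels = 1024, lateral_pixels = 8)
  m <- slab_model(delta_n = 2.1e-4, thickness_um = 1900, attenuation_mm = 0.8)
  pair <- simulate_bscan(m, cfg, noise_off())
  flat <- flatten(pair, detect_surfaces(pair))
  prof <- lateral_average(flat, width_um = 60)
  est <- fit_birefringence(prof, cfg)
  # depth at which the noise-free phase reaches 90 deg:
  fold_depth <- 90 * 1.3 / (360 * 2.1e-4)
  expect_lte(est$fit_window_um[2], fold_depth)
  expect_equal(est$delta_n, 2.1e-4, tolerance = 0.005 * 2.1e-4)
})

test_that("noisy recovery is unbiased within 5% and tightens with lateral averaging", {
  cfg <- small_config(depth_pixels = 512, lateral_pixels = 128)
  m <- slab_model(delta_n = 1e-4)
  rec_wide <- rec_narrow <- numeric(10)
  for (s in 1:10) {
    pair <- simulate_bscan(m, cfg, noise_model(seed = s))
    seg <- detect_surfaces(pair)
    flat <- flatten(pair, seg)
    floor_deg <- 2 * estimate_retardation_noise(pair, seg)
    rec_wide[s] <- fit_birefringence(
      lateral_average(flat, columns = 1:128), cfg,
      min_retardation_deg = floor_deg
    )$delta_n
    rec_narrow[s] <- fit_birefringence(
      lateral_average(flat, columns = 1:8), cfg,
      min_retardation_deg = floor_deg
    )$delta_n
  }
  expect_lt(abs(mean(rec_wide) - 1e-4) / 1e-4, 0.05)
  expect_lt(sd(rec_wide), sd(rec_narrow))
})

test_that("negative retardation slopes give negative delta-n, unclipped", {
  prof <- tibble::tibble(depth_um = seq(0, 100, by = 2),
                         retardation_deg = 10 - 0.02 * seq(0, 100, by = 2))
  est <- fit_birefringence(prof, imaging_config())
  expect_lt(est$delta_n, 0)
  expect_equal(est$slope_deg_per_um, -0.02, tolerance = 1e-9)
})

test_that("fit preconditions are enforced", {
  cfg <- imaging_config()
  prof <- tibble::tibble(depth_um = c(10, 20), retardation_deg = c(1, 2))
  expect_error(fit_birefringence(prof, cfg), "Fewer than 3")
  expect_error(
    fit_birefringence(tibble::tibble(depth_um = 1:20,
                                     retardation_deg = rnorm(20)),
                      cfg, fit_window = c(50, 40)),
    "zmax > zmin"
  )
})

test_that("layer windows validate ordering and report absent windows", {
  expect_error(layer_windows("a", 10, 10), "non-empty")
  expect_error(layer_windows(c("a", "b"), c(0, 40), c(50, 90)), "overlap")
  cfg <- small_config(depth_pixels = 128, lateral_pixels = 16)
  pair <- simulate_bscan(slab_model(thickness_um = 200), cfg, noise_off())
  flat <- flatten(pair, detect_surfaces(pair))
  w <- layer_windows(c("near", "deep"), c(0, 5000), c(150, 5400))
  est <- layer_birefringence(flat, w, cfg)
  expect_true(is.na(est$delta_n[est$layer == "deep"]))
  expect_match(est$note[est$layer == "deep"], "max detection depth")
  expect_false(is.na(est$delta_n[est$layer == "near"]))
})

test_that("percent change reproduces the manipulation-site increases", {
  expect_equal(signif(percent_change(1.40e-4, 1.01e-4), 3), 38.6)
  expect_equal(signif(percent_change(1.37e-4, 1.01e-4), 3), 35.6)
  expect_equal(percent_change(5e-5, 5e-5), 0)
  expect_equal(percent_change(5e-5, 1e-4), -50)
  expect_error(percent_change(1e-4, 0), "non-zero")
})

test_that("estimates tidy to one-row tibbles with the fit diagnostics", {
  cfg <- small_config(depth_pixels = 256, lateral_pixels = 16)
  pair <- simulate_bscan(slab_model(thickness_um = 400), cfg, noise_off())
  flat <- flatten(pair, detect_surfaces(pair))
  est <- fit_birefringence(lateral_average(flat, width_um = 100), cfg)
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_true(all(c("delta_n", "slope_deg_per_um", "r_squared",
                    "n_points") %in% names(td)))
  gl <- glance(est)
  expect_equal(gl$n_points, est$n_points)
})
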