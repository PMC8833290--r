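test_that("zero degradation renders a constant background inside the disk", {
  vol <- render_phantom(phantom_spec("uniform", background_hu = 30),
                        degradation_spec(),
                        spacing = c(0.8, 0.8, 1), dims = c(280L, 280L, 1L))
  gt <- attr(vol, "ground_truth")
  rr <- cbctqa:::row_coords(vol)
  cc <- cbctqa:::col_coords(vol)
  d <- sqrt(outer((rr - gt$center_mm[1])^2, (cc - gt$center_mm[2])^2, `+`))
  inside <- d < gt$radius_mm - 2
  expect_true(all(vol$voxels[, , 1][inside] == 30))
  expect_true(all(vol$voxels[, , 1][d > gt$radius_mm + 2] == -1000))
})

test_that("white-noise SD and seed determinism hold", {
  vol <- noisy_uniform_volume(sigma = 20, seed = 11, n_slices = 1L)
  gt <- attr(vol, "ground_truth")
  rr <- cbctqa:::row_coords(vol)
  cc <- cbctqa:::col_coords(vol)
  d <- sqrt(outer((rr - gt$center_mm[1])^2, (cc - gt$center_mm[2])^2, `+`))
  interior <- vol$voxels[, , 1][d < gt$radius_mm - 5]
  expect_gt(length(interior), 1e5)
  expect_lt(abs(sd(interior) / 20 - 1), 0.02)

  again <- noisy_uniform_volume(sigma = 20, seed = 11, n_slices = 1L)
  expect_identical(vol$voxels, again$voxels)
  other <- noisy_uniform_volume(sigma = 20, seed = 12, n_slices = 1L)
  expect_false(identical(vol$voxels, other$voxels))
})

test_that("noise scales linearly: doubling sigma doubles the interior SD", {
  sds <- vapply(c(10, 20), function(s) {
    vol <- noisy_uniform_volume(sigma = s, seed = 3, n_slices = 1L)
    gt <- attr(vol, "ground_truth")
    rr <- cbctqa:::row_coords(vol)
    cc <- cbctqa:::col_coords(vol)
    d <- sqrt(outer((rr - gt$center_mm[1])^2, (cc - gt$center_mm[2])^2, `+`))
    sd(vol$voxels[, , 1][d < gt$radius_mm - 5])
  }, 0)
  expect_lt(abs(sds[2] / sds[1] - 2), 0.06)
})

test_that("noiseless rod centroids sit on the nominal square corners", {
  vol <- render_phantom(phantom_spec("insert", background_hu = 100),
                        degradation_spec())
  gt <- attr(vol, "ground_truth")
  nominal <- gt$rod_centers_mm
  found <- match_centers(detect_rods(vol), nominal)
  expect_lt(max(abs(found - nominal)), 0.05)
})

test_that("rendered degradations have the injected qualitative signatures", {
  deg <- degradation_spec(cupping_amplitude = 80,
                          edge_smear = c(width = 5, depth = -40),
                          double_contour = c(offset = 3, fraction = 0.1))
  vol <- render_phantom(phantom_spec("uniform"), deg)
  gt <- attr(vol, "ground_truth")
  sl <- vol$voxels[, , 1]
  rr <- cbctqa:::row_coords(vol)
  cc <- cbctqa:::col_coords(vol)
  d <- sqrt(outer((rr - gt$center_mm[1])^2, (cc - gt$center_mm[2])^2, `+`))
  ctr_val <- mean(sl[d < 5])
  mid_val <- mean(sl[abs(d - 0.7 * gt$radius_mm) < 1])
  expect_gt(mid_val - ctr_val, 80 * 0.49 * 0.9)  # parabola at 0.7 R
  # rim smear pulls the last 5 mm down
  rim_val <- mean(sl[abs(d - (gt$radius_mm - 0.5)) < 0.4])
  expect_lt(rim_val - ctr_val, 80)  # smear offsets part of the cupping rise
  # ghost contour is a local bump at R - offset
  ghost <- mean(sl[abs(d - (gt$radius_mm - 3)) < 0.3])
  inner <- mean(sl[abs(d - (gt$radius_mm - 8)) < 0.3])
  expect_gt(ghost, inner + 20)
})

test_that("noiseless slanted edge matches the analytic Gaussian ESF", {
  vol <- render_edge(list(angle = 3, low_hu = 0, high_hu = 1000),
                     blur_sigma = 0.5, noise_sigma = 0)
  gt <- attr(vol, "ground_truth")
  th <- 3 * pi / 180
  rr <- cbctqa:::row_coords(vol)
  cc <- cbctqa:::col_coords(vol)
  d <- outer(-(rr - gt$center_mm[1]) * sin(th),
             (cc - gt$center_mm[2]) * cos(th), `+`)
  expected <- 1000 * pnorm(d / 0.5)
  expect_lt(max(abs(vol$voxels[, , 1] - expected)), 0.5)
})

test_that("sharp edge renders pure plateaus and angle is recoverable", {
  vol <- render_edge(list(angle = 3, low_hu = 0, high_hu = 1000),
                     blur_sigma = 0, noise_sigma = 0)
  v <- vol$voxels[, , 1]
  expect_true(all(v %in% c(0, 500, 1000)))
  expect_lt(mean(v == 500), 0.01)   # only the sub-pixel boundary line

  blurred <- render_edge(list(angle = 3, low_hu = 0, high_hu = 1000),
                         blur_sigma = 0.5, noise_sigma = 0)
  esf <- build_oversampled_esf(blurred)
  expect_lt(abs(esf$angle_deg - 3), 0.1)
  expect_warning(render_edge(list(angle = 0, low_hu = 0, high_hu = 100),
                             blur_sigma = 0.3), "phase diversity")
})

test_that("calibration simulator honours its deterministic skeleton", {
  spec <- calibration_sim_spec(n_runs = 3, mod_amplitude = 0, fluct_sd = 0,
                               hysteresis = 0,
                               offsets = c(tSx = 1, tSy = 2, tSz = 3, tCx = 4,
                                           tCy = 5, tCz = 6, rx = 0.1,
                                           ry = 0.2, rz = 0.3))
  recs <- simulate_calibration_runs(spec)
  expect_length(recs, 6L)
  for (r in recs)
    expect_equal(unname(r$corrections),
                 matrix(rep(c(1:6, 0.1, 0.2, 0.3), each = 53), 53, 9),
                 tolerance = 1e-12)
})

test_that("injected fluctuation SD and hysteresis are recovered", {
  spec <- calibration_sim_spec(n_runs = 8, seed = 5,
                               fluct_sd = c(tCz = 2.1), mod_amplitude = 0,
                               hysteresis = c(tSz = 4.6))
  recs <- simulate_calibration_runs(spec)
  st <- calibration_stats(recs)
  # pooled per-angle SD estimate within the n = 8 chi-square spread
  est <- st$summary$mean_angle_sd[st$summary$correction == "tCz" &
                                    st$summary$direction == "cw"]
  expect_lt(abs(est / 2.1 - 1), 0.35)
  # mean |CW - CCW| close to the injected hysteresis
  expect_lt(abs(mean(st$hysteresis[, "tSz"]) - 4.6), 0.5)
  expect_lt(max(abs(colMeans(st$hysteresis)[c("tSx", "tCy", "rz")])), 0.5)
})

test_that("simulated DLP tables invert the dose-index formula", {
  tab <- simulate_dlp(10, peripheral_to_central_ratio = 1, noise_cv = 0)
  expect_equal(tab$dlp_mGy_cm, rep(100, 5))
  tab23 <- simulate_dlp(7.5, peripheral_to_central_ratio = 2.3, noise_cv = 0)
  res <- cbdi_w(tab23)
  expect_equal(res$cbdi_w, 7.5, tolerance = 1e-12)
  expect_equal(res$peripheral_to_central_ratio, 2.3, tolerance = 1e-12)
})

test_that("noisy DLP simulation is unbiased for the dose index", {
  ests <- vapply(1:300, function(s)
    cbdi_w(simulate_dlp(10, 1.5, noise_cv = 0.05, seed = s))$cbdi_w, 0)
  expect_lt(abs(mean(ests) / 10 - 1), 0.005)
})
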