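test_that("calibration schedule counts views correctly", {
  expect_length(calibration_schedule(0, 520, 10), 53L)
  expect_length(calibration_schedule(0, 0, 10), 1L)
  expect_equal(calibration_schedule(0, 360, 90), c(0, 90, 180, 270, 360))
  expect_warning(out <- calibration_schedule(0, 100, 30), "last view")
  expect_equal(out, c(0, 30, 60, 90))
})

test_that("identical runs give zero spread and zero hysteresis", {
  ang <- calibration_schedule(0, 40, 10)
  corr <- matrix(rep(1:9, each = 5), 5, 9,
                 dimnames = list(NULL, cbctqa:::CORRECTION_NAMES))
  recs <- list(calibration_record(1, "cw", ang, corr),
               calibration_record(1, "ccw", ang, corr),
               calibration_record(2, "cw", ang, corr),
               calibration_record(2, "ccw", ang, corr))
  st <- calibration_stats(recs)
  expect_true(all(st$overall$sd == 0))
  expect_true(all(st$summary$max_angle_sd == 0))
  expect_true(all(st$hysteresis == 0))
})

test_that("per-angle SD uses n - 1 and matches hand arithmetic", {
  ang <- 0
  mk <- function(val, run, dir)
    calibration_record(run, dir, ang,
                       matrix(val, 1, 9,
                              dimnames = list(NULL, cbctqa:::CORRECTION_NAMES)))
  st <- calibration_stats(list(mk(1, 1, "cw"), mk(3, 2, "cw")))
  expect_equal(unname(st$per_angle_sd$cw[1, ]), rep(sqrt(2), 9))
  expect_equal(st$overall$mean, rep(2, 9), ignore_attr = TRUE)
})

test_that("calibration stats equal the naive two-loop oracle exactly", {
  spec <- calibration_sim_spec(n_runs = 3, angle_stop = 40, seed = 2)
  recs <- simulate_calibration_runs(spec)
  st <- calibration_stats(recs)
  oracle <- calibration_stats_oracle(recs)
  for (d in c("cw", "ccw")) for (k in cbctqa:::CORRECTION_NAMES) {
    o <- oracle[[paste(d, k)]]
    row <- st$overall[st$overall$direction == d & st$overall$correction == k, ]
    expect_equal(row$mean, o$mean)
    expect_equal(row$sd, o$sd)
    expect_equal(unname(st$per_angle_sd[[d]][, k]), o$per_angle_sd)
  }
})

test_that("hysteresis is symmetric under swapping direction labels", {
  spec <- calibration_sim_spec(n_runs = 4, angle_stop = 60, seed = 9)
  recs <- simulate_calibration_runs(spec)
  swapped <- lapply(recs, function(r) {
    r$direction <- if (r$direction == "cw") "ccw" else "cw"
    r
  })
  expect_equal(calibration_stats(recs)$hysteresis,
               calibration_stats(swapped)$hysteresis)
})

test_that("mismatched angle grids are an alignment error", {
  mk <- function(ang, run) calibration_record(
    run, "cw", ang, matrix(0, length(ang), 9,
                           dimnames = list(NULL, cbctqa:::CORRECTION_NAMES)))
  expect_error(calibration_stats(list(mk(c(0, 10), 1), mk(c(0, 20), 2))),
               "alignment")
})

test_that("calibration records round-trip through CSV", {
  recs <- simulate_calibration_runs(
    calibration_sim_spec(n_runs = 2, angle_stop = 30, seed = 4))
  path <- file.path(tempdir(), "calib.csv")
  write_calibration_csv(recs, path)
  back <- read_calibration_csv(path)
  key <- function(rs) vapply(rs, function(r)
    paste(r$run_id, r$direction), "")
  back <- back[match(key(recs), key(back))]
  for (i in seq_along(recs))
    expect_equal(back[[i]]$corrections, recs[[i]]$corrections,
                 tolerance = 1e-9)
})

test_that("rod detection meets its noise budgets", {
  # noiseless: < 0.05 mm (checked in test-phantom_synth too, via truth)
  vol <- render_phantom(phantom_spec("insert", background_hu = 100),
                        degradation_spec())
  nominal <- attr(vol, "ground_truth")$rod_centers_mm
  expect_lt(max(abs(match_centers(detect_rods(vol), nominal) - nominal)),
            0.05)

  # 20 HU noise, 25 seeds on a reduced grid: mean centroid error < 0.2 mm
  errs <- vapply(1:25, function(s) {
    v <- render_phantom(phantom_spec("insert", diameter = 90,
                                     background_hu = 100,
                                     rods = data.frame(
                                       row = c(-25, -25, 25, 25),
                                       col = c(-25, 25, -25, 25),
                                       radius = 3, hu = 1000)),
                        degradation_spec(noise_sigma = 20, seed = s),
                        spacing = c(0.4, 0.4, 1), dims = c(256L, 256L, 1L))
    nom <- attr(v, "ground_truth")$rod_centers_mm
    mean(sqrt(rowSums((match_centers(detect_rods(v), nom) - nom)^2)))
  }, 0)
  expect_lt(mean(errs), 0.2)
})

test_that("too few blobs raise a detection error with the count", {
  vol <- render_phantom(phantom_spec("insert", background_hu = 100,
                                     rods = data.frame(row = c(-25, 0, 25),
                                                       col = c(-25, 25, 0),
                                                       radius = 3, hu = 1000)),
                        degradation_spec(),
                        spacing = c(0.8, 0.8, 1), dims = c(280L, 280L, 1L))
  expect_error(detect_rods(vol, n_rods = 4), "3 component")
})

test_that("fidelity is exact on the nominal square and shift/rotation invariant", {
  exact <- imaging_fidelity(square_centers())
  expect_equal(exact$mean_abs_error, 0)

  shifted <- imaging_fidelity(square_centers(r0 = 0.1, c0 = 0.1))
  expect_equal(shifted$mean_abs_error, 0, tolerance = 1e-12)

  th <- 17 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rotated <- imaging_fidelity(square_centers() %*% Rm)
  expect_equal(rotated$mean_abs_error, 0, tolerance = 1e-9)
})

test_that("a single displaced rod reproduces the brute-force distance errors", {
  centers <- square_centers()
  centers[4, ] <- centers[4, ] + 0.5 / sqrt(2)  # 0.5 mm outward on diagonal
  res <- imaging_fidelity(centers)
  oracle <- pairwise_distances(centers)
  nominal <- sort(c(rep(50, 4), rep(50 * sqrt(2), 2)))
  expect_equal(res$pair_distances$measured, oracle)
  expect_equal(res$mean_abs_error, mean(abs(oracle - nominal)))
  expect_equal(res$sd_abs_error, sd(abs(oracle - nominal)))
})

test_that("degenerate nominal layouts are a matching error", {
  expect_error(imaging_fidelity(square_centers(),
                                nominal = c(50, 50, 50, 50, 50 * sqrt(2),
                                            50 * sqrt(2) + 1e-12)),
               "matching error")
})

test_that("injected calibration offsets and SDs are recovered across ensembles", {
  # parameter-recovery property: offsets within 3 SE, per-ensemble SD
  # estimates inside the n = 8 chi-square 95% band in >= 93% of ensembles
  n_ens <- 60
  sd_true <- 2.1
  off_true <- 11.5
  band <- sqrt(qchisq(c(0.025, 0.975), df = 7) / 7) * sd_true
  in_band <- logical(n_ens)
  off_ok <- logical(n_ens)
  for (e in seq_len(n_ens)) {
    spec <- calibration_sim_spec(n_runs = 8, angle_stop = 120, seed = 1000 + e,
                                 mod_amplitude = 0,
                                 offsets = c(tCz = off_true),
                                 fluct_sd = c(tCz = sd_true), hysteresis = 0)
    st <- calibration_stats(simulate_calibration_runs(spec))
    sds <- st$per_angle_sd$cw[, "tCz"]
    est <- sqrt(mean(sds^2))                 # pooled over angles
    in_band[e] <- est >= band[1] && est <= band[2]
    n_angle <- length(st$angles)
    se <- sd_true / sqrt(8 * n_angle)
    m <- st$overall$mean[st$overall$correction == "tCz" &
                           st$overall$direction == "cw"]
    off_ok[e] <- abs(m - off_true) <= 3 * se
  }
  expect_gte(mean(in_band), 0.93)
  expect_gte(mean(off_ok), 0.93)
})
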