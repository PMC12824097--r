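test_that("sphere geometry and calibration round trip", {
  # R = 30 um, r = 2 um -> h ~ r^2/2R = 66.67 nm
  expect_equal(sphere_height(2000, 30000), 66.67, tolerance = 0.1 / 66.67)
  r <- seq(0, 2500, by = 25)
  h <- sphere_height(r, 30000)
  prof <- data.frame(r = r, intensity = 120 + 0.85 * h)
  cal <- calibrate_intensity_to_height(prof, bead_diameter = 60)
  expect_lt(abs(cal$slope / 0.85 - 1), 0.01)
  expect_error(calibrate_intensity_to_height(prof, bead_diameter = -1),
               "positive")
  flat <- data.frame(r = r, intensity = 120 + stats::rnorm(length(r), 0, 1e-4))
  expect_error(calibrate_intensity_to_height(flat), "monotone|slope")
})

test_that("intensity_to_height removes means, is linear, and round-trips", {
  cal <- height_calibration(slope = 0.8, intercept = 100)
  const <- fluctuation_movie(array(55, c(16, 2, 2)), units = "au")
  h <- intensity_to_height(const, cal)
  expect_true(all(h$values == 0))
  expect_identical(h$units, "nm")
  # round trip through the generator's inverse calibration
  src <- simulate_height_series(mech_params(), 20, 512, seed = 1)
  img <- height_to_intensity(src, cal, baseline = 130)
  back <- intensity_to_height(img, cal)
  expect_equal(back$values, src$values, tolerance = 1e-10)
  cal2 <- height_calibration(slope = 1.6, intercept = 100)
  half <- intensity_to_height(img, cal2)
  expect_equal(half$values, src$values / 2, tolerance = 1e-10)
})

test_that("select_fbr_regions screens branch membership and drift", {
  cal <- height_calibration(slope = 1, intercept = 100,
                            valid_height_range = c(0, 100))
  # uniform in-branch movie (intensity 150 = mid-branch): full tiling
  v <- array(150, c(64, 8, 8))
  m <- fluctuation_movie(v, units = "au")
  sel <- select_fbr_regions(m, cal)
  expect_identical(nrow(sel), 4L)
  # left half far out of branch -> only right-half regions remain
  v2 <- v; v2[, , 1:4] <- 400
  sel2 <- select_fbr_regions(fluctuation_movie(v2, units = "au"), cal)
  expect_true(all(sel2[, "col"] >= 5))
  expect_identical(nrow(sel2), 2L)
  # strong linear drift in one region -> excluded
  v3 <- v
  v3[, 1:4, 1:4] <- v3[, 1:4, 1:4] + seq(0, 30, length.out = 64)
  sel3 <- select_fbr_regions(fluctuation_movie(v3, units = "au"), cal)
  expect_false(any(sel3[, "row"] == 1 & sel3[, "col"] == 1))
  expect_identical(nrow(sel3), 3L)
})

test_that("periodogram-average PSD satisfies Parseval and known spectra", {
  fs <- 20
  n <- 2048
  t <- (0:(n - 1)) / fs
  # pure tone at an exact segment bin (k = 16 of 256): power a^2/2
  a <- 3
  x <- a * sin(2 * pi * (fs * 16 / 256) * t)
  psd <- estimate_psd(x, fs, n_segments = 8L)
  df <- psd$freq[2] - psd$freq[1]
  expect_lt(abs(sum(psd$power) * df / (a^2 / 2) - 1), 0.02)
  # white noise: flat at v / (fs/2)
  set.seed(2)
  w <- stats::rnorm(2^15, sd = 4)
  psd_w <- estimate_psd(w, fs, n_segments = 32L)
  expect_lt(abs(mean(psd_w$power) / (16 / (fs / 2)) - 1), 0.05)
  # Parseval on an arbitrary synthetic series
  m <- simulate_height_series(mech_params(), fs, 2048, seed = 3)
  ps <- estimate_psd(as.numeric(m$values), fs, n_segments = 8L)
  seg_var <- mean(vapply(1:8, function(s) {
    seg <- as.numeric(m$values)[((s - 1) * 256 + 1):(s * 256)]
    mean((seg - mean(seg))^2)
  }, numeric(1)))
  expect_lt(abs(sum(ps$power) * (ps$freq[2] - ps$freq[1]) / seg_var - 1), 0.02)
  expect_error(estimate_psd(1:10, 20), "short")
})

test_that("AR estimator matches the closed-form AR(2) spectrum at mid-band", {
  set.seed(7)
  a1 <- 0.6; a2 <- -0.3; fs <- 20
  x <- as.numeric(stats::arima.sim(list(ar = c(a1, a2)), 2^14, sd = 1))
  psd <- estimate_psd(x, fs, method = "ar", ar_order = 4L)
  om <- 2 * pi * psd$freq / fs
  S_true <- 2 * (1 / fs) / Mod(1 - a1 * exp(-1i * om) - a2 * exp(-2i * om))^2
  mid <- psd$freq > 2 & psd$freq < 8
  expect_lt(max(abs(psd$power[mid] / S_true[mid] - 1)), 0.10)
  expect_error(estimate_psd(stats::rnorm(20), fs, method = "ar",
                            ar_order = 16L), "short")
})

test_that("fit_helfrich recovers exact model curves (all four free) within 1%", {
  p <- mech_params(sigma = 500)
  fit <- fit_helfrich(model_psd(p), fixed = default_fixed(a_active = NULL),
                      n_log_bins = 0)
  expect_lt(abs(fit$params$sigma / p$sigma - 1), 0.01)
  expect_lt(abs(fit$params$gamma / p$gamma - 1), 0.01)
  expect_lt(abs(fit$params$eta_eff / p$eta_eff - 1), 0.01)
  expect_lt(abs(fit$params$a_active / p$a_active - 1), 0.01)
  expect_gt(fit$r_squared, 0.999)
})

test_that("fit_helfrich recovers sigma from a seeded synthetic series within 20%", {
  p <- mech_params(sigma = 500)
  m <- simulate_height_series(p, 20, 2048, seed = 11)
  fit <- fit_helfrich(estimate_psd(as.numeric(m$values), 20))
  expect_lt(abs(fit$params$sigma / 500 - 1), 0.20)
  expect_true(fit$converged)
})

test_that("fit_helfrich rejects an empty frequency range", {
  p <- mech_params()
  expect_error(fit_helfrich(model_psd(p), freq_range = c(100, 200)), "range")
})

test_that("compute_sd_time: degenerate, analytic, and map forms", {
  expect_error(compute_sd_time(c(5)), "frames")
  expect_equal(compute_sd_time(rep(3, 100)), 0)
  set.seed(4)
  expect_lt(abs(compute_sd_time(stats::rnorm(20000, sd = 5)) / 5 - 1), 0.03)
  m <- simulate_fluctuation_movie(matrix(500, 2, 2), mech_params(),
                                  n_frames = 512, seed = 1)
  sdm <- compute_sd_time(m)
  expect_identical(dim(sdm), c(2L, 2L))
  expect_error(compute_sd_time(
    fluctuation_movie(array(1:8, c(2, 2, 2)), units = "au")), "height")
})

test_that("map_pixelwise centers on truth and separates zones", {
  truth <- matrix(rep(c(300, 1300), each = 6), 3, 4)
  m <- simulate_fluctuation_movie(truth, mech_params(), n_frames = 2048,
                                  seed = 21)
  map <- map_pixelwise(m)
  left <- stats::median(map$sigma_map[, 1:2], na.rm = TRUE)
  right <- stats::median(map$sigma_map[, 3:4], na.rm = TRUE)
  expect_lt(abs(left / 300 - 1), 0.35)
  expect_lt(abs(right / 1300 - 1), 0.35)
  expect_gt(right, left)
  # uniform movie: median within 20% of truth
  mu <- simulate_fluctuation_movie(matrix(500, 3, 3), mech_params(),
                                   n_frames = 2048, seed = 22)
  mapu <- map_pixelwise(mu)
  expect_lt(abs(stats::median(mapu$sigma_map, na.rm = TRUE) / 500 - 1), 0.20)
})

test_that("a non-stationary jump pixel is excluded from the valid mask", {
  m <- simulate_fluctuation_movie(matrix(500, 2, 2), mech_params(),
                                  n_frames = 2048, seed = 30)
  m$values[1025:2048, 1, 1] <- m$values[1025:2048, 1, 1] + 60
  map <- map_pixelwise(m)
  expect_false(map$valid_mask[1, 1])
  expect_true(any(map$valid_mask[-1]))
})

test_that("threshold filtering is idempotent", {
  set.seed(5)
  map <- tension_map(matrix(stats::runif(100, 0, 8000), 10),
                     matrix(stats::runif(100, 0, 20), 10),
                     matrix(stats::runif(100, 0.8, 1), 10))
  again <- apply_tension_thresholds(map)
  expect_identical(map$valid_mask, again$valid_mask)
  expect_identical(map$sigma_map, again$sigma_map)
})
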