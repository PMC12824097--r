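test_that("simulate_height_series is deterministic and validates input", {
  p <- mech_params()
  a <- simulate_height_series(p, 20, 512, seed = 3)
  b <- simulate_height_series(p, 20, 512, seed = 3)
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, simulate_height_series(p, 20, 512, seed = 4)$values))
  expect_error(simulate_height_series(p, -1, 512, seed = 1), "positive")
  expect_error(simulate_height_series(p, 20, 100, seed = 1), "256")
  # zero mean by construction, nm units
  expect_lt(abs(mean(a$values)), 1e-10)
  expect_identical(a$units, "nm")
})

test_that("sample variance matches the integrated model PSD within 5%", {
  p <- mech_params(sigma = 500)
  m <- simulate_height_series(p, 20, 2^15, seed = 1)
  v_model <- helfrich_variance(p, f_max = 10)
  expect_lt(abs(stats::var(as.numeric(m$values)) / v_model - 1), 0.05)
})

test_that("spectral synthesis hits the model band variance in >=95% of 50 seeds", {
  p <- mech_params(sigma = 300)
  v_model <- helfrich_variance(p, f_max = 10)
  ok <- vapply(1:50, function(s) {
    v <- stats::var(as.numeric(
      simulate_height_series(p, 20, 2^15, seed = s)$values))
    abs(v / v_model - 1) < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("empirical spectrum lies within 95% chi-square bands at >=90% of bins", {
  p <- mech_params(sigma = 500)
  m <- simulate_height_series(p, 20, 2^15, seed = 5)
  psd <- estimate_psd(as.numeric(m$values), 20, n_segments = 8L)
  S <- helfrich_psd(psd$freq, p)
  lo <- stats::qchisq(0.025, 16) / 16
  hi <- stats::qchisq(0.975, 16) / 16
  frac <- mean(psd$power / S > lo & psd$power / S < hi)
  expect_gte(frac, 0.90)
})

test_that("model variance is monotone decreasing in sigma and SD_time follows", {
  sigmas <- c(100, 300, 1000, 2000)
  v <- vapply(sigmas, function(s)
    helfrich_variance(mech_params(sigma = s), f_max = 10), numeric(1))
  expect_true(all(diff(v) < 0))
  sd_emp <- vapply(sigmas, function(s) {
    m <- simulate_height_series(mech_params(sigma = s), 20, 4096, seed = 42)
    compute_sd_time(as.numeric(m$values))
  }, numeric(1))
  expect_true(all(diff(sd_emp) < 0))
})

test_that("simulate_fluctuation_movie stores truth and orders zone SD_time", {
  truth <- matrix(rep(c(300, 1300), each = 4), 2, 4)
  m <- simulate_fluctuation_movie(truth, mech_params(), n_frames = 1024,
                                  seed = 9)
  expect_identical(m$truth_tension, truth)
  expect_identical(dim(m$values), c(1024L, 2L, 4L))
  sdm <- compute_sd_time(m)
  expect_lt(mean(sdm[, 3:4]), mean(sdm[, 1:2]))
  m2 <- simulate_fluctuation_movie(truth, mech_params(), n_frames = 1024,
                                   seed = 9)
  expect_identical(m$values, m2$values)
  expect_error(simulate_fluctuation_movie(matrix(c(1, -1), 1), mech_params()),
               "positive")
})

test_that("simulate_tirf_frame: empty case, centroid, determinism", {
  f0 <- simulate_tirf_frame(NULL, background = 7, noise_sd = 0,
                            shape = c(32, 32))
  expect_true(all(.subset2(f0, "values") == 7))
  f1 <- simulate_tirf_frame(matrix(c(15.5, 18.5), 1), amplitudes = 100,
                            psf_sigma = 2, background = 0, noise_sd = 0,
                            shape = c(32, 32))
  img <- f1$values[, , 1, 1]
  w <- img / sum(img)
  centroid <- c(sum(row(img) * w), sum(col(img) * w))
  expect_lt(max(abs(centroid - c(15.5, 18.5))), 0.1)
  a <- simulate_tirf_frame(matrix(c(10, 10), 1), noise_sd = 2, seed = 1,
                           shape = c(24, 24))
  b <- simulate_tirf_frame(matrix(c(10, 10), 1), noise_sd = 2, seed = 1,
                           shape = c(24, 24))
  expect_identical(a$values, b$values)
  expect_error(simulate_tirf_frame(matrix(c(5, 5), 1), psf_sigma = 0),
               "psf_sigma")
  expect_error(simulate_tirf_frame(matrix(c(50, 5), 1), shape = c(32, 32)),
               "inside")
})

test_that("simulate_scattering_profile: Guinier limit, round trip, flags", {
  prof <- simulate_scattering_profile(rg = 3, i0 = 50, noise_cv = 0)
  expect_lt(abs(prof$intensity[1] / (50 * exp(-prof$s[1]^2 * 3)) - 1), 1e-12)
  fit <- guinier_fit_globular(prof)
  expect_equal(fit$rg, 3.00, tolerance = 5e-4)
  sup <- simulate_scattering_profile(rg = 3, noise_cv = 0,
                                     interparticle = TRUE)
  expect_true(detect_interparticle_effect(sup, n_low = 5)$interparticle)
  expect_false(detect_interparticle_effect(prof, n_low = 5)$interparticle)
  expect_error(simulate_scattering_profile(rg = 3, rc = 4), "rc")
  expect_error(simulate_scattering_profile(rg = 3, noise_cv = -1), "noise_cv")
  a <- simulate_scattering_profile(rg = 3, noise_cv = 0.02, seed = 2)
  b <- simulate_scattering_profile(rg = 3, noise_cv = 0.02, seed = 2)
  expect_identical(a$intensity, b$intensity)
})

test_that("simulate_fcs_curve: zero-noise pass-through and determinism", {
  tau <- 10^seq(-6, -1, length.out = 60)
  cv <- simulate_fcs_curve(n_particles = 5, tau_d = 1e-4, s_struct = 5,
                           tau_grid = tau, noise_cv = 0)
  expect_equal(cv$g, fcs_model(tau, 5, 1e-4, 5), tolerance = 1e-14)
  a <- simulate_fcs_curve(tau_grid = tau, noise_cv = 0.01, seed = 8)
  b <- simulate_fcs_curve(tau_grid = tau, noise_cv = 0.01, seed = 8)
  expect_identical(a$g, b$g)
  expect_error(simulate_fcs_curve(noise_cv = -0.1), "noise_cv")
})

test_that("simulate_coloc_stack honors its construction contract", {
  # disjoint channels when nothing overlaps
  st0 <- simulate_coloc_stack(n_endosomes = 4, n_overlapping = 0,
                              n_actin_extra = 2, n_slices = 1, seed = 1)
  expect_false(any(st0$truth_masks[, , 1, 1] & st0$truth_masks[, , 1, 2]))
  # stored truth fraction
  st <- simulate_coloc_stack(n_endosomes = 5, n_overlapping = 3, seed = 2)
  expect_equal(st$truth_overlap_fraction, 0.6)
  expect_error(simulate_coloc_stack(n_endosomes = 2, n_overlapping = 3),
               "n_overlapping")
  # cortical ring: one channel-2 object touches the border zone and is large
  str <- simulate_coloc_stack(cortical_ring = TRUE, n_slices = 1, seed = 3)
  ring_lab <- label_objects(str$truth_masks[, , 1, 2])
  expect_gt(max(ring_lab$areas), 500)
  a <- simulate_coloc_stack(seed = 5)
  b <- simulate_coloc_stack(seed = 5)
  expect_identical(a$values, b$values)
})

test_that("simulate_cell_image fixes region means and nests masks", {
  ci <- simulate_cell_image(200, 50, noise_sd = 0)
  nm <- ci$extra$nuclear_mask; cm <- ci$extra$cell_mask
  r <- nuclear_cytoplasmic_ratio(ci, nm, cm)
  expect_equal(r$ratio, 4.0)
  ci2 <- simulate_cell_image(80, 80, noise_sd = 0)
  expect_equal(nuclear_cytoplasmic_ratio(ci2, ci2$extra$nuclear_mask,
                                         ci2$extra$cell_mask)$ratio, 1.0)
  expect_error(
    simulate_cell_image(nuclear_mask = matrix(TRUE, 4, 4),
                        cell_mask = matrix(TRUE, 4, 4)),
    "strictly inside")
  a <- simulate_cell_image(noise_sd = 5, seed = 2)
  b <- simulate_cell_image(noise_sd = 5, seed = 2)
  expect_identical(a$values, b$values)
})
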