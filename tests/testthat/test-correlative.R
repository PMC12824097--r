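test_that("register_frames recovers integer shifts and is inverse-consistent", {
  set.seed(1)
  ref <- simulate_tirf_frame(cbind(c(20, 35, 12), c(15, 30, 40)),
                             noise_sd = 0, shape = c(48, 48))$values[, , 1, 1]
  expect_identical(register_frames(ref, ref), c(0L, 0L))
  mov <- matrix(0, 48, 48)
  mov[(1:45) + 3, (1:46)] <- ref[1:45, 3:48]    # shift by (3, -2)
  expect_identical(register_frames(ref, mov, max_shift = 6), c(3L, -2L))
  expect_identical(register_frames(mov, ref, max_shift = 6), c(-3L, 2L))
  # robust at additive noise SNR ~ 5
  noisy <- mov + matrix(stats::rnorm(48 * 48, 0, max(ref) / 5), 48, 48)
  expect_identical(register_frames(ref, noisy, max_shift = 6), c(3L, -2L))
  expect_error(register_frames(ref, mov, max_shift = 48), "max_shift")
  expect_error(register_frames(ref, mov[1:40, ]), "shape")
})

test_that("detect_clusters finds peaks, honors separation and edge margin", {
  one <- simulate_tirf_frame(matrix(c(20, 25), 1), noise_sd = 0,
                             shape = c(48, 48))
  cs <- detect_clusters(one, threshold = 50, edge_margin = 5)
  expect_identical(nrow(cs$centers), 1L)
  expect_identical(unname(cs$centers[1, ]), c(20, 25))
  centers <- cbind(c(10, 10, 30, 40, 24), c(10, 40, 24, 38, 8))
  five <- simulate_tirf_frame(centers, amplitudes = c(100, 90, 80, 70, 60),
                              noise_sd = 0, shape = c(48, 48))
  cs5 <- detect_clusters(five, threshold = 30, edge_margin = 2)
  expect_identical(nrow(cs5$centers), 5L)
  d <- as.matrix(stats::dist(rbind(centers, cs5$centers)))
  expect_lt(max(apply(d[6:10, 1:5, drop = FALSE], 2, min)), 1)
  # peak 2 px from the border is excluded and counted
  near <- simulate_tirf_frame(matrix(c(2, 24), 1), noise_sd = 0,
                              shape = c(48, 48))
  csn <- detect_clusters(near, threshold = 50, edge_margin = 5)
  expect_identical(nrow(csn$centers), 0L)
  expect_identical(csn$excluded_edge, 1L)
})

test_that("line scans have length 11, propagate masks, and skip border clusters", {
  map <- tension_map(matrix(700, 20, 20))
  sc <- line_scan_profiles(map, rbind(c(10, 10)))
  expect_length(sc[[1]]$x, 11L)
  expect_true(all(sc[[1]]$x == 700) && all(sc[[1]]$y == 700))
  # invalidate the pixel at x-offset +2 only
  map2 <- map
  map2$valid_mask[10, 12] <- FALSE
  sc2 <- line_scan_profiles(map2, rbind(c(10, 10)))
  expect_true(is.na(sc2[[1]]$x["2"]))
  expect_false(anyNA(sc2[[1]]$x[c("-2", "0", "1", "3")]))
  expect_warning(line_scan_profiles(map, rbind(c(3, 10))), "border")
})

test_that("radial_average normalizes, pools by distance, and reports SEM", {
  map <- tension_map(matrix(840, 20, 20))
  prof <- radial_average(line_scan_profiles(map, rbind(c(10, 10), c(8, 8))))
  expect_true(all(prof$profile$mean_norm == 1))
  expect_true(all(prof$profile$sem == 0))
  expect_identical(prof$profile$distance, (0:5) * 65)
  # +30% ring at Euclidean distance 2 px (130 nm)
  sig <- matrix(1000, 21, 21)
  rr <- (row(sig) - 11)^2 + (col(sig) - 11)^2
  sig[rr >= 1.5^2 & rr <= 2.5^2] <- 1300
  profr <- radial_average(line_scan_profiles(tension_map(sig),
                                             rbind(c(11, 11))))
  expect_equal(profr$profile$mean_norm[profr$profile$distance == 130], 1.3)
  expect_equal(profr$profile$mean_norm[profr$profile$distance == 0], 1)
  # hand arithmetic: two clusters at 1.2 and 1.4 -> mean 1.3, SEM 0.1
  scans <- list(list(x = stats::setNames(c(rep(1.2, 5), 1, rep(1.2, 5)), -5:5),
                     y = stats::setNames(c(rep(1.2, 5), 1, rep(1.2, 5)), -5:5)),
                list(x = stats::setNames(c(rep(1.4, 5), 1, rep(1.4, 5)), -5:5),
                     y = stats::setNames(c(rep(1.4, 5), 1, rep(1.4, 5)), -5:5)))
  pr <- radial_average(scans)
  at_d <- pr$profile$distance == 65
  expect_equal(pr$profile$mean_norm[at_d], 1.3)
  expect_equal(pr$profile$sem[at_d], 0.1)
  # zero center -> dropped; all dropped -> error
  bad <- list(list(x = stats::setNames(c(rep(1, 5), 0, rep(1, 5)), -5:5),
                   y = stats::setNames(rep(1, 11), -5:5)))
  expect_error(suppressWarnings(radial_average(bad)), "empty")
})

test_that("tension_surge measures the windowed max increase", {
  map <- tension_map(matrix(500, 15, 15))
  expect_equal(tension_surge(map, c(8, 8))$max_surge, 0)
  # planted surge echoing the ~1,300 pN/um scale
  sig <- matrix(500, 15, 15)
  sig[8, 11] <- 1800       # distance 3 px from center
  sig[8, 14] <- 9e5        # distance 6 px: outside the 325-nm window
  s <- tension_surge(tension_map(sig, thresholds = list(
    r2_min = 0.9, sigma_max = Inf, sd_max = 15)), c(8, 8))
  expect_equal(s$max_surge, 1300)
  # translation equivariance
  sig2 <- matrix(500, 15, 15)
  sig2[10, 13] <- 1800
  s2 <- tension_surge(tension_map(sig2, thresholds = list(
    r2_min = 0.9, sigma_max = Inf, sd_max = 15)), c(10, 10))
  expect_equal(s2$max_surge, s$max_surge)
  # baseline normalization of the 10x10 window mean
  base <- tension_map(matrix(500, 15, 15))
  sn <- tension_surge(tension_map(matrix(650, 15, 15)), c(8, 8),
                      baseline_map = base)
  expect_equal(sn$local_mean_norm, 1.3)
})

test_that("baseline_backtrace translates coordinates and drops out-of-bounds", {
  pre <- tension_map(matrix(500, 40, 40))
  post <- simulate_tirf_frame(rbind(c(20, 20), c(10, 35)), noise_sd = 0,
                              shape = c(40, 40))
  cs0 <- baseline_backtrace(pre, post, shift = c(0L, 0L), threshold = 50)
  expect_identical(sort(cs0$centers[, 1]), c(10, 20))
  cs <- baseline_backtrace(pre, post, shift = c(3L, -2L), threshold = 50)
  expect_true(all(cs$centers[, 2] %in% c(22, 37)))
  expect_true(all(cs$centers[, 1] %in% c(17, 7)))
  # shift pushing a center out of bounds
  cs_oob <- baseline_backtrace(pre, post, shift = c(0L, 33L), threshold = 50)
  expect_identical(cs_oob$dropped_oob, 1L)
})

test_that("mann_whitney_u: exact enumeration, symmetry, and oracle agreement", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1)
  expect_identical(r$method, "exact")
  same <- mann_whitney_u(c(1.5, 2.5, 9), c(1.5, 2.5, 9))
  expect_equal(same$u, 4.5)   # n1*n2/2
  set.seed(13)
  for (i in 1:20) {
    a <- stats::rnorm(sample(2:6, 1))
    b <- stats::rnorm(sample(2:8, 1))
    expect_equal(mann_whitney_u(a, b)$p, mw_exact_oracle(a, b))
  }
  # large-sample normal approximation tracks wilcox.test
  set.seed(14)
  a <- stats::rnorm(30); b <- stats::rnorm(35, 0.6)
  mine <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_identical(mine$method, "normal")
  expect_equal(mine$u, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("end-to-end: a planted tension ring is detected against baseline", {
  # movie-level check; ~40 s of pixel fits
  h <- 17; w <- 17
  centers <- rbind(c(6, 6), c(6, 12), c(12, 6), c(12, 12), c(9, 9))
  mk_truth <- function(ring) {
    truth <- matrix(500, h, w)
    if (ring) for (k in seq_len(nrow(centers))) {
      rr <- (row(truth) - centers[k, 1])^2 + (col(truth) - centers[k, 2])^2
      truth[rr >= 1.5^2 & rr <= 2.5^2] <- 650
    }
    truth
  }
  analyze <- function(ring, seed) {
    m <- simulate_fluctuation_movie(mk_truth(ring), mech_params(),
                                    n_frames = 2048, seed = seed)
    map <- map_pixelwise(m)
    M <- radial_average(line_scan_profiles(map, centers))$per_cluster
    M[, 3]   # per-cluster normalized value at 2 px = 130 nm
  }
  ring_vals <- analyze(TRUE, 101)
  base_vals <- analyze(FALSE, 102)
  expect_lt(mann_whitney_u(ring_vals, base_vals, "greater")$p, 0.05)
  base2 <- analyze(FALSE, 103)
  expect_gt(mann_whitney_u(base2, base_vals, "greater")$p, 0.05)
})
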