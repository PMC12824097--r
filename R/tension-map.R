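#' Per-pixel tension map container
#'
#' Holds pixel-wise fitted membrane tension, SD_time, fit quality and
#' the validity mask obtained by thresholding. The default thresholds
#' keep a pixel only when r^2 > 0.9, tension < 5,000 pN/um and
#' SD_time < 15 nm.
#'
#' @param sigma_map H x W fitted tension, pN/um.
#' @param sd_time_map H x W SD_time, nm (defaults to zeros).
#' @param r2_map H x W fit r^2 (defaults to ones).
#' @param thresholds list with `r2_min`, `sigma_max`, `sd_max`.
#' @param pixel_size pixel size, nm.
#' @return An object of class `tension_map`; invalid pixels carry `NA`
#'   in `sigma_map`.
#' @export
tension_map <- function(sigma_map, sd_time_map = NULL, r2_map = NULL,
                        thresholds = list(r2_min = 0.9, sigma_max = 5000,
                                          sd_max = 15),
                        pixel_size = 65) {
  sigma_map <- as.matrix(sigma_map)
  if (is.null(sd_time_map)) sd_time_map <- array(0, dim(sigma_map))
  if (is.null(r2_map)) r2_map <- array(1, dim(sigma_map))
  if (!all(dim(sd_time_map) == dim(sigma_map)) ||
      !all(dim(r2_map) == dim(sigma_map)))
    stop("tension_map: map dimensions differ")
  x <- structure(list(sigma_map = sigma_map, sd_time_map = sd_time_map,
                      r2_map = r2_map, valid_mask = NULL,
                      thresholds = thresholds, pixel_size = pixel_size),
                 class = "tension_map")
  apply_tension_thresholds(x)
}

#' Apply (or re-apply) validity thresholds to a tension map
#'
#' The mask keeps pixels with finite tension satisfying all three
#' thresholds; applying the thresholds twice is idempotent. Pixels
#' failing the mask carry `NA` in `sigma_map`.
#'
#' @param map a [tension_map()].
#' @param thresholds optional replacement thresholds.
#' @return The map with `valid_mask` (and `sigma_map` `NA`s) updated.
#' @export
apply_tension_thresholds <- function(map, thresholds = NULL) {
  if (!inherits(map, "tension_map"))
    stop("apply_tension_thresholds: not a tension_map")
  th <- if (is.null(thresholds)) map$thresholds else thresholds
  ok <- is.finite(map$sigma_map) &
    map$r2_map > th$r2_min &
    map$sigma_map < th$sigma_max &
    map$sd_time_map < th$sd_max
  ok[is.na(ok)] <- FALSE
  out <- map
  out$thresholds <- th
  out$valid_mask <- ok
  out$sigma_map[!ok] <- NA_real_
  out
}

#' @export
print.tension_map <- function(x, ...) {
  d <- dim(x$sigma_map)
  cat(sprintf("tension_map: %d x %d px, %d/%d valid, median sigma = %.4g pN/um\n",
              d[1], d[2], sum(x$valid_mask), length(x$valid_mask),
              stats::median(x$sigma_map[x$valid_mask])))
  invisible(x)
}

#' Pixel-wise tension and SD_time mapping
#'
#' Runs the full per-pixel pipeline on a height-mode movie: PSD
#' estimation ([estimate_psd()]), Helfrich-model fitting
#' ([fit_helfrich()]) and SD_time ([compute_sd_time()]), then applies
#' the validity thresholds. Invalid pixels carry `NA` tension.
#'
#' @param movie a height-mode [fluctuation_movie()].
#' @param fixed fixed model parameters passed to [fit_helfrich()].
#' @param thresholds validity thresholds, see [tension_map()].
#' @param psd_method PSD estimator.
#' @param ... further arguments to [estimate_psd()].
#' @return A [tension_map()].
#' @export
map_pixelwise <- function(movie,
                          fixed = list(kappa = 15, temperature = 310.15,
                                       q_min = pi / 5.2, q_max = pi / 0.065,
                                       a_active = 1.5),
                          thresholds = list(r2_min = 0.9, sigma_max = 5000,
                                            sd_max = 15),
                          psd_method = "periodogram-average", ...) {
  if (!inherits(movie, "fluctuation_movie") || movie$units != "nm")
    stop("map_pixelwise: movie must be in height units")
  d <- dim(movie$values)
  h <- d[2]; w <- d[3]
  fs <- .movie_rate(movie)
  sig <- r2 <- matrix(NA_real_, h, w)
  sdm <- compute_sd_time(movie)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    psd <- estimate_psd(movie$values[, i, j], fs, method = psd_method, ...)
    fit <- tryCatch(fit_helfrich(psd, fixed = fixed),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      sig[i, j] <- fit$params$sigma
      r2[i, j] <- fit$r_squared
    }
  }
  tension_map(sig, sdm, r2, thresholds = thresholds,
              pixel_size = movie$pixel_size)
}

#' Fit selected regions of a movie
#'
#' Region-level convenience: averages each region's pixels into mean
#' region series statistics — the PSD is estimated per pixel and
#' averaged across the region (fluctuations of neighboring pixels are
#' treated as independent realizations), fitted once, and SD_time is
#' the region mean of pixel SD_time.
#'
#' @param movie a height-mode [fluctuation_movie()].
#' @param origins integer matrix of region origins as returned by
#'   [select_fbr_regions()].
#' @param region_size region side length, px.
#' @inheritParams map_pixelwise
#' @return data frame with one row per region: origin, fitted
#'   parameters, r^2 and SD_time.
#' @export
fit_regions <- function(movie, origins, region_size = 4L,
                        fixed = list(kappa = 15, temperature = 310.15,
                                     q_min = pi / 5.2, q_max = pi / 0.065,
                                     a_active = 1.5),
                        psd_method = "periodogram-average", ...) {
  if (!inherits(movie, "fluctuation_movie") || movie$units != "nm")
    stop("fit_regions: movie must be in height units")
  fs <- .movie_rate(movie)
  sdm <- compute_sd_time(movie)
  res <- vector("list", nrow(origins))
  for (k in seq_len(NROW(origins))) {
    i0 <- origins[k, 1]; j0 <- origins[k, 2]
    ii <- i0:(i0 + region_size - 1L); jj <- j0:(j0 + region_size - 1L)
    acc <- NULL
    for (j in jj) for (i in ii) {
      p <- estimate_psd(movie$values[, i, j], fs, method = psd_method, ...)
      acc <- if (is.null(acc)) p$power else acc + p$power
      freq <- p$freq
    }
    psd <- structure(list(freq = freq, power = acc / (region_size^2),
                          method = psd_method,
                          n_frames = dim(movie$values)[1],
                          sampling_rate = fs),
                     class = "psd_estimate")
    fit <- fit_helfrich(psd, fixed = fixed)
    res[[k]] <- data.frame(row = i0, col = j0,
                           sigma = fit$params$sigma,
                           gamma = fit$params$gamma,
                           eta_eff = fit$params$eta_eff,
                           a_active = fit$params$a_active,
                           r_squared = fit$r_squared,
                           sd_time = mean(sdm[ii, jj]))
  }
  do.call(rbind, res)
}
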