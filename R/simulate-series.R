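#' Acquisition presets for fluctuation movies
#'
#' Two named presets reflect the acquisition settings used for
#' correlative TIRF-IRM movies (2,048 frames at 20 Hz, i.e. 50-ms
#' interval) and fast IRM-only movies (8,192 frames at 50 Hz, 20-ms
#' interval).
#'
#' @param name `"tirf-irm"` or `"irm-fast"`.
#' @return List with `n_frames`, `sampling_rate` (Hz), `pixel_size` (nm).
#' @export
irm_preset <- function(name = c("tirf-irm", "irm-fast")) {
  name <- match.arg(name)
  switch(name,
         "tirf-irm" = list(n_frames = 2048L, sampling_rate = 20,
                           pixel_size = 65),
         "irm-fast" = list(n_frames = 8192L, sampling_rate = 50,
                           pixel_size = 65))
}

# Draw one zero-mean stationary Gaussian series with one-sided PSD
# S_one(f) = helfrich_psd(f, params) using the current RNG stream.
# Spectral synthesis: complex Gaussian Fourier coefficients with
# E|X_k|^2 = n * fs * S_one(f_k) / 2, Hermitian-symmetrized and
# inverse-transformed, so the population spectrum equals the model
# exactly on the discrete grid.
.height_series_draw <- function(params, sampling_rate, n_frames) {
  n <- as.integer(n_frames)
  fs <- sampling_rate
  half <- n %/% 2L
  f <- (1:half) * fs / n                    # (0, Nyquist]
  S <- helfrich_psd(f, params) * 1e-6       # work in um^2/Hz internally
  amp <- sqrt(n * fs * S / 2)
  X <- complex(real = rep(0, n), imaginary = rep(0, n))
  k <- 1:(half - 1L)
  X[k + 1L] <- amp[k] * complex(real = stats::rnorm(half - 1L),
                                imaginary = stats::rnorm(half - 1L)) / sqrt(2)
  X[half + 1L] <- amp[half] * stats::rnorm(1L)   # Nyquist bin is real
  X[n:(half + 2L)] <- Conj(X[2L:half])
  h_um <- Re(stats::fft(X, inverse = TRUE)) / n
  h_um * 1e3                                 # nm
}

#' Simulate a single-region membrane height fluctuation series
#'
#' Draws a stationary, zero-mean Gaussian time series whose population
#' power spectral density equals the Helfrich model ([helfrich_psd()])
#' at the given parameters, by spectral synthesis with complex Gaussian
#' Fourier coefficients.
#'
#' @param params a [mech_params()] object.
#' @param sampling_rate frame rate, Hz.
#' @param n_frames number of frames (>= 256).
#' @param seed RNG seed.
#' @param pixel_size pixel size, nm (metadata only).
#' @return A single-pixel [fluctuation_movie()] in height units (nm).
#' @examples
#' m <- simulate_height_series(mech_params(sigma = 500), 20, 2048, seed = 1)
#' stats::sd(m$values)
#' @export
simulate_height_series <- function(params, sampling_rate, n_frames,
                                   seed = NULL, pixel_size = 65) {
  if (!.is_mech_params(params)) params <- do.call(mech_params, as.list(params))
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("simulate_height_series: sampling_rate must be positive")
  if (n_frames < 256L)
    stop("simulate_height_series: need at least 256 frames")
  h <- .with_seed(seed, .height_series_draw(params, sampling_rate, n_frames))
  fluctuation_movie(h, units = "nm", pixel_size = pixel_size,
                    frame_interval = 1 / sampling_rate, seed = seed,
                    truth_tension = matrix(params$sigma, 1, 1))
}

#' Simulate a pixel-wise fluctuation movie with a known tension field
#'
#' Generates one independent Helfrich-spectrum height series per pixel,
#' taking the tension of each pixel from `truth_tension` and all other
#' parameters from `base_params`. Pixels are spatially uncorrelated by
#' construction (a stated fidelity limitation, adequate for testing
#' per-pixel and per-region fitting).
#'
#' @param truth_tension H x W matrix of tensions, pN/um; all positive.
#' @param base_params a [mech_params()] object supplying all non-tension
#'   parameters.
#' @param pixel_size pixel size, nm.
#' @param sampling_rate frame rate, Hz.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return A [fluctuation_movie()] in height units carrying
#'   `truth_tension`.
#' @export
simulate_fluctuation_movie <- function(truth_tension, base_params,
                                       pixel_size = 65, sampling_rate = 20,
                                       n_frames = 2048L, seed = NULL) {
  truth_tension <- as.matrix(truth_tension)
  if (any(!is.finite(truth_tension)) || any(truth_tension <= 0))
    stop("simulate_fluctuation_movie: truth_tension must be positive")
  if (!.is_mech_params(base_params))
    base_params <- do.call(mech_params, as.list(base_params))
  h <- nrow(truth_tension); w <- ncol(truth_tension)
  vals <- .with_seed(seed, {
    a <- array(0, c(n_frames, h, w))
    for (j in seq_len(w)) for (i in seq_len(h)) {
      p <- base_params
      p$sigma <- truth_tension[i, j]
      a[, i, j] <- .height_series_draw(p, sampling_rate, n_frames)
    }
    a
  })
  fluctuation_movie(vals, units = "nm", pixel_size = pixel_size,
                    frame_interval = 1 / sampling_rate, seed = seed,
                    truth_tension = truth_tension)
}
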