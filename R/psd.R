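#' Power spectral density estimate of a height time series
#'
#' Two estimators are provided. `"periodogram-average"` (the default
#' test oracle) averages one-sided periodograms of non-overlapping,
#' demeaned segments (Bartlett/Welch with a rectangular window); its
#' scaling is exactly Parseval-consistent, i.e. `sum(power) * df`
#' equals the mean segment variance. `"ar"` fits an autoregressive
#' model by Burg's method (forward-backward prediction error, the
#' moving-window cousin of the covariance-method estimators used for
#' membrane fluctuation spectra) and evaluates its rational spectrum.
#'
#' @param series numeric height series in nm, or a single-pixel
#'   height-mode [fluctuation_movie()].
#' @param sampling_rate sampling rate, Hz (taken from the movie when
#'   omitted).
#' @param method `"periodogram-average"` or `"ar"`.
#' @param ar_order autoregressive model order (default 16).
#' @param n_segments number of segments for the periodogram average.
#' @param n_freq frequency grid size for the AR spectrum.
#' @return An object of class `psd_estimate` with fields `freq` (Hz,
#'   excluding 0), `power` (nm^2/Hz), `method`, `n_frames`,
#'   `sampling_rate`.
#' @export
estimate_psd <- function(series, sampling_rate = NULL,
                         method = c("periodogram-average", "ar"),
                         ar_order = 16L, n_segments = 8L, n_freq = 256L) {
  method <- match.arg(method)
  if (inherits(series, "fluctuation_movie")) {
    if (series$units != "nm")
      stop("estimate_psd: movie must be in height units")
    if (prod(dim(series$values)[2:3]) != 1L)
      stop("estimate_psd: movie must be a single-pixel series; use map_pixelwise for fields")
    if (is.null(sampling_rate)) sampling_rate <- .movie_rate(series)
    series <- as.numeric(series$values)
  }
  if (is.null(sampling_rate) || sampling_rate <= 0)
    stop("estimate_psd: sampling_rate must be positive")
  n <- length(series)
  if (method == "ar" && n < 4L * ar_order)
    stop("estimate_psd: series too short for the requested AR order")
  if (method == "periodogram-average" && n < 4L * n_segments)
    stop("estimate_psd: series too short")
  fs <- sampling_rate
  if (method == "periodogram-average") {
    seg_len <- n %/% n_segments
    if (seg_len %% 2L == 1L) seg_len <- seg_len - 1L
    half <- seg_len %/% 2L
    freq <- (1:half) * fs / seg_len
    acc <- numeric(half)
    for (s in seq_len(n_segments)) {
      x <- series[((s - 1L) * seg_len + 1L):(s * seg_len)]
      x <- x - mean(x)
      P <- Mod(stats::fft(x))^2
      S <- 2 * P[2:(half + 1L)] / (seg_len * fs)
      S[half] <- S[half] / 2            # Nyquist bin counted once
      acc <- acc + S
    }
    power <- acc / n_segments
  } else {
    fit <- stats::ar.burg(series, aic = FALSE, order.max = ar_order,
                          demean = TRUE)
    a <- fit$ar
    s2 <- fit$var.pred
    freq <- seq_len(n_freq) * (fs / 2) / n_freq
    om <- outer(2 * pi * freq / fs, seq_along(a))
    A <- 1 - (cos(om) %*% a) + 1i * (sin(om) %*% a)
    power <- as.vector(2 * (s2 / fs) / Mod(A)^2)
  }
  structure(list(freq = freq, power = power, method = method,
                 n_frames = n, sampling_rate = fs),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("psd_estimate [%s]: %d bins on (%.3g, %.3g] Hz from %d frames\n",
              x$method, length(x$freq), min(x$freq), max(x$freq), x$n_frames))
  invisible(x)
}

#' Temporal standard deviation of membrane height (SD_time)
#'
#' Per-pixel standard deviation of the height series over time; the
#' value of a region is the mean of its pixels' SD_time.
#'
#' @param x a height-mode [fluctuation_movie()] or a numeric series.
#' @return An H x W matrix of SD_time in nm for a movie, a scalar for a
#'   series.
#' @export
compute_sd_time <- function(x) {
  if (inherits(x, "fluctuation_movie")) {
    if (x$units != "nm") stop("compute_sd_time: movie must be in height units")
    if (dim(x$values)[1] < 2L) stop("compute_sd_time: need >= 2 frames")
    return(apply(x$values, c(2, 3), stats::sd))
  }
  if (length(x) < 2L) stop("compute_sd_time: need >= 2 frames")
  stats::sd(x)
}
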