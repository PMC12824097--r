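# Evaluate expr with a locally seeded RNG, restoring global state after.
# All generators route randomness through this so no global state leaks.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop("seed must be a single finite number")
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Time-resolved basal-membrane movie
#'
#' Container for a T x H x W array of relative membrane height (nm) or
#' interference intensity (arbitrary units), with acquisition metadata
#' and, for synthetic movies, the generating per-pixel tension field.
#'
#' @param values numeric array, dim `c(T, H, W)` (a plain vector or
#'   matrix is promoted to a single-pixel / single-column movie).
#' @param units `"nm"` (relative height) or `"au"` (intensity).
#' @param pixel_size pixel size, nm.
#' @param frame_interval frame interval, s.
#' @param seed generating seed, or `NULL`.
#' @param truth_tension optional H x W matrix of generating tension,
#'   pN/um.
#' @return An object of class `fluctuation_movie`.
#' @export
fluctuation_movie <- function(values, units = c("nm", "au"),
                              pixel_size = 65, frame_interval = 0.05,
                              seed = NULL, truth_tension = NULL) {
  units <- match.arg(units)
  if (is.null(dim(values))) values <- array(values, c(length(values), 1L, 1L))
  if (length(dim(values)) == 2L)
    values <- array(values, c(nrow(values), ncol(values), 1L))
  if (length(dim(values)) != 3L || dim(values)[1] < 2L)
    stop("fluctuation_movie: values must have >= 2 frames")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("fluctuation_movie: frame_interval must be positive")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("fluctuation_movie: pixel_size must be positive")
  if (!is.null(truth_tension)) {
    truth_tension <- as.matrix(truth_tension)
    if (!all(dim(truth_tension) == dim(values)[2:3]))
      stop("fluctuation_movie: truth_tension must match spatial dimensions")
  }
  structure(list(values = values, units = units, pixel_size = pixel_size,
                 frame_interval = frame_interval, seed = seed,
                 truth_tension = truth_tension),
            class = "fluctuation_movie")
}

#' @export
print.fluctuation_movie <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("fluctuation_movie: %d frames of %d x %d px [%s], %g nm/px, %g s/frame\n",
              d[1], d[2], d[3], x$units, x$pixel_size, x$frame_interval))
  if (!is.null(x$truth_tension)) cat("  carries ground-truth tension field\n")
  invisible(x)
}

# sampling rate in Hz
.movie_rate <- function(movie) 1 / movie$frame_interval

#' Multi-channel fluorescence stack
#'
#' Container for one or more fluorescence channels of a Z x H x W image
#' stack, stored as an array with dim `c(H, W, Z, C)`.
#'
#' @param values numeric array `c(H, W, Z, C)`; a matrix is promoted to
#'   a single-slice, single-channel stack.
#' @param channels character vector of channel names, length C.
#' @param pixel_size_xy lateral pixel size, um (default 0.13).
#' @param z_step axial step, um (default 1).
#' @param truth_masks optional logical array of the same dim.
#' @param truth_overlap_fraction optional ground-truth overlap fraction.
#' @param extra optional named list of additional ground-truth metadata.
#' @return An object of class `fluorescence_stack`.
#' @export
fluorescence_stack <- function(values, channels = NULL,
                               pixel_size_xy = 0.13, z_step = 1,
                               truth_masks = NULL,
                               truth_overlap_fraction = NULL,
                               extra = list()) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L, 1L))
  if (length(dim(values)) == 3L) values <- array(values, c(dim(values), 1L))
  if (length(dim(values)) != 4L)
    stop("fluorescence_stack: values must be H x W x Z x C")
  if (any(values < 0)) stop("fluorescence_stack: intensities must be >= 0")
  nc <- dim(values)[4]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (length(channels) != nc)
    stop("fluorescence_stack: channel names must match channel count")
  if (!is.null(truth_masks) && !all(dim(truth_masks) == dim(values)))
    stop("fluorescence_stack: truth_masks must match values dimensions")
  if (!is.null(truth_overlap_fraction) &&
      (truth_overlap_fraction < 0 || truth_overlap_fraction > 1))
    stop("fluorescence_stack: truth_overlap_fraction must lie in [0, 1]")
  structure(list(values = values, channels = channels,
                 pixel_size_xy = pixel_size_xy, z_step = z_step,
                 truth_masks = truth_masks,
                 truth_overlap_fraction = truth_overlap_fraction,
                 extra = extra),
            class = "fluorescence_stack")
}

#' @export
print.fluorescence_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("fluorescence_stack: %d x %d px, %d slice(s), channels: %s\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", ")))
  invisible(x)
}

# channel c, slice z as a matrix
.slice <- function(stack, z = 1L, channel = 1L) {
  if (is.character(channel)) channel <- match(channel, stack$channels)
  stack$values[, , z, channel]
}

#' One-dimensional small-angle scattering profile
#'
#' @param s momentum transfer grid, 1/nm; strictly increasing.
#' @param intensity positive scattered intensities, arbitrary units.
#' @param sigma_I optional intensity uncertainties.
#' @return An object of class `scattering_profile`.
#' @export
scattering_profile <- function(s, intensity, sigma_I = NULL) {
  if (length(s) != length(intensity) || length(s) < 8L)
    stop("scattering_profile: need matched s/intensity of length >= 8")
  if (any(diff(s) <= 0)) stop("scattering_profile: s must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("scattering_profile: intensities must be positive and finite")
  if (!is.null(sigma_I) && length(sigma_I) != length(s))
    stop("scattering_profile: sigma_I length mismatch")
  structure(list(s = as.numeric(s), intensity = as.numeric(intensity),
                 sigma_I = sigma_I),
            class = "scattering_profile")
}

#' Fluorescence correlation curve
#'
#' @param tau strictly increasing positive lag times, s.
#' @param g correlation amplitudes G(tau).
#' @param label free-text label (e.g. unlabeled-ligand concentration).
#' @return An object of class `correlation_curve`.
#' @export
correlation_curve <- function(tau, g, label = "") {
  if (length(tau) != length(g) || length(tau) < 10L)
    stop("correlation_curve: need matched tau/g of length >= 10")
  if (any(tau <= 0) || any(diff(tau) <= 0))
    stop("correlation_curve: tau must be positive and strictly increasing")
  if (any(!is.finite(g))) stop("correlation_curve: g must be finite")
  structure(list(tau = as.numeric(tau), g = as.numeric(g), label = label),
            class = "correlation_curve")
}
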