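#' Height of a sphere surface above its contact point
#'
#' Exact sphere geometry used to convert radial position on a bead
#' interference image into local gap height:
#' \eqn{h(r) = R - \sqrt{R^2 - r^2}} (approximately \eqn{r^2/2R} for
#' \eqn{r \ll R}).
#'
#' @param r radial distance from the contact point, nm.
#' @param radius sphere radius, nm.
#' @return Height, nm.
#' @export
sphere_height <- function(r, radius) {
  if (any(r < 0) || radius <= 0 || any(r > radius))
    stop("sphere_height: need 0 <= r <= radius and radius > 0")
  radius - sqrt(radius^2 - r^2)
}

#' Intensity-to-height calibration of interference images
#'
#' @param slope intensity units per nm of height (dI/dh), non-zero.
#' @param intercept intensity at zero height, a.u.
#' @param valid_height_range first-branch height interval, nm.
#' @param intensity_range intensity interval spanned by the first
#'   branch (used to screen candidate regions).
#' @param wavelength illumination wavelength, nm (546 by default, the
#'   center of the interference filter band).
#' @param refractive_index medium refractive index.
#' @return An object of class `height_calibration`.
#' @export
height_calibration <- function(slope, intercept = 0,
                               valid_height_range = c(0, 100),
                               intensity_range = NULL,
                               wavelength = 546, refractive_index = 1.335) {
  if (!is.numeric(slope) || slope == 0)
    stop("height_calibration: slope must be non-zero")
  if (diff(valid_height_range) <= 0)
    stop("height_calibration: valid_height_range must have positive width")
  if (is.null(intensity_range))
    intensity_range <- sort(intercept + slope * valid_height_range)
  structure(list(slope = slope, intercept = intercept,
                 valid_height_range = valid_height_range,
                 intensity_range = intensity_range,
                 wavelength = wavelength,
                 refractive_index = refractive_index),
            class = "height_calibration")
}

#' Calibrate interference intensity against membrane height
#'
#' Uses the radial interference profile of a large bead of known
#' diameter resting on the coverslip: each radial position r maps to a
#' known gap height through exact sphere geometry
#' ([sphere_height()]), and intensity is regressed linearly on height
#' over the first interference branch (the monotone segment within
#' roughly the first 100 nm, bounded above by a quarter wavelength in
#' the medium).
#'
#' @param bead_profile data frame with columns `r` (radial distance
#'   from the contact point, nm) and `intensity` (a.u.).
#' @param bead_diameter bead diameter, um (60 for NIST polystyrene
#'   calibration beads).
#' @param pixel_size pixel size, nm (metadata; `r` is already in nm).
#' @param wavelength illumination wavelength, nm.
#' @param refractive_index medium refractive index.
#' @return A [height_calibration()] with the fitted slope.
#' @export
calibrate_intensity_to_height <- function(bead_profile, bead_diameter = 60,
                                          pixel_size = 65, wavelength = 546,
                                          refractive_index = 1.335) {
  if (bead_diameter <= 0)
    stop("calibrate_intensity_to_height: bead_diameter must be positive")
  if (!all(c("r", "intensity") %in% names(bead_profile)))
    stop("calibrate_intensity_to_height: bead_profile needs columns r, intensity")
  R <- bead_diameter / 2 * 1e3                 # nm
  r <- bead_profile$r
  I <- bead_profile$intensity
  keep <- r >= 0 & r <= R
  r <- r[keep]; I <- I[keep]
  h <- sphere_height(r, R)
  h_branch <- wavelength / (4 * refractive_index)
  in_branch <- h <= h_branch
  if (sum(in_branch) < 3)
    stop("calibration error: bead profile does not cover the first branch")
  h <- h[in_branch]; I <- I[in_branch]
  ord <- order(h)
  h <- h[ord]; I <- I[ord]
  if (abs(stats::cor(h, I)) < 0.5)
    stop("calibration error: no monotone first-branch segment found")
  fit <- stats::lm(I ~ h)
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0) stop("calibration error: zero intensity-height slope")
  height_calibration(slope = slope,
                     intercept = unname(stats::coef(fit)[1]),
                     valid_height_range = c(0, h_branch),
                     intensity_range = range(stats::fitted(fit)),
                     wavelength = wavelength,
                     refractive_index = refractive_index)
}

#' Convert an intensity movie to relative membrane height
#'
#' First-branch linearization: for each pixel the temporal mean
#' intensity is subtracted and the residual divided by the calibration
#' slope, yielding zero-mean relative height in nm.
#'
#' @param movie an intensity-mode [fluctuation_movie()].
#' @param cal a [height_calibration()].
#' @return A height-mode [fluctuation_movie()]; each pixel series has
#'   exactly zero mean.
#' @export
intensity_to_height <- function(movie, cal) {
  if (!inherits(movie, "fluctuation_movie") || movie$units != "au")
    stop("intensity_to_height: movie must be in intensity units")
  if (cal$slope == 0) stop("intensity_to_height: calibration slope is zero")
  v <- movie$values
  mu <- apply(v, c(2, 3), mean)
  h <- sweep(v, c(2, 3), mu, "-") / cal$slope
  fluctuation_movie(h, units = "nm", pixel_size = movie$pixel_size,
                    frame_interval = movie$frame_interval, seed = movie$seed,
                    truth_tension = movie$truth_tension)
}

#' Convert a height movie to interference intensity
#'
#' Inverse of [intensity_to_height()]: intensity = baseline +
#' slope * height. Used by the synthetic-data route so the calibration
#' operations can be exercised round-trip.
#'
#' @param movie a height-mode [fluctuation_movie()].
#' @param cal a [height_calibration()].
#' @param baseline constant intensity offset added to every pixel, a.u.
#' @return An intensity-mode [fluctuation_movie()].
#' @export
height_to_intensity <- function(movie, cal, baseline = NULL) {
  if (!inherits(movie, "fluctuation_movie") || movie$units != "nm")
    stop("height_to_intensity: movie must be in height units")
  if (is.null(baseline)) baseline <- mean(cal$intensity_range)
  v <- baseline + cal$slope * movie$values
  fluctuation_movie(v, units = "au", pixel_size = movie$pixel_size,
                    frame_interval = movie$frame_interval, seed = movie$seed,
                    truth_tension = movie$truth_tension)
}

#' Select stable first-branch regions of an intensity movie
#'
#' Tiles the field into non-overlapping `region_size` x `region_size`
#' regions (4 x 4 pixels by default) and keeps those whose mean
#' intensity lies inside the first interference branch of the
#' calibration and whose temporal drift (fitted linear trend of the
#' region-mean intensity over the whole movie) stays below the
#' stability limit.
#'
#' @param movie an intensity-mode [fluctuation_movie()].
#' @param cal a [height_calibration()].
#' @param region_size region side length, px.
#' @param stability_limits list with `max_drift_fraction`: maximal
#'   allowed absolute end-to-end linear drift, as a fraction of the
#'   first-branch intensity span.
#' @return Integer matrix of region origins (columns `row`, `col`,
#'   1-based top-left corners); zero rows when nothing qualifies.
#' @export
select_fbr_regions <- function(movie, cal, region_size = 4L,
                               stability_limits = list(max_drift_fraction = 0.05)) {
  if (!inherits(movie, "fluctuation_movie") || movie$units != "au")
    stop("select_fbr_regions: movie must be in intensity units")
  d <- dim(movie$values)
  nt <- d[1]; h <- d[2]; w <- d[3]
  span <- diff(cal$intensity_range)
  max_drift <- stability_limits$max_drift_fraction * span
  tt <- seq_len(nt)
  out <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  for (i0 in seq(1L, h - region_size + 1L, by = region_size)) {
    for (j0 in seq(1L, w - region_size + 1L, by = region_size)) {
      block <- movie$values[, i0:(i0 + region_size - 1L),
                            j0:(j0 + region_size - 1L), drop = FALSE]
      reg_mean <- apply(block, 1, mean)
      m <- mean(reg_mean)
      if (m < min(cal$intensity_range) || m > max(cal$intensity_range)) next
      slope <- stats::cov(tt, reg_mean) / stats::var(tt)
      if (abs(slope) * (nt - 1) > max_drift) next
      out <- rbind(out, c(i0, j0))
    }
  }
  out
}
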