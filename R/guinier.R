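#' Guinier fit for a globular scatterer
#'
#' Weighted linear fit of `ln I` versus `s^2` over the low-angle
#' window, giving the radius of gyration `rg = sqrt(-3 * slope)` and
#' forward intensity `i0 = exp(intercept)`. The admissible window
#' `s * rg <= srg_max` depends on the estimate itself, so the fit
#' iterates the window with the current rg until it stabilizes (at
#' most 20 iterations). Points are weighted by `(I / sigma_I)^2` when
#' uncertainties are present (the error of ln I), unweighted otherwise.
#'
#' @param profile a [scattering_profile()].
#' @param srg_max Guinier window limit in `s * rg` units (1.3 by
#'   convention for globular shapes).
#' @return An object of class `guinier_result`: `rg` (nm), `i0`,
#'   `fit_range_max_srg`, `r2`, `n_points`.
#' @export
guinier_fit_globular <- function(profile, srg_max = 1.3) {
  s <- profile$s; I <- profile$intensity
  wts <- if (!is.null(profile$sigma_I)) (I / profile$sigma_I)^2 else NULL
  fit_window <- function(keep) {
    x <- s[keep]^2; y <- log(I[keep])
    fit <- if (is.null(wts)) stats::lm(y ~ x)
           else stats::lm(y ~ x, weights = wts[keep])
    slope <- unname(stats::coef(fit)[2])
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
    list(slope = slope, intercept = unname(stats::coef(fit)[1]), r2 = r2)
  }
  # initial window: first third of the grid
  keep <- seq_len(max(3L, length(s) %/% 3L))
  rg <- NA_real_
  for (it in 1:20) {
    if (sum(keep) < 3 || length(keep) < 3)
      stop("fit error: too few points in the Guinier window")
    f <- fit_window(keep)
    if (f$slope >= 0)
      stop("fit error: non-decaying profile (non-negative Guinier slope)")
    rg_new <- sqrt(-3 * f$slope)
    keep_new <- which(s * rg_new <= srg_max)
    if (length(keep_new) < 3)
      stop("fit error: too few points with s*rg <= srg_max")
    if (is.finite(rg) && abs(rg_new - rg) < 1e-9 * rg_new &&
        identical(keep_new, keep)) { rg <- rg_new; keep <- keep_new; break }
    rg <- rg_new; keep <- keep_new
  }
  f <- fit_window(keep)
  rg <- sqrt(-3 * f$slope)
  structure(list(rg = rg, i0 = exp(f$intercept),
                 fit_range_max_srg = max(profile$s[keep]) * rg,
                 r2 = f$r2, n_points = length(keep), window = keep),
            class = "guinier_result")
}

#' Guinier fit for a rod-like scatterer
#'
#' Linear fit of `ln(s * I)` versus `s^2` over the given window; the
#' cross-section radius is `rc = sqrt(-2 * slope)`.
#'
#' @param profile a [scattering_profile()].
#' @param range optional index or logical vector selecting the fit
#'   window (default: all points).
#' @return An object of class `rod_guinier_result`: `rc` (nm), `r2`,
#'   `n_points`.
#' @export
guinier_fit_rod <- function(profile, range = NULL) {
  s <- profile$s; I <- profile$intensity
  keep <- if (is.null(range)) seq_along(s) else range
  x <- s[keep]^2; y <- log(s[keep] * I[keep])
  if (length(x) < 3) stop("fit error: too few points")
  wts <- if (!is.null(profile$sigma_I)) (I[keep] / profile$sigma_I[keep])^2
         else NULL
  fit <- if (is.null(wts)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = wts)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("fit error: non-decaying profile (non-negative rod Guinier slope)")
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(rc = sqrt(-2 * slope), r2 = r2,
                 n_points = length(x)),
            class = "rod_guinier_result")
}

#' Shape parameters from Guinier radii
#'
#' Persistence length and aspect ratio of an elongated scatterer from
#' its radius of gyration and cross-section radius:
#' \eqn{L = \sqrt{12 (R_g^2 - R_c^2)}}, \eqn{A = R_g / R_c}.
#'
#' @param rg radius of gyration, nm.
#' @param rc cross-section radius, nm; must satisfy `rc <= rg`.
#' @return List `l_persist` (nm), `a_aspect` (dimensionless).
#' @examples
#' shape_parameters(5.63, 0.78)  # L = 19.31 nm, A = 7.22
#' @export
shape_parameters <- function(rg, rc) {
  if (rc <= 0 || rg <= 0) stop("shape_parameters: radii must be positive")
  if (rc > rg)
    stop("shape_parameters: rc > rg gives a negative radicand (domain error)")
  list(l_persist = sqrt(12 * (rg^2 - rc^2)), a_aspect = rg / rc)
}

#' Dimensionless Kratky transform
#'
#' Computes `y = (s * rg)^2 * I(s) / i0` on `x = s * rg`. For an ideal
#' globular (Guinier) scatterer the curve peaks at
#' \eqn{x = \sqrt{3} \approx 1.73}. The peak is located by grid
#' maximum.
#'
#' @param profile a [scattering_profile()].
#' @param rg radius of gyration, nm.
#' @param i0 forward intensity, a.u.
#' @return An object of class `kratky_curve`: `x`, `y`, `peak_x`.
#' @export
dimensionless_kratky <- function(profile, rg, i0) {
  if (rg <= 0 || i0 <= 0) stop("dimensionless_kratky: rg and i0 must be positive")
  x <- profile$s * rg
  y <- x^2 * profile$intensity / i0
  structure(list(x = x, y = y, peak_x = x[which.max(y)]),
            class = "kratky_curve")
}

#' Detect an interparticle (structure-factor) effect
#'
#' Mutually repelling charged particles suppress scattering at the
#' lowest angles, pulling the measured intensity below the Guinier
#' extrapolation as s approaches 0. The test refits Guinier on the
#' profile excluding the `n_low` lowest-s points, extrapolates to those
#' points, and flags an interparticle effect when the mean relative
#' deficit exceeds `deficit_tol` and all-but-chance points fall below
#' the extrapolation (one-sided sign test p < 0.05).
#'
#' @param profile a [scattering_profile()].
#' @param rg radius of gyration (used for the Guinier window of the
#'   refit); when `NULL`, taken from the refit itself.
#' @param n_low number of lowest-s points examined (>= 3).
#' @param deficit_tol mean relative deficit threshold.
#' @return List `interparticle` (logical), `mean_deficit`, `p_sign`;
#'   `interparticle = NA` when fewer than 3 low-s points are available.
#' @export
detect_interparticle_effect <- function(profile, rg = NULL, n_low = 5L,
                                        deficit_tol = 0.05) {
  if (n_low < 3L)
    return(list(interparticle = NA, mean_deficit = NA_real_, p_sign = NA_real_))
  s <- profile$s; I <- profile$intensity
  if (length(s) < n_low + 8L)
    return(list(interparticle = NA, mean_deficit = NA_real_, p_sign = NA_real_))
  rest <- scattering_profile(s[-(1:n_low)], I[-(1:n_low)],
                             sigma_I = profile$sigma_I[-(1:n_low)])
  g <- guinier_fit_globular(rest)
  pred <- g$i0 * exp(-s[1:n_low]^2 * g$rg^2 / 3)
  deficit <- (pred - I[1:n_low]) / pred
  n_below <- sum(deficit > 0)
  p_sign <- stats::pbinom(n_below - 1, n_low, 0.5, lower.tail = FALSE)
  list(interparticle = mean(deficit) > deficit_tol && p_sign < 0.05,
       mean_deficit = mean(deficit), p_sign = p_sign)
}
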